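## Readers and writers for the tables the pipeline consumes and emits.
## One internal coordinate convention everywhere: 0-based, half-open
## intervals; single-base sites carry the 0-based position of the cytosine.

CX_COLS <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")

#' Read a per-cytosine methylation count table
#'
#' The table is a 6-column TSV — a restriction of the Bismark CX-report
#' layout — with columns `chrom`, `pos` (0-based), `strand` (`+`/`-`),
#' `context` (`CG`, `CA`, `CT`, `CC`), `n_meth` (bisulfite-protected C
#' reads) and `n_unmeth` (converted T reads). Files may be
#' gzip-compressed.
#'
#' @param path path to the TSV (optionally `.gz`).
#' @param min_coverage drop sites whose total read coverage
#'   (`n_meth + n_unmeth`) is below this value.
#' @return a tibble of validated sites, sorted by `chrom`, `pos`,
#'   `strand`.
#' @details Duplicated `(chrom, pos, strand)` rows are an error, not
#'   summed: duplicates indicate an upstream bug.
#' @export
read_cx_table <- function(path, min_coverage = 0) {
  stopifnot(min_coverage >= 0)
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_names = CX_COLS,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      strand = readr::col_character(),
      context = readr::col_character(),
      n_meth = readr::col_integer(),
      n_unmeth = readr::col_integer()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed cytosine table row at line %d of %s",
                  probs$row[1], path))
  }
  validate_cx_sites(x, what = path)
  x <- dplyr::filter(x, .data$n_meth + .data$n_unmeth >= min_coverage)
  dplyr::arrange(x, .data$chrom, .data$pos, .data$strand)
}

validate_cx_sites <- function(x, what = "cytosine table") {
  assert_cols(x, CX_COLS, what)
  if (anyNA(x$pos) || anyNA(x$n_meth) || anyNA(x$n_unmeth)) {
    abort(sprintf("%s: missing values in pos or counts", what))
  }
  if (any(x$n_meth < 0) || any(x$n_unmeth < 0)) {
    abort(sprintf("%s: negative methylation counts", what))
  }
  bad_ctx <- setdiff(unique(x$context), VALID_CONTEXTS)
  if (length(bad_ctx)) {
    abort(sprintf("%s: unknown context string(s): %s",
                  what, paste(bad_ctx, collapse = ", ")))
  }
  if (!all(x$strand %in% c("+", "-"))) {
    abort(sprintf("%s: strand must be '+' or '-'", what))
  }
  if (anyDuplicated(x[c("chrom", "pos", "strand")])) {
    abort(sprintf("%s: duplicated (chrom, pos, strand) rows", what))
  }
  invisible(x)
}

#' Write a per-cytosine methylation count table
#'
#' @param sites tibble with the [read_cx_table()] columns.
#' @param path output TSV path (written without a header; `.gz` is
#'   compressed automatically).
#' @return `path`, invisibly.
#' @export
write_cx_table <- function(sites, path) {
  assert_cols(sites, CX_COLS, "sites")
  readr::write_tsv(sites[CX_COLS], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 or BED12
#'
#' Coordinates are normalised to the internal 0-based half-open
#' convention (GFF3 is 1-based closed on disk; BED12 is already 0-based
#' half-open). Overlapping exons within a gene are merged.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"bed12"`; `"auto"` guesses from the file
#'   extension.
#' @return a tibble of exons: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `exon_rank` (1 = most 5' on the genome).
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed(\\.gz)?$", path)) "bed12" else "gff3"
  }
  exons <- if (dialect == "gff3") read_annotation_gff3(path) else
    read_annotation_bed12(path)
  validate_gene_models(exons)
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0) abort(sprintf("no exon features in %s", path))
  gid <- if (!is.null(ex$gene_id)) {
    as.character(ex$gene_id)
  } else if (!is.null(ex$Parent)) {
    vapply(ex$Parent, function(p) as.character(p)[1], character(1))
  } else {
    abort("GFF3 exons carry neither gene_id nor Parent attributes")
  }
  exons <- tibble(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(ex)
  )
  ## check exons sit inside their gene spans when gene rows are present
  gn <- gr[tolower(as.character(gr$type)) == "gene"]
  if (length(gn) > 0 && !is.null(gn$ID)) {
    spans <- tibble(
      gene_id = as.character(gn$ID),
      gstart = GenomicRanges::start(gn) - 1L,
      gend = GenomicRanges::end(gn)
    )
    chk <- dplyr::inner_join(exons, spans, by = "gene_id")
    if (any(chk$start < chk$gstart | chk$end > chk$gend)) {
      abort(sprintf("exon outside gene span in %s", path))
    }
  }
  exons
}

read_annotation_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)
  nm <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
  names(bl) <- nm
  flat <- unlist(bl, use.names = TRUE)
  tibble(
    gene_id = names(flat),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    strand = as.character(GenomicRanges::strand(flat)),
    start = GenomicRanges::start(flat) - 1L,
    end = GenomicRanges::end(flat)
  )
}

## enforce GeneModel invariants: merge overlaps, sort, rank
validate_gene_models <- function(exons) {
  assert_cols(exons, c("gene_id", "chrom", "strand", "start", "end"),
              "gene models")
  if (!all(exons$strand %in% c("+", "-"))) {
    abort("gene models: unknown strand (must be '+' or '-')")
  }
  if (any(exons$end <= exons$start)) {
    abort("gene models: exon end must exceed start")
  }
  exons |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::reframe({
      ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    dplyr::arrange(.data$chrom, .data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(exon_rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Gene spans from an exon table
#'
#' @param genes exon tibble from [read_annotation()].
#' @return one row per gene: `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (span of the first to last exon), `n_exons`.
#' @export
gene_spans <- function(genes) {
  genes |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_exons = dplyr::n(), .groups = "drop")
}

#' Intron intervals from an exon table
#'
#' Introns are the gaps between consecutive exons of a gene.
#'
#' @inheritParams gene_spans
#' @return tibble `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_introns <- function(genes) {
  genes |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::reframe(start = head(.data$end, -1), end = tail(.data$start, -1)) |>
    dplyr::filter(.data$end > .data$start)
}

#' Partition a genome into exonic / intronic / repeat / intergenic
#'
#' Produces disjoint labelled intervals covering every base of every
#' chromosome, with precedence exonic > intronic > repeat > intergenic
#' when annotations overlap.
#'
#' @param genes exon tibble from [read_annotation()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param repeats optional repeat intervals: tibble `chrom`, `start`,
#'   `end` (0-based half-open; BED3 content).
#' @return tibble `chrom`, `start`, `end`, `width`, `label`.
#' @export
partition_genome <- function(genes, chrom_sizes, repeats = NULL) {
  chroms <- unique(c(genes$chrom, if (!is.null(repeats)) repeats$chrom))
  missing <- setdiff(chroms, names(chrom_sizes))
  if (length(missing)) {
    abort(sprintf("chrom_sizes does not cover: %s",
                  paste(missing, collapse = ", ")))
  }
  check_bounds <- function(df, what) {
    lim <- chrom_sizes[df$chrom]
    if (any(df$end > lim) || any(df$start < 0)) {
      abort(sprintf("%s interval beyond chromosome end", what))
    }
  }
  check_bounds(genes, "exon")
  if (!is.null(repeats)) check_bounds(repeats, "repeat")

  genome_gr <- GenomicRanges::GRanges(
    seqnames = names(chrom_sizes),
    ranges = IRanges::IRanges(start = 1L, width = unname(chrom_sizes))
  )
  empty <- GenomicRanges::GRanges()
  exonic <- GenomicRanges::reduce(to_granges(genes))
  GenomicRanges::strand(exonic) <- "*"
  genic <- GenomicRanges::reduce(to_granges(gene_spans(genes)))
  GenomicRanges::strand(genic) <- "*"
  intronic <- GenomicRanges::setdiff(genic, exonic)
  rep_gr <- if (is.null(repeats) || nrow(repeats) == 0) empty else
    GenomicRanges::reduce(to_granges(repeats))
  rep_only <- GenomicRanges::setdiff(rep_gr,
                                     GenomicRanges::union(exonic, intronic))
  used <- Reduce(GenomicRanges::union, list(exonic, intronic, rep_only))
  intergenic <- GenomicRanges::setdiff(genome_gr, used)

  as_tbl <- function(gr, label) {
    if (length(gr) == 0) return(tibble(chrom = character(), start = integer(),
                                       end = integer(), label = character()))
    tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      label = label
    )
  }
  dplyr::bind_rows(
    as_tbl(exonic, "exonic"), as_tbl(intronic, "intronic"),
    as_tbl(rep_only, "repeat"), as_tbl(intergenic, "intergenic")
  ) |>
    dplyr::mutate(width = .data$end - .data$start) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end", "width", "label")
}

#' Pool symmetric CG strand pairs
#'
#' A CG dinucleotide exposes a cytosine on each strand (plus-strand C at
#' `p`, minus-strand C at `p + 1`). This sums the counts of such pairs
#' into a single plus-strand record at `p`; unpaired CG sites are kept
#' as-is. Non-CG contexts are inherently asymmetric and pass through
#' unchanged.
#'
#' @param sites cytosine tibble (see [read_cx_table()]).
#' @return tibble with pooled CG records.
#' @export
pool_cg_strands <- function(sites) {
  grp <- group_cols_present(sites)
  cg <- dplyr::filter(sites, .data$context == "CG")
  other <- dplyr::filter(sites, .data$context != "CG")
  pooled <- cg |>
    dplyr::mutate(dyad = ifelse(.data$strand == "+", .data$pos, .data$pos - 1L)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "chrom", "dyad")))) |>
    dplyr::summarise(
      strand = "+", context = "CG",
      n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
      .groups = "drop"
    ) |>
    dplyr::rename(pos = "dyad")
  dplyr::bind_rows(pooled, other) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "chrom", "pos"))))
}

#' Read / write read-level CG state records
#'
#' TSV layout: `read_id`, `feature_id`, `states` (comma-joined `M`/`U`
#' over the CG positions the read covers, in genomic order); any further
#' columns (e.g. `tissue`) are preserved.
#'
#' @param path TSV path.
#' @return tibble with at least `read_id`, `feature_id`, `states`.
#' @export
read_read_level <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  assert_cols(x, c("read_id", "feature_id", "states"), path)
  bad <- !grepl("^[MU](,[MU])*$", x$states)
  if (any(bad)) {
    abort(sprintf("%s: malformed states field at data row %d",
                  path, which(bad)[1]))
  }
  x
}

#' @rdname read_read_level
#' @param records tibble of read-level records.
#' @export
write_read_level <- function(records, path) {
  assert_cols(records, c("read_id", "feature_id", "states"), "records")
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read / write long-format expression tables
#'
#' Layout: `gene_id`, `sample`, `replicate`, `fpkm`. Negative FPKM or a
#' duplicated `(gene, sample, replicate)` key is an error.
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  assert_cols(x, c("gene_id", "sample", "replicate", "fpkm"), path)
  if (any(x$fpkm < 0, na.rm = TRUE)) abort(sprintf("%s: negative FPKM", path))
  if (anyDuplicated(x[c("gene_id", "sample", "replicate")])) {
    abort(sprintf("%s: duplicated (gene, sample, replicate) rows", path))
  }
  x
}

#' @rdname read_expression
#' @param expression tibble of expression rows.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Read / write differential-expression call tables
#'
#' Layout: `gene_id`, `sample_a`, `sample_b`, `q_value`, `fold_change`.
#' A gene is differentially expressed in a pair when `q_value < 0.05`
#' and `fold_change > 2` (fold change is the larger over the smaller
#' FPKM, so always > 0).
#'
#' @param path TSV path.
#' @return tibble with an `is_de` logical column added per the rule.
#' @export
read_de_calls <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  assert_cols(x, c("gene_id", "sample_a", "sample_b", "q_value", "fold_change"),
              path)
  if (any(x$q_value < 0 | x$q_value > 1, na.rm = TRUE)) {
    abort(sprintf("%s: q_value outside [0, 1]", path))
  }
  if (any(x$fold_change <= 0, na.rm = TRUE)) {
    abort(sprintf("%s: fold_change must be positive", path))
  }
  dplyr::mutate(x, is_de = .data$q_value < 0.05 & .data$fold_change > 2)
}

#' @rdname read_de_calls
#' @param de_calls tibble of DE call rows.
#' @export
write_de_calls <- function(de_calls, path) {
  readr::write_tsv(de_calls, path, progress = FALSE)
  invisible(path)
}

#' Read / write percent-spliced-in (PSI) tables
#'
#' SUPPA-style long layout: `event_id`, `event_type` (`SE`, `RI`, `A5`,
#' `A3`), `chrom`, `start`, `end` (0-based half-open event interval),
#' `sample`, `replicate`, `psi`. Missing PSI (SUPPA emits NA for
#' zero-expression events) is kept as `NA`, never coerced to 0.
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_psi <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), na = c("", "NA"),
                       progress = FALSE)
  assert_cols(x, c("event_id", "event_type", "chrom", "start", "end",
                   "sample", "replicate", "psi"), path)
  bad_type <- setdiff(unique(x$event_type), c("SE", "RI", "A5", "A3"))
  if (length(bad_type)) {
    abort(sprintf("%s: unknown event_type: %s", path,
                  paste(bad_type, collapse = ", ")))
  }
  if (any(x$psi < 0 | x$psi > 1, na.rm = TRUE)) {
    abort(sprintf("%s: PSI outside [0, 1]", path))
  }
  x
}

#' @rdname read_psi
#' @param psi tibble of PSI rows.
#' @export
write_psi <- function(psi, path) {
  readr::write_tsv(psi, path, progress = FALSE)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' @rdname read_genome_fasta
#' @param genome named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), filepath = path)
  invisible(path)
}
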