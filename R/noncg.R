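## Non-CG (CH / CW) methylation analysis: sequence-context annotation,
## context-level summaries, per-context gene profiles split by CG
## methylation class, the CH error-rate estimator based on reads
## supporting a CG dinucleotide at reference CH sites, and position
## frequency matrices around methylated CA sites.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Annotate cytosine dinucleotide contexts from a genome
#'
#' Assigns each position its context — the reference base immediately
#' downstream of the cytosine on its own strand (`CG`, `CA`, `CT`,
#' `CC`). On the minus strand the downstream base is the complement of
#' the base at `pos - 1`. Positions whose claimed strand does not
#' carry a C are an error; terminal cytosines with no downstream base
#' are dropped (count in the `n_dropped` attribute).
#'
#' @param genome named character vector of chromosome sequences (see
#'   [read_genome_fasta()]).
#' @param positions tibble `chrom`, `pos` (0-based), `strand`.
#' @return input tibble with a `context` column; terminal positions
#'   removed.
#' @export
annotate_context <- function(genome, positions) {
  assert_cols(positions, c("chrom", "pos", "strand"), "positions")
  out <- positions
  out$context <- NA_character_
  for (ch in unique(positions$chrom)) {
    if (!ch %in% names(genome)) abort(sprintf("chromosome %s not in genome", ch))
    seq_chars <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    sel <- which(positions$chrom == ch)
    p <- positions$pos[sel]
    s <- positions$strand[sel]
    base <- seq_chars[p + 1L]
    own <- ifelse(s == "+", base, COMPLEMENT[base])
    if (any(own != "C")) {
      abort(sprintf("position %s:%d is not a cytosine on strand %s",
                    ch, p[which(own != "C")[1]], s[which(own != "C")[1]]))
    }
    down_pos <- ifelse(s == "+", p + 2L, p)       # 1-based index downstream
    in_bounds <- down_pos >= 1L & down_pos <= length(seq_chars)
    down <- rep(NA_character_, length(p))
    down[in_bounds] <- seq_chars[down_pos[in_bounds]]
    down <- ifelse(s == "+", down, COMPLEMENT[down])
    out$context[sel] <- ifelse(is.na(down), NA_character_,
                               paste0("C", down))
  }
  n_dropped <- sum(is.na(out$context))
  out <- dplyr::filter(out, !is.na(.data$context))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Weighted methylation summary per sequence context
#'
#' Summarises weighted methylation, site counts and informative
#' coverage per context, including the derived aggregates CH
#' (CA + CT + CC) and CW (CA + CT), per sample grouping present.
#'
#' @param sites cytosine tibble, optionally with `tissue` /
#'   `replicate` columns.
#' @return tibble: grouping columns, `context`, `level`, `n_sites`,
#'   `n_informative`.
#' @export
context_summary <- function(sites) {
  grp <- group_cols_present(sites)
  base <- sites |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "context")))) |>
    dplyr::summarise(n_meth = sum(.data$n_meth),
                     n_unmeth = sum(.data$n_unmeth),
                     n_sites = dplyr::n(), .groups = "drop")
  derived <- purrr::map_dfr(
    list(CH = c("CA", "CT", "CC"), CW = c("CA", "CT")),
    function(members) dplyr::filter(base, .data$context %in% members) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(n_meth = sum(.data$n_meth),
                       n_unmeth = sum(.data$n_unmeth),
                       n_sites = sum(.data$n_sites), .groups = "drop"),
    .id = "context"
  )
  dplyr::bind_rows(base, derived) |>
    dplyr::mutate(
      n_informative = .data$n_meth + .data$n_unmeth,
      level = ifelse(.data$n_informative > 0,
                     .data$n_meth / .data$n_informative, NA_real_)
    ) |>
    dplyr::select(dplyr::all_of(c(grp, "context", "level", "n_sites",
                                  "n_informative")))
}

#' Per-context gene profiles split by CG-methylation gene class
#'
#' Profiles each requested context along methylated and unmethylated
#' genes (classes defined on the genes' overall CG methylation:
#' methylated > `meth_cutoff`, unmethylated < `unmeth_cutoff`), with
#' optional exon/intron restriction. Empty gene classes yield no rows
#' for that class, with a warning.
#'
#' @param sites single-sample cytosine tibble containing CG and CH
#'   context rows.
#' @param genes exon tibble.
#' @param contexts contexts to profile (default CG, CA, CT).
#' @param meth_cutoff,unmeth_cutoff genic CG-level class cutoffs
#'   (defaults 0.05 and 0.005).
#' @inheritParams gene_aligned_profile
#' @return tibble: `context`, `gene_class`, `offset`, `value`,
#'   `n_contributing`, `coverage`.
#' @export
context_profiles <- function(sites, genes, contexts = c("CG", "CA", "CT"),
                             meth_cutoff = 0.05, unmeth_cutoff = 0.005,
                             end = "5prime", bin_width = 100, span = 3000,
                             region_filter = "any") {
  g_levels <- aggregate_methylation(sites, genes, feature = "gene",
                                    context_filter = "CG")
  classes <- list(
    methylated = g_levels$feature_id[!is.na(g_levels$level) &
                                       g_levels$level > meth_cutoff],
    unmethylated = g_levels$feature_id[!is.na(g_levels$level) &
                                         g_levels$level < unmeth_cutoff]
  )
  purrr::imap_dfr(classes, function(ids, cl) {
    if (length(ids) == 0) {
      warn(sprintf("no genes in the %s class; profiles missing", cl))
      return(tibble())
    }
    gsub_ <- dplyr::filter(genes, .data$gene_id %in% ids)
    purrr::map_dfr(contexts, function(ctx) {
      pr <- gene_aligned_profile(sites, gsub_, end = end,
                                 bin_width = bin_width, span = span,
                                 region_filter = region_filter,
                                 context_filter = ctx)
      dplyr::mutate(as_tibble(pr), context = ctx, gene_class = cl,
                    .before = 1)
    })
  })
}

#' CH error rate from reads supporting CG at reference CH sites
#'
#' Estimates the apparent CH methylation that is explained by genetic
#' CG polymorphism: the percentage of reads overlapping reference CH
#' sites whose base pattern indicates a CG dinucleotide there.
#'
#' @param records read-level tibble `sample`, `indicates_cg` (logical),
#'   one row per assessed read (see
#'   [simulate_ch_error_records()] for the expected upstream layer).
#' @return tibble per sample: `n_reads_assessed`, `n_reads_cg`,
#'   `rate` (percent); `NA` rate with a warning when nothing was
#'   assessed.
#' @export
ch_error_rate <- function(records) {
  assert_cols(records, c("sample", "indicates_cg"), "records")
  out <- records |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_reads_assessed = dplyr::n(),
      n_reads_cg = sum(.data$indicates_cg),
      rate = 100 * .data$n_reads_cg / .data$n_reads_assessed,
      .groups = "drop")
  if (nrow(out) == 0) {
    warn("no reads assessed; error rate undefined")
    return(tibble(sample = character(), n_reads_assessed = integer(),
                  n_reads_cg = integer(), rate = numeric()))
  }
  out
}

#' Position frequency matrix around methylated CA sites
#'
#' Extracts a fixed window around each site (minus-strand windows are
#' reverse-complemented so the methylated C sits at offset 0 with its
#' A at +1), and reports per-position nucleotide frequencies and
#' information content (2 minus the Shannon entropy in bits). Windows
#' that would run past a sequence end drop their site (count in the
#' `n_dropped` attribute).
#'
#' @param sites tibble `chrom`, `pos`, `strand` of methylated CA
#'   cytosines (apply a methylation cutoff upstream).
#' @param genome named character vector of sequences.
#' @param window half-width in bp (default 5: offsets -5..+5).
#' @return tibble of class `"pfm"`: `offset`, `A`, `C`, `G`, `T`
#'   (frequencies summing to 1 per row), `bits`.
#' @export
motif_matrix <- function(sites, genome, window = 5) {
  assert_cols(sites, c("chrom", "pos", "strand"), "sites")
  mats <- vector("list", nrow(sites))
  n_dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    seq_str <- genome[[sites$chrom[i]]]
    n <- nchar(seq_str)
    lo <- sites$pos[i] - window
    hi <- sites$pos[i] + window
    if (lo < 0 || hi >= n) { n_dropped <- n_dropped + 1L; next }
    win <- strsplit(substr(seq_str, lo + 1L, hi + 1L), "",
                    fixed = TRUE)[[1]]
    if (sites$strand[i] == "-") win <- rev(unname(COMPLEMENT[win]))
    mats[[i]] <- win
  }
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 0) abort("no sites with a complete window")
  m <- do.call(rbind, mats)
  offsets <- seq(-window, window)
  out <- purrr::map_dfr(seq_along(offsets), function(j) {
    tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    freq <- as.numeric(tab) / sum(tab)
    ent <- -sum(ifelse(freq > 0, freq * log2(freq), 0))
    tibble(offset = offsets[j], A = freq[1], C = freq[2], G = freq[3],
           T = freq[4], bits = 2 - ent)
  })
  class(out) <- c("pfm", class(out))
  attr(out, "n_sites") <- length(mats)
  attr(out, "n_dropped") <- n_dropped
  out
}
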