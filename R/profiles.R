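## Gene-aligned binned profiles: methylation metaplots, splice-event
## frequency profiles, site-class frequency profiles, and the
## eligibility-filtered percent-methylation-change vectors that feed
## kernel-density plots.

## gene-aligned offset of genomic positions; 5prime measures from the
## TSS-proximal end along the coding strand, 3prime from the other end
align_offset <- function(pos, gstart, gend, strand, end) {
  five <- ifelse(strand == "+", pos - gstart, gend - 1L - pos)
  if (end == "5prime") five else (gend - gstart - 1L) - five
}

new_profile <- function(df, end, bin_width, kind) {
  structure(df, class = c("meth_profile", class(df)),
            end = end, bin_width = bin_width, kind = kind)
}

## full bin grid over [0, span)
bin_grid <- function(span, bin_width) {
  tibble(offset = seq(0L, span - 1L, by = bin_width))
}

## number of genes whose body covers at least one base of each bin
genes_spanning <- function(glen, grid, bin_width) {
  vapply(grid$offset, function(o) sum(glen > o), integer(1))
}

#' Gene-aligned methylation metaprofile
#'
#' Aligns genes at their 5' or 3' ends and averages site methylation
#' (count-weighted) within fixed-width bins of distance from the
#' alignment point. Genes shorter than the profiled span contribute
#' only over their own length.
#'
#' @param sites cytosine tibble for a single sample (pool replicates
#'   first, e.g. with [pool_replicates()]).
#' @param genes exon tibble from [read_annotation()].
#' @param end alignment end, `"5prime"` or `"3prime"`.
#' @param bin_width bin width in bp (default 100).
#' @param span profiled distance from the alignment point (default
#'   3000 bp).
#' @param region_filter restrict to exonic or intronic sites.
#' @param context_filter contexts to profile (default CG).
#' @param gene_min_level,gene_max_level optional filter on the gene's
#'   overall CG methylation (e.g. methylated genes > 0.05,
#'   unmethylated < 0.005).
#' @return a `meth_profile` tibble: `offset`, `value`,
#'   `n_contributing`, `coverage` (`value` is `NA` where no site
#'   contributes).
#' @export
gene_aligned_profile <- function(sites, genes, end = c("5prime", "3prime"),
                                 bin_width = 100, span = 3000,
                                 region_filter = c("any", "exonic",
                                                   "intronic"),
                                 context_filter = "CG",
                                 gene_min_level = NULL,
                                 gene_max_level = NULL) {
  end <- match.arg(end)
  region_filter <- match.arg(region_filter)
  if (bin_width <= 0) abort("bin_width must be positive")
  if ("tissue" %in% names(sites) && dplyr::n_distinct(sites$tissue) > 1) {
    abort("profile sites must come from a single sample; filter first")
  }
  genes <- filter_genes_by_level(genes, sites, gene_min_level, gene_max_level)
  x <- dplyr::filter(sites, .data$context %in% context_filter) |>
    locate_sites(genes)
  x <- switch(region_filter,
    any = dplyr::filter(x, !is.na(.data$gene_id)),
    exonic = dplyr::filter(x, .data$region == "exonic"),
    intronic = dplyr::filter(x, .data$region == "intronic")
  )
  span_tbl <- gene_spans(genes)
  x <- dplyr::inner_join(
    x, dplyr::select(span_tbl, "gene_id", gstart = "start", gend = "end",
                     gstrand = "strand"), by = "gene_id")
  x$offset <- align_offset(x$pos, x$gstart, x$gend, x$gstrand, end)
  x <- dplyr::filter(x, .data$offset >= 0, .data$offset < span)
  x$bin <- (x$offset %/% bin_width) * bin_width
  agg <- x |>
    dplyr::group_by(offset = .data$bin) |>
    dplyr::summarise(coverage = sum(.data$n_meth + .data$n_unmeth),
                     n_meth = sum(.data$n_meth),
                     n_contributing = dplyr::n(), .groups = "drop")
  out <- bin_grid(span, bin_width) |>
    dplyr::left_join(agg, by = "offset") |>
    dplyr::mutate(
      n_contributing = dplyr::coalesce(.data$n_contributing, 0L),
      coverage = dplyr::coalesce(.data$coverage, 0L),
      value = ifelse(.data$coverage > 0, .data$n_meth / .data$coverage,
                     NA_real_)
    ) |>
    dplyr::select("offset", "value", "n_contributing", "coverage")
  new_profile(out, end, bin_width, "methylation")
}

## subset genes by their overall weighted CG methylation
filter_genes_by_level <- function(genes, sites, min_level, max_level) {
  if (is.null(min_level) && is.null(max_level)) return(genes)
  g <- aggregate_methylation(sites, genes, feature = "gene",
                             context_filter = "CG")
  keep <- g$feature_id[
    !is.na(g$level) &
      (is.null(min_level) | g$level > (min_level %||% -Inf)) &
      (is.null(max_level) | g$level < (max_level %||% Inf))
  ]
  dplyr::filter(genes, .data$gene_id %in% keep)
}

#' Splice-event frequency profile along gene bodies
#'
#' Maps alternative-splicing event intervals into gene-aligned
#' coordinates and reports, per bin and event type, the number of
#' events overlapping the bin divided by the number of genes spanning
#' it. Events not overlapping any supplied gene are skipped (their
#' count is attached as the `n_skipped` attribute, with a warning).
#'
#' @param events event coordinate tibble: `event_id`, `event_type`,
#'   `chrom`, `start`, `end` (0-based half-open); one row per event
#'   (deduplicated internally if replicate rows are passed).
#' @param genes exon tibble (pre-filtered to the gene class of
#'   interest, e.g. methylated genes).
#' @inheritParams gene_aligned_profile
#' @return `meth_profile` tibble: `event_type`, `offset`, `value`,
#'   `n_contributing`.
#' @export
event_frequency_profile <- function(events, genes, end = c("5prime", "3prime"),
                                    bin_width = 20, span = 3000) {
  end <- match.arg(end)
  if (bin_width <= 0) abort("bin_width must be positive")
  ev <- dplyr::distinct(events, .data$event_id, .data$event_type,
                        .data$chrom, .data$start, .data$end)
  span_tbl <- gene_spans(genes)
  hit <- if (nrow(ev) == 0) integer(0) else {
    ev_gr <- to_granges(dplyr::select(ev, -dplyr::any_of("strand")))
    GenomicRanges::findOverlaps(ev_gr, to_granges(span_tbl),
                                ignore.strand = TRUE, select = "first")
  }
  n_skipped <- sum(is.na(hit))
  if (n_skipped > 0) {
    warn(sprintf("%d event(s) overlap no annotated gene; skipped", n_skipped))
  }
  ev <- ev[!is.na(hit), , drop = FALSE]
  g <- span_tbl[hit[!is.na(hit)], ]
  ## event interval in aligned coordinates (ends may swap on reflection)
  o1 <- align_offset(ev$start, g$start, g$end, g$strand, end)
  o2 <- align_offset(ev$end - 1L, g$start, g$end, g$strand, end)
  lo <- pmax(pmin(o1, o2), 0L)
  hi <- pmin(pmax(o1, o2), span - 1L)
  keep <- lo <= hi
  ev <- ev[keep, , drop = FALSE]; lo <- lo[keep]; hi <- hi[keep]

  grid <- bin_grid(span, bin_width)
  denom <- genes_spanning(span_tbl$end - span_tbl$start, grid, bin_width)
  types <- unique(events$event_type)
  if (length(types) == 0) types <- NA_character_   # zero profile, no events
  out <- purrr::map_dfr(types, function(ty) {
    sel <- !is.na(ty) & ev$event_type %in% ty
    counts <- vapply(grid$offset, function(o) {
      sum(sel & lo < o + bin_width & hi >= o)
    }, integer(1))
    tibble(event_type = ty, offset = grid$offset,
           n_contributing = counts,
           value = ifelse(denom > 0, counts / denom, NA_real_))
  })
  out <- new_profile(out, end, bin_width, "event_frequency")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Frequency profiles of highly and lowly methylated CG sites
#'
#' Classifies sites of a single sample by fractional methylation —
#' high (>= `high_cutoff`) vs low (strictly inside `low_band`) — and
#' profiles each class's per-bin site count normalised by the number
#' of genes spanning the bin.
#'
#' @param sites single-sample cytosine tibble (CG context rows used).
#' @param genes exon tibble (pre-filtered to the gene class of
#'   interest).
#' @param high_cutoff inclusive lower bound of the high class
#'   (default 0.8).
#' @param low_band exclusive bounds of the low class (default
#'   (0.05, 0.8)).
#' @inheritParams gene_aligned_profile
#' @return `meth_profile` tibble: `site_class`, `offset`, `value`,
#'   `n_contributing`.
#' @export
site_class_profile <- function(sites, genes, high_cutoff = 0.8,
                               low_band = c(0.05, 0.8),
                               end = c("5prime", "3prime"),
                               bin_width = 20, span = 3000) {
  end <- match.arg(end)
  if (low_band[2] > high_cutoff) {
    abort("low_band overlaps the high class; classes must be disjoint")
  }
  x <- dplyr::filter(sites, .data$context == "CG") |>
    dplyr::mutate(frac = ifelse(.data$n_meth + .data$n_unmeth > 0,
                                .data$n_meth /
                                  (.data$n_meth + .data$n_unmeth),
                                NA_real_),
                  site_class = dplyr::case_when(
                    is.na(.data$frac) ~ NA_character_,
                    .data$frac >= high_cutoff ~ "high",
                    .data$frac > low_band[1] & .data$frac < low_band[2] ~
                      "low",
                    TRUE ~ NA_character_
                  )) |>
    dplyr::filter(!is.na(.data$site_class)) |>
    locate_sites(genes) |>
    dplyr::filter(!is.na(.data$gene_id))
  span_tbl <- gene_spans(genes)
  x <- dplyr::inner_join(
    x, dplyr::select(span_tbl, "gene_id", gstart = "start", gend = "end",
                     gstrand = "strand"), by = "gene_id")
  x$offset <- align_offset(x$pos, x$gstart, x$gend, x$gstrand, end)
  x <- dplyr::filter(x, .data$offset >= 0, .data$offset < span)
  x$bin <- (x$offset %/% bin_width) * bin_width
  grid <- bin_grid(span, bin_width)
  denom <- genes_spanning(span_tbl$end - span_tbl$start, grid, bin_width)
  out <- purrr::map_dfr(c("high", "low"), function(cl) {
    counts <- x |>
      dplyr::filter(.data$site_class == cl) |>
      dplyr::count(offset = .data$bin, name = "n_contributing")
    grid |>
      dplyr::left_join(counts, by = "offset") |>
      dplyr::mutate(site_class = cl,
                    n_contributing = dplyr::coalesce(.data$n_contributing,
                                                     0L),
                    value = ifelse(denom > 0, .data$n_contributing / denom,
                                   NA_real_)) |>
      dplyr::select("site_class", "offset", "value", "n_contributing")
  })
  new_profile(out, end, bin_width, "site_class_frequency")
}

#' Eligible percent-methylation-change vector for density plots
#'
#' Joins two samples of a pooled count table and returns the signed
#' percent-methylation-change of every feature passing the
#' kernel-density eligibility rules: at least 10 (sites) or 20
#' (exons/genes) informative sequenced cytosines in each sample, and a
#' fractional methylation of at least `min_level` in at least one.
#'
#' @param counts count tibble from [aggregate_counts()] with a
#'   `tissue` column; replicates, if present, are pooled by count
#'   summation.
#' @param pair the two sample labels, `c(sample_a, sample_b)`.
#' @param resolution `"site"`, `"exon"` or `"gene"` (sets the
#'   informative-cytosine threshold).
#' @param min_level minimum level in at least one sample (default 0.1).
#' @return tibble `feature_id`, `level_a`, `level_b`, `pmc`.
#' @export
change_density_inputs <- function(counts, pair,
                                  resolution = c("site", "exon", "gene"),
                                  min_level = 0.1) {
  resolution <- match.arg(resolution)
  min_informative <- if (resolution == "site") 10 else 20
  pooled <- if ("replicate" %in% names(counts)) pool_replicates(counts) else
    dplyr::mutate(counts,
                  informative = .data$n_meth + .data$n_unmeth,
                  level = ifelse(.data$n_meth + .data$n_unmeth > 0,
                                 .data$n_meth /
                                   (.data$n_meth + .data$n_unmeth),
                                 NA_real_))
  a <- dplyr::filter(pooled, .data$tissue == pair[1])
  b <- dplyr::filter(pooled, .data$tissue == pair[2])
  dplyr::inner_join(
    dplyr::select(a, "feature_id", level_a = "level",
                  informative_a = "informative"),
    dplyr::select(b, "feature_id", level_b = "level",
                  informative_b = "informative"),
    by = "feature_id"
  ) |>
    dplyr::filter(.data$informative_a >= min_informative,
                  .data$informative_b >= min_informative,
                  dplyr::coalesce(.data$level_a, 0) >= min_level |
                    dplyr::coalesce(.data$level_b, 0) >= min_level) |>
    dplyr::mutate(pmc = percent_methylation_change(.data$level_a,
                                                   .data$level_b)) |>
    dplyr::select("feature_id", "level_a", "level_b", "pmc")
}
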