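## Core methylation statistics: weighted aggregation at site / exon /
## gene resolution, the two-sided Fisher exact test on methylated vs
## unmethylated counts, the signed percent-methylation-change statistic,
## differential calling with biological-replicate concordance, and
## state binning of exons and single reads.

#' Aggregate cytosine counts into a feature methylation matrix
#'
#' Computes the weighted methylation level of each feature — summed
#' methylated counts over summed total counts of the contributing sites
#' (count-weighted, never a mean of per-site fractions) — together with
#' the number of informative cytosines (total sequenced coverage) and
#' distinct sites. Grouping columns present in `sites` (`tissue`,
#' `replicate`) are preserved, so one call aggregates a whole
#' multi-sample table.
#'
#' @param sites cytosine tibble (see [read_cx_table()]), optionally with
#'   `tissue` / `replicate` columns.
#' @param genes exon tibble from [read_annotation()].
#' @param feature `"exon"`, `"gene"` or `"site"` resolution.
#' @param context_filter contexts to keep (default CG).
#' @param region_filter for gene (and site) resolution: restrict to
#'   sites in exons, introns, or anywhere within the gene span.
#' @return tibble: `feature_id`, grouping columns, `level` (`NA` where
#'   no informative cytosines), `informative`, `n_sites`.
#' @export
aggregate_methylation <- function(sites, genes,
                                  feature = c("exon", "gene", "site"),
                                  context_filter = "CG",
                                  region_filter = c("any", "exonic",
                                                    "intronic")) {
  feature <- match.arg(feature)
  region_filter <- match.arg(region_filter)
  if (nrow(genes) == 0 && feature != "site") abort("empty feature set")
  bad <- setdiff(context_filter, VALID_CONTEXTS)
  if (length(bad)) {
    abort(sprintf("unknown context in filter: %s", paste(bad, collapse = ", ")))
  }
  grp <- group_cols_present(sites)
  x <- dplyr::filter(sites, .data$context %in% context_filter)

  if (feature == "site") {
    out <- x |>
      dplyr::mutate(feature_id = paste0(.data$chrom, ":", .data$pos, ":",
                                        .data$strand),
                    informative = .data$n_meth + .data$n_unmeth,
                    level = ifelse(.data$informative > 0,
                                   .data$n_meth / .data$informative, NA_real_),
                    n_sites = 1L) |>
      dplyr::select(dplyr::all_of(c("feature_id", grp, "level",
                                    "informative", "n_sites")))
    return(out)
  }

  located <- locate_sites(x, genes)
  located <- switch(region_filter,
    any = dplyr::filter(located, !is.na(.data$gene_id)),
    exonic = dplyr::filter(located, .data$region == "exonic"),
    intronic = dplyr::filter(located, .data$region == "intronic")
  )
  id_col <- if (feature == "exon") "exon_id" else "gene_id"
  if (feature == "exon") located <- dplyr::filter(located, !is.na(.data$exon_id))

  agg <- located |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(id_col, grp)))) |>
    dplyr::summarise(
      n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
      n_sites = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      informative = .data$n_meth + .data$n_unmeth,
      level = ifelse(.data$informative > 0,
                     .data$n_meth / .data$informative, NA_real_)
    ) |>
    dplyr::rename(feature_id = dplyr::all_of(id_col)) |>
    dplyr::select(dplyr::all_of(c("feature_id", grp, "level", "informative",
                                  "n_sites")))
  agg
}

#' Aggregate raw counts per feature (for testing-level statistics)
#'
#' Like [aggregate_methylation()] but keeps the summed methylated /
#' unmethylated counts, which the Fisher test consumes.
#'
#' @inheritParams aggregate_methylation
#' @return tibble `feature_id`, grouping columns, `n_meth`, `n_unmeth`.
#' @export
aggregate_counts <- function(sites, genes,
                             feature = c("exon", "gene", "site"),
                             context_filter = "CG",
                             region_filter = c("any", "exonic", "intronic")) {
  feature <- match.arg(feature)
  region_filter <- match.arg(region_filter)
  grp <- group_cols_present(sites)
  x <- dplyr::filter(sites, .data$context %in% context_filter)
  if (feature == "site") {
    return(x |>
      dplyr::mutate(feature_id = paste0(.data$chrom, ":", .data$pos, ":",
                                        .data$strand)) |>
      dplyr::select(dplyr::all_of(c("feature_id", grp, "n_meth",
                                    "n_unmeth"))))
  }
  located <- locate_sites(x, genes)
  located <- switch(region_filter,
    any = dplyr::filter(located, !is.na(.data$gene_id)),
    exonic = dplyr::filter(located, .data$region == "exonic"),
    intronic = dplyr::filter(located, .data$region == "intronic")
  )
  id_col <- if (feature == "exon") "exon_id" else "gene_id"
  if (feature == "exon") located <- dplyr::filter(located, !is.na(.data$exon_id))
  located |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(id_col, grp)))) |>
    dplyr::summarise(n_meth = sum(.data$n_meth),
                     n_unmeth = sum(.data$n_unmeth), .groups = "drop") |>
    dplyr::rename(feature_id = dplyr::all_of(id_col))
}

#' Signed percent-methylation-change
#'
#' The difference between two methylation levels divided by the larger
#' level, as a signed percent: positive when the first sample is the
#' more methylated one. `pmc(a, b) = 100 (a - b) / a` when `a > b`,
#' `-100 (b - a) / b` when `b > a`, and 0 when equal (including the
#' 0/0 case, where no change is the only consistent reading). Missing
#' inputs propagate as `NA`.
#'
#' @param m_a,m_b methylation fractions in `[0, 1]` (vectorised).
#' @return signed percents in `[-100, 100]`.
#' @export
percent_methylation_change <- function(m_a, m_b) {
  stopifnot(length(m_a) == length(m_b))
  out <- rep(NA_real_, length(m_a))
  ok <- !is.na(m_a) & !is.na(m_b)
  a <- m_a[ok]; b <- m_b[ok]
  r <- numeric(length(a))
  up <- a > b
  dn <- b > a
  ## divide before scaling so a full loss is exactly +/-100
  r[up] <- 100 * ((a[up] - b[up]) / a[up])
  r[dn] <- -100 * ((b[dn] - a[dn]) / b[dn])
  out[ok] <- r
  out
}

#' Two-sided Fisher exact test on 2x2 count tables (vectorised)
#'
#' Tests association in tables `(n_meth, n_unmeth)` x sample. The
#' two-sided p-value sums the hypergeometric probabilities of all
#' tables with the observed margins whose point probability does not
#' exceed the observed one (with the standard `1 + 1e-7` relative
#' tolerance for floating-point ties).
#'
#' @param a,b methylated / unmethylated counts in sample 1.
#' @param c,d methylated / unmethylated counts in sample 2.
#' @return p-values in `[0, 1]`; degenerate tables (an empty margin)
#'   give p = 1.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(a) == length(c),
            length(a) == length(d))
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) abort("negative counts")
  vapply(seq_along(a), function(i) {
    if (anyNA(c(a[i], b[i], c[i], d[i]))) return(NA_real_)
    m <- a[i] + c[i]          # methylated margin
    n <- b[i] + d[i]          # unmethylated margin
    k <- a[i] + b[i]          # sample-1 margin
    if (m == 0 || n == 0 || k == 0 || c[i] + d[i] == 0) return(1)
    lo <- max(0, k - n); hi <- min(k, m)
    dens <- dhyper(lo:hi, m, n, k)
    p <- sum(dens[dens <= dens[a[i] - lo + 1] * (1 + 1e-7)])
    min(p, 1)
  }, numeric(1))
}

#' Call differential methylation between two samples
#'
#' Runs the Fisher exact test on each biological replicate separately
#' and requires `p < alpha` in every replicate (replicate concordance);
#' the signed percent-methylation-change is computed on the
#' replicate-pooled counts. Eligibility follows the kernel-density
#' rules: at least `min_informative` sequenced cytosines in each
#' sample (pooled) and a fractional methylation of at least `min_level`
#' in at least one sample. Differential features with
#' `|pmc| >= pmc_full_cutoff` are classified `"full"`, the rest
#' `"partial"`.
#'
#' @param counts long count tibble from [aggregate_counts()]:
#'   `feature_id`, `tissue`, `replicate`, `n_meth`, `n_unmeth`.
#' @param pair character vector of the two sample (tissue) labels to
#'   compare, `c(sample_a, sample_b)`.
#' @param alpha per-replicate significance level. The analyses use
#'   0.001 at site resolution and 0.05 at exon/gene resolution.
#' @param min_level minimum fractional methylation in at least one
#'   sample (default 0.1).
#' @param min_informative minimum pooled informative cytosines per
#'   sample (10 for sites, 20 for exons/genes).
#' @param pmc_full_cutoff |pmc| at or above which a differential
#'   feature is a full (vs partial) change (default 90).
#' @param p_adjust optional Benjamini-Hochberg correction of the
#'   per-replicate p-values across features (off by default; the
#'   replicate-concordance rule is the primary error control).
#' @return a tibble of class `"dm_calls"`: `feature_id`, `sample_a`,
#'   `sample_b`, per-replicate p-values (`p_rep1`, `p_rep2`, ...),
#'   pooled levels and informative counts, `pmc`, `eligible`, `is_dm`,
#'   `dm_class` (`"none"`, `"partial"`, `"full"`).
#' @export
call_differential_methylation <- function(counts, pair, alpha = 0.001,
                                          min_level = 0.1,
                                          min_informative = 10,
                                          pmc_full_cutoff = 90,
                                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  assert_cols(counts, c("feature_id", "tissue", "replicate", "n_meth",
                        "n_unmeth"), "counts")
  stopifnot(length(pair) == 2)
  x <- dplyr::filter(counts, .data$tissue %in% pair)
  reps <- sort(unique(x$replicate))
  if (length(reps) < 1) abort("no replicates found for the requested pair")

  wide <- x |>
    dplyr::mutate(side = ifelse(.data$tissue == pair[1], "a", "b")) |>
    tidyr::pivot_wider(
      id_cols = "feature_id", names_from = c("side", "replicate"),
      values_from = c("n_meth", "n_unmeth"), values_fill = 0L,
      names_glue = "{.value}_{side}{replicate}"
    )
  need <- as.vector(outer(c("n_meth", "n_unmeth"),
                          as.vector(outer(c("a", "b"), reps, paste0)),
                          paste, sep = "_"))
  for (col in setdiff(need, names(wide))) wide[[col]] <- 0L

  p_mat <- sapply(reps, function(r) {
    fisher_exact_2x2(wide[[paste0("n_meth_a", r)]],
                     wide[[paste0("n_unmeth_a", r)]],
                     wide[[paste0("n_meth_b", r)]],
                     wide[[paste0("n_unmeth_b", r)]])
  })
  if (is.null(dim(p_mat))) p_mat <- matrix(p_mat, ncol = length(reps))
  if (p_adjust == "BH") p_mat <- apply(p_mat, 2, p.adjust, method = "BH")

  sum_cols <- function(prefix, side) {
    Reduce(`+`, lapply(reps, function(r) wide[[paste0(prefix, side, r)]]))
  }
  meth_a <- sum_cols("n_meth_", "a"); unmeth_a <- sum_cols("n_unmeth_", "a")
  meth_b <- sum_cols("n_meth_", "b"); unmeth_b <- sum_cols("n_unmeth_", "b")
  inf_a <- meth_a + unmeth_a; inf_b <- meth_b + unmeth_b
  level_a <- ifelse(inf_a > 0, meth_a / inf_a, NA_real_)
  level_b <- ifelse(inf_b > 0, meth_b / inf_b, NA_real_)

  eligible <- inf_a >= min_informative & inf_b >= min_informative &
    (dplyr::coalesce(level_a, 0) >= min_level |
     dplyr::coalesce(level_b, 0) >= min_level)
  pmc <- percent_methylation_change(level_a, level_b)
  concordant <- apply(p_mat < alpha, 1, all)
  is_dm <- eligible & dplyr::coalesce(concordant, FALSE)
  dm_class <- dplyr::case_when(
    !is_dm ~ "none",
    abs(pmc) >= pmc_full_cutoff ~ "full",
    TRUE ~ "partial"
  )

  out <- tibble(
    feature_id = wide$feature_id, sample_a = pair[1], sample_b = pair[2]
  )
  for (j in seq_along(reps)) out[[paste0("p_rep", reps[j])]] <- p_mat[, j]
  out <- dplyr::bind_cols(out, tibble(
    level_a = level_a, level_b = level_b,
    informative_a = inf_a, informative_b = inf_b,
    pmc = pmc, eligible = eligible, is_dm = is_dm, dm_class = dm_class
  ))
  class(out) <- c("dm_calls", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "pmc_full_cutoff") <- pmc_full_cutoff
  out
}

#' Bin exons into methylation states
#'
#' Restricts to exons methylated to at least `min_level` with at least
#' `min_informative` informative cytosines in at least one of the given
#' samples, then bins each eligible exon per sample into
#' `unmethylated` (level < 0.1), `intermediate` (0.1 <= level <= 0.9)
#' or `full` (level > 0.9).
#'
#' @param m methylation matrix from [aggregate_methylation()] with a
#'   `tissue` column (replicates should be pooled upstream or the bins
#'   are per replicate).
#' @param samples samples used both for eligibility and binning
#'   (default: all present).
#' @param min_level,min_informative eligibility thresholds (defaults
#'   0.34 and 4).
#' @return tibble `feature_id`, `tissue`, `level`, `state`; empty (with
#'   a warning) when no exon is eligible.
#' @export
classify_exon_states <- function(m, samples = unique(m$tissue),
                                 min_level = 0.34, min_informative = 4) {
  assert_cols(m, c("feature_id", "tissue", "level", "informative"), "m")
  x <- dplyr::filter(m, .data$tissue %in% samples)
  eligible <- x |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(ok = any(!is.na(.data$level) & .data$level >= min_level &
                                .data$informative >= min_informative),
                     .groups = "drop") |>
    dplyr::filter(.data$ok)
  if (nrow(eligible) == 0) {
    warn("no exons pass the state-binning eligibility rule")
    return(tibble(feature_id = character(), tissue = character(),
                  level = numeric(), state = character()))
  }
  x |>
    dplyr::semi_join(eligible, by = "feature_id") |>
    dplyr::filter(!is.na(.data$level)) |>
    dplyr::mutate(state = dplyr::case_when(
      .data$level < 0.1 ~ "unmethylated",
      .data$level <= 0.9 ~ "intermediate",
      TRUE ~ "full"
    )) |>
    dplyr::select("feature_id", "tissue", "level", "state")
}

#' State proportions from binned exons
#'
#' @param states output of [classify_exon_states()].
#' @return tibble `tissue`, `state`, `n`, `proportion` (proportions sum
#'   to 1 within each sample).
#' @export
state_proportions <- function(states) {
  states |>
    dplyr::mutate(state = factor(.data$state,
                                 c("unmethylated", "intermediate", "full"))) |>
    dplyr::count(.data$tissue, .data$state, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Classify single bisulfite reads by epiallele state
#'
#' Groups reads by the CG count of their exon (1, 2 or 3 CGs) and
#' classifies each read as `fully` methylated (all states M),
#' `unmethylated` (all U) or `partially` methylated (a mixture; only
#' possible with 2+ CGs). Proportions sum to 1 within each group.
#'
#' @param records read-level tibble (`read_id`, `feature_id`, `states`,
#'   optionally `tissue`).
#' @param max_cg keep reads covering at most this many CGs (default 3).
#' @return tibble: grouping columns, `cg_count`, `read_class`, `n`,
#'   `proportion`.
#' @export
classify_reads <- function(records, max_cg = 3) {
  assert_cols(records, c("read_id", "feature_id", "states"), "records")
  grp <- intersect("tissue", names(records))
  x <- records |>
    dplyr::mutate(
      n_m = stringr::str_count(.data$states, stringr::fixed("M")),
      cg_count = stringr::str_count(.data$states,
                                    stringr::fixed(",")) + 1L,
      read_class = dplyr::case_when(
        .data$n_m == .data$cg_count ~ "fully",
        .data$n_m == 0L ~ "unmethylated",
        TRUE ~ "partially"
      )
    ) |>
    dplyr::filter(.data$cg_count <= max_cg)
  x |>
    dplyr::mutate(read_class = factor(.data$read_class,
                                      c("fully", "partially",
                                        "unmethylated"))) |>
    dplyr::count(dplyr::across(dplyr::all_of(c(grp, "cg_count",
                                               "read_class"))),
                 .drop = FALSE, name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "cg_count")))) |>
    dplyr::mutate(proportion = {
      s <- sum(.data$n)
      if (s > 0) .data$n / s else rep(NA_real_, dplyr::n())
    }) |>
    dplyr::ungroup()
}

#' Count experiment-specific vs tissue-specific methylated exons
#'
#' For two tissues assayed in two experiments each, an exon is
#' "methylated" in a column when its level is at or above `threshold`.
#' A tissue-specific exon is methylated in both experiments of exactly
#' one tissue and in neither experiment of the other; an
#' experiment-specific exon is methylated in both tissues of exactly
#' one experiment and in neither tissue of the other.
#'
#' @param m methylation matrix with `feature_id`, `tissue`,
#'   `replicate`, `level` (replicate = experiment).
#' @param tissue_a,tissue_b the two tissues to compare.
#' @param threshold methylated-call threshold on the level (default
#'   0.1).
#' @return tibble `category` (`experiment_specific`,
#'   `tissue_specific`), `n`.
#' @export
experiment_vs_tissue_counts <- function(m, tissue_a, tissue_b,
                                        threshold = 0.1) {
  assert_cols(m, c("feature_id", "tissue", "replicate", "level"), "m")
  x <- dplyr::filter(m, .data$tissue %in% c(tissue_a, tissue_b))
  reps <- sort(unique(x$replicate))
  if (length(reps) != 2) abort("exactly two experiments (replicates) required")
  wide <- x |>
    dplyr::mutate(meth = !is.na(.data$level) & .data$level >= threshold) |>
    tidyr::pivot_wider(id_cols = "feature_id",
                       names_from = c("tissue", "replicate"),
                       values_from = "meth",
                       names_glue = "{tissue}_e{replicate}")
  need <- as.vector(outer(c(tissue_a, tissue_b), reps,
                          function(t, r) sprintf("%s_e%s", t, r)))
  if (!all(need %in% names(wide))) {
    abort("missing tissue x experiment columns for the comparison")
  }
  a1 <- dplyr::coalesce(wide[[sprintf("%s_e%s", tissue_a, reps[1])]], FALSE)
  a2 <- dplyr::coalesce(wide[[sprintf("%s_e%s", tissue_a, reps[2])]], FALSE)
  b1 <- dplyr::coalesce(wide[[sprintf("%s_e%s", tissue_b, reps[1])]], FALSE)
  b2 <- dplyr::coalesce(wide[[sprintf("%s_e%s", tissue_b, reps[2])]], FALSE)
  tissue_specific <- (a1 & a2 & !b1 & !b2) | (b1 & b2 & !a1 & !a2)
  experiment_specific <- (a1 & b1 & !a2 & !b2) | (a2 & b2 & !a1 & !b1)
  tibble(
    category = c("experiment_specific", "tissue_specific"),
    n = c(sum(experiment_specific), sum(tissue_specific))
  )
}

#' Pool replicates of a count or methylation table
#'
#' Sums methylated / unmethylated counts over replicates (the combined
#' estimate used for levels and pmc; tests stay per replicate).
#'
#' @param counts tibble with `feature_id`, `tissue`, `replicate`,
#'   `n_meth`, `n_unmeth` (site tables with `chrom`/`pos`/`strand` also
#'   work: all non-replicate columns are kept as keys).
#' @return tibble without the `replicate` column, counts summed, plus
#'   `level` and `informative`.
#' @export
pool_replicates <- function(counts) {
  keys <- setdiff(names(counts), c("replicate", "n_meth", "n_unmeth"))
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_meth = sum(.data$n_meth),
                     n_unmeth = sum(.data$n_unmeth), .groups = "drop") |>
    dplyr::mutate(informative = .data$n_meth + .data$n_unmeth,
                  level = ifelse(.data$informative > 0,
                                 .data$n_meth / .data$informative, NA_real_))
}
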