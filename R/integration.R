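## Expression and splicing integration: gene responsiveness, set
## overlap representation factors with exact hypergeometric tails,
## methylation-change vs expression-change correlation, differential
## percent-spliced-in calling, and sample-structure summaries
## (pairwise correlation, PCA, average-linkage clustering).

#' Gene responsiveness scores
#'
#' Counts, per gene, the pairwise stage comparisons in which it is
#' differentially expressed. With seven developmental stages there are
#' 21 pairwise comparisons, so scores range from 0 (constitutive) to
#' 21 (differential in every pair).
#'
#' @param de_calls long tibble `gene_id`, `sample_a`, `sample_b`,
#'   `is_de` (e.g. from [read_de_calls()]). Each unordered pair may
#'   appear at most once per gene.
#' @return tibble `gene_id`, `responsiveness`.
#' @export
gene_responsiveness <- function(de_calls) {
  assert_cols(de_calls, c("gene_id", "sample_a", "sample_b", "is_de"),
              "de_calls")
  key <- paste(pmin(de_calls$sample_a, de_calls$sample_b),
               pmax(de_calls$sample_a, de_calls$sample_b))
  if (anyDuplicated(data.frame(g = de_calls$gene_id, k = key))) {
    abort("duplicated sample-pair rows per gene")
  }
  de_calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(responsiveness = sum(.data$is_de, na.rm = TRUE),
                     .groups = "drop")
}

#' Representation factor of a two-set overlap
#'
#' For gene sets A and B inside a universe U, the expected overlap
#' under independence is `|A| |B| / |U|` and the representation factor
#' is observed/expected (< 1 means under-representation). Enrichment
#' and depletion p-values are exact hypergeometric tails
#' (`P[X >= observed]` and `P[X <= observed]`).
#'
#' @param set_a,set_b character vectors of feature ids; must be subsets
#'   of `universe`.
#' @param universe character vector of all eligible ids.
#' @return one-row tibble of class `"overlap_result"`: `n_universe`,
#'   `n_a`, `n_b`, `n_observed`, `expected`,
#'   `representation_factor`, `p_enrich`, `p_deplete`.
#' @export
overlap_representation <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    abort("set_a and set_b must be subsets of the universe")
  }
  n_u <- length(universe); n_a <- length(set_a); n_b <- length(set_b)
  obs <- length(intersect(set_a, set_b))
  expected <- n_a * n_b / n_u
  out <- tibble(
    n_universe = n_u, n_a = n_a, n_b = n_b, n_observed = obs,
    expected = expected,
    representation_factor = ifelse(expected > 0, obs / expected, NA_real_),
    p_enrich = phyper(obs - 1, n_a, n_u - n_a, n_b, lower.tail = FALSE),
    p_deplete = phyper(obs, n_a, n_u - n_a, n_b)
  )
  class(out) <- c("overlap_result", class(out))
  out
}

#' Correlate methylation change with expression change
#'
#' Pearson correlation between gene-level percent-methylation-change
#' and expression log fold change over paired, non-missing genes,
#' optionally restricted to a subset (e.g. genes both differentially
#' methylated and differentially expressed).
#'
#' @param changes tibble `feature_id` (gene), `pmc`.
#' @param logfc tibble `gene_id`, `logfc`.
#' @param subset optional character vector of gene ids to restrict to.
#' @return one-row tibble `r`, `n`, `p_value`; `r` is `NA` with a
#'   warning when fewer than 3 pairs remain or an input is constant.
#' @export
change_expression_correlation <- function(changes, logfc, subset = NULL) {
  x <- dplyr::inner_join(
    dplyr::select(changes, gene_id = "feature_id", "pmc"),
    dplyr::select(logfc, "gene_id", "logfc"), by = "gene_id") |>
    dplyr::filter(!is.na(.data$pmc), !is.na(.data$logfc))
  if (!is.null(subset)) x <- dplyr::filter(x, .data$gene_id %in% subset)
  if (nrow(x) < 3) {
    warn("fewer than 3 paired observations; correlation undefined")
    return(tibble(r = NA_real_, n = nrow(x), p_value = NA_real_))
  }
  if (sd(x$pmc) == 0 || sd(x$logfc) == 0) {
    warn("constant input vector; correlation undefined")
    return(tibble(r = NA_real_, n = nrow(x), p_value = NA_real_))
  }
  ct <- cor.test(x$pmc, x$logfc, method = "pearson")
  tibble(r = unname(ct$estimate), n = nrow(x), p_value = ct$p.value)
}

#' Call differential splicing from replicate PSI values
#'
#' Per event, computes the mean percent-spliced-in difference between
#' two samples across replicates and tests it with a two-sample t-test
#' on the replicate PSI values (pooled-variance Student t by default:
#' with two replicates per side the Welch degrees of freedom collapse
#' and the test has almost no power; Welch and an exact permutation
#' test are available). p-values are Benjamini-Hochberg corrected
#' across events; an event is differentially spliced when
#' `|delta PSI| >= min_dpsi` and `q < alpha`. Events missing PSI in
#' any replicate of either sample are dropped (count reported in the
#' `n_dropped` attribute).
#'
#' @param psi long PSI tibble (see [read_psi()]).
#' @param pair the two sample labels, `c(sample_a, sample_b)`.
#' @param min_dpsi minimum |delta PSI| (default 0.1).
#' @param alpha q-value threshold (default 0.05).
#' @param method `"student"` (pooled variance, default), `"welch"`, or
#'   `"permutation"` (exact, all within-margin relabellings).
#' @return tibble of class `"dse_calls"`: `event_id`, `event_type`,
#'   `dpsi` (mean sample_b minus sample_a), `p_value`, `q_value`,
#'   `is_dse`.
#' @export
call_dse <- function(psi, pair, min_dpsi = 0.1, alpha = 0.05,
                     method = c("student", "welch", "permutation")) {
  method <- match.arg(method)
  assert_cols(psi, c("event_id", "sample", "replicate", "psi"), "psi")
  x <- dplyr::filter(psi, .data$sample %in% pair)
  complete <- x |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      ok = sum(!is.na(.data$psi) & .data$sample == pair[1]) >= 2 &
        sum(!is.na(.data$psi) & .data$sample == pair[2]) >= 2 &
        !anyNA(.data$psi),
      .groups = "drop")
  n_dropped <- sum(!complete$ok)
  if (n_dropped > 0) {
    inform(sprintf("%d event(s) dropped for missing replicate PSI",
                   n_dropped))
  }
  x <- dplyr::semi_join(x, dplyr::filter(complete, .data$ok), by = "event_id")
  types <- if ("event_type" %in% names(psi)) {
    dplyr::distinct(psi, .data$event_id, .data$event_type)
  } else NULL

  stats_tbl <- x |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      dpsi = mean(.data$psi[.data$sample == pair[2]]) -
        mean(.data$psi[.data$sample == pair[1]]),
      p_value = psi_test_p(.data$psi[.data$sample == pair[1]],
                           .data$psi[.data$sample == pair[2]], method),
      .groups = "drop"
    ) |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, method = "BH"),
                  is_dse = abs(.data$dpsi) >= min_dpsi &
                    .data$q_value < alpha)
  if (!is.null(types)) {
    stats_tbl <- dplyr::left_join(stats_tbl, types, by = "event_id") |>
      dplyr::relocate("event_type", .after = "event_id")
  }
  class(stats_tbl) <- c("dse_calls", class(stats_tbl))
  attr(stats_tbl, "n_dropped") <- n_dropped
  stats_tbl
}

psi_test_p <- function(a, b, method) {
  if (method == "permutation") {
    obs <- abs(mean(b) - mean(a))
    pool <- c(a, b)
    idx <- utils::combn(length(pool), length(a))
    ds <- apply(idx, 2, function(i) {
      abs(mean(pool[-i]) - mean(pool[i]))
    })
    return(mean(ds >= obs - 1e-12))
  }
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(t.test(a, b, var.equal = (method == "student"))$p.value,
           error = function(e) NA_real_)
}

#' Sample-structure summary of a methylation matrix
#'
#' Builds the feature x (sample, replicate) matrix of methylation
#' levels, drops features with any missing value (count reported), and
#' returns pairwise Pearson correlations, PCA coordinates of the
#' columns (centred), and an average-linkage dendrogram on the
#' Euclidean distance matrix.
#'
#' @param m methylation matrix tibble with `feature_id`, `tissue`,
#'   `replicate`, `level` (e.g. methylated-exon levels).
#' @return list of class `"sample_structure"`: `correlations` (long
#'   tibble), `pca` (tibble of column scores with variance-explained
#'   attribute), `hclust`, `n_features`, `n_dropped`.
#' @export
sample_structure <- function(m) {
  assert_cols(m, c("feature_id", "tissue", "replicate", "level"), "m")
  wide <- tidyr::pivot_wider(m, id_cols = "feature_id",
                             names_from = c("tissue", "replicate"),
                             values_from = "level",
                             names_glue = "{tissue}_rep{replicate}")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$feature_id
  keep <- complete.cases(mat)
  n_dropped <- sum(!keep)
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2) abort("fewer than 2 complete-case features")

  cors <- cor(mat, method = "pearson")
  cor_tbl <- as_tibble(as.table(cors), .name_repair = "minimal")
  names(cor_tbl) <- c("column_a", "column_b", "r")

  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  pca_tbl <- as_tibble(pc$x, rownames = "column")
  attr(pca_tbl, "variance_explained") <- pc$sdev^2 / sum(pc$sdev^2)

  hc <- hclust(dist(t(mat), method = "euclidean"), method = "average")

  structure(
    list(correlations = cor_tbl, pca = pca_tbl, hclust = hc,
         n_features = nrow(mat), n_dropped = n_dropped),
    class = "sample_structure"
  )
}

#' @export
print.sample_structure <- function(x, ...) {
  cat(sprintf("sample_structure: %d complete-case features (%d dropped)\n",
              x$n_features, x$n_dropped))
  ve <- attr(x$pca, "variance_explained")
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * ve[1], 100 * ve[2] %na% 0))
  cat("columns:", paste(x$pca$column, collapse = ", "), "\n")
  invisible(x)
}
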