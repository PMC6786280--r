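## broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy differential-methylation calls
#'
#' @param x a `dm_calls` tibble from
#'   [call_differential_methylation()].
#' @param ... unused.
#' @return a plain tibble of the call columns.
#' @method tidy dm_calls
#' @export
tidy.dm_calls <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Summarise differential-methylation calls
#'
#' @inheritParams tidy.dm_calls
#' @return one-row tibble: features tested/eligible, DM counts split
#'   into partial and full, and the median |pmc| of differential
#'   features.
#' @method glance dm_calls
#' @export
glance.dm_calls <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_eligible = sum(x$eligible, na.rm = TRUE),
    n_dm = sum(x$is_dm, na.rm = TRUE),
    n_partial = sum(x$dm_class == "partial"),
    n_full = sum(x$dm_class == "full"),
    median_abs_pmc_dm = median(abs(x$pmc[x$is_dm]), na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}

#' Tidy an overlap representation result
#'
#' @param x an `overlap_result` from [overlap_representation()].
#' @param ... unused.
#' @return a plain tibble.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) as_tibble(unclass(x))

#' @rdname tidy.overlap_result
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  dplyr::select(as_tibble(unclass(x)), "representation_factor",
                "p_enrich", "p_deplete")
}

#' Tidy a sample-structure summary
#'
#' @param x a `sample_structure` from [sample_structure()].
#' @param ... unused.
#' @return PCA coordinates of the sample columns, one row per column.
#' @method tidy sample_structure
#' @export
tidy.sample_structure <- function(x, ...) x$pca

#' @rdname tidy.sample_structure
#' @method glance sample_structure
#' @export
glance.sample_structure <- function(x, ...) {
  ve <- attr(x$pca, "variance_explained")
  tibble(n_features = x$n_features, n_dropped = x$n_dropped,
         pc1_var = ve[1], pc2_var = if (length(ve) > 1) ve[2] else NA_real_)
}

#' Tidy differential-splicing calls
#'
#' @param x a `dse_calls` tibble from [call_dse()].
#' @param ... unused.
#' @return a plain tibble.
#' @method tidy dse_calls
#' @export
tidy.dse_calls <- function(x, ...) as_tibble(unclass(x))

#' @rdname tidy.dse_calls
#' @method glance dse_calls
#' @export
glance.dse_calls <- function(x, ...) {
  tibble(n_events = nrow(x), n_dse = sum(x$is_dse, na.rm = TRUE),
         n_dropped = attr(x, "n_dropped") %||% 0L)
}
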