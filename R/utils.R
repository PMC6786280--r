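## internal helpers shared across modules

`%na%` <- function(x, y) ifelse(is.na(x), y, x)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

VALID_CONTEXTS <- c("CG", "CA", "CT", "CC")

#' Fractional methylation of count pairs
#'
#' Weighted methylation of one or more cytosine observations:
#' `sum(n_meth) / sum(n_meth + n_unmeth)`. Returns `NA` when total
#' coverage is zero.
#'
#' @param n_meth,n_unmeth integer vectors of methylated / unmethylated
#'   read counts.
#' @return a single fraction in `[0, 1]`, or `NA_real_`.
#' @export
meth_fraction <- function(n_meth, n_unmeth) {
  tot <- sum(n_meth) + sum(n_unmeth)
  if (tot == 0) return(NA_real_)
  sum(n_meth) / tot
}

## grouping columns (sample structure) present in a site/feature table
group_cols_present <- function(df, candidates = c("tissue", "replicate")) {
  intersect(candidates, names(df))
}

## GRanges from a 0-based half-open interval tibble
to_granges <- function(df, start_col = "start", end_col = "end") {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df[[start_col]] + 1L, end = df[[end_col]]),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

## GRanges of width-1 sites (0-based positions)
sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
}
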