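# Independent oracles used to freeze expected values. Each is written
# from first principles (exact arithmetic, brute-force enumeration)
# and never calls the implementation path it checks.

# ---- exact integer arithmetic on base-1e4 digit vectors -------------
# Enough for products of two binomial coefficients with n <= 30
# (each factor <= choose(30, 15), exact in doubles; the product is not).

big_norm <- function(d) {
  carry <- 0
  out <- numeric(0)
  i <- 1
  while (i <= length(d) || carry > 0) {
    v <- (if (i <= length(d)) d[i] else 0) + carry
    out[i] <- v %% 1e4
    carry <- v %/% 1e4
    i <- i + 1
  }
  while (length(out) > 1 && out[length(out)] == 0) {
    out <- out[-length(out)]
  }
  out
}

# exact product of two non-negative integers representable in doubles
big_from_prod <- function(x, y) {
  x1 <- x %/% 1e4; x0 <- x %% 1e4
  y1 <- y %/% 1e4; y0 <- y %% 1e4
  big_norm(c(x0 * y0, x0 * y1 + x1 * y0, x1 * y1))
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

# a <= b, exactly
big_leq <- function(a, b) {
  if (length(a) != length(b)) return(length(a) < length(b))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  TRUE
}

big_to_double <- function(a) sum(a * 1e4^(seq_along(a) - 1))

# ---- exact two-sided Fisher p for a 2x2 table -----------------------
# Table rows are samples (margins r1 = a+b, r2 = c+d), columns are
# methylated/unmethylated. Enumerates the conditional distribution of
# the top-left cell with exact rational arithmetic: the two-sided p
# sums all outcomes whose exact point probability (integer numerator
# over the common denominator) is <= the observed one.
fisher_oracle_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; m <- a + c
  if (r1 == 0 || r2 == 0 || m == 0 || b + d == 0) return(1)
  lo <- max(0, m - r2); hi <- min(m, r1)
  ks <- lo:hi
  nums <- lapply(ks, function(k) {
    big_from_prod(choose(r1, k), choose(r2, m - k))
  })
  obs <- nums[[a - lo + 1]]
  total <- Reduce(big_add, nums)
  sel <- Reduce(big_add, nums[vapply(nums, big_leq, logical(1), obs)])
  big_to_double(sel) / big_to_double(total)
}

# margin-wise exact oracle: two-sided p for every table with row
# margins (r1, r2) and methylated-column margin m. The point-probability
# numerators C(r1,k) C(r2,m-k) exceed 2^53, so they are compared through
# exact base-2^14 digit vectors (every intermediate stays below 2^53);
# only the final probability ratio is taken in floating point.
fisher_oracle_margin <- function(r1, r2, m) {
  lo <- max(0, m - r2); hi <- min(m, r1)
  ks <- lo:hi
  x <- choose(r1, ks); y <- choose(r2, m - ks)
  B14 <- 16384
  x1 <- x %/% B14; x0 <- x %% B14
  y1 <- y %/% B14; y0 <- y %% B14
  A <- x1 * y1; Bm <- x1 * y0 + x0 * y1; C <- x0 * y0
  d0 <- C %% B14; t1 <- Bm + C %/% B14
  d1 <- t1 %% B14; t2 <- A + t1 %/% B14
  d2 <- t2 %% B14; t3 <- t2 %/% B14
  d3 <- t3 %% B14; d4 <- t3 %/% B14
  o <- order(d4, d3, d2, d1, d0)
  csum <- cumsum((x * y)[o])
  keystr <- paste(d4, d3, d2, d1, d0)
  sorted_keys <- keystr[o]
  last_pos <- vapply(keystr, function(s) max(which(sorted_keys == s)),
                     numeric(1))
  csum[last_pos] / csum[length(csum)]
}

# ---- exact hypergeometric overlap tails -----------------------------
# For |U| <= 50 every term is exact in doubles.
overlap_oracle_tails <- function(n_u, n_a, n_b, obs) {
  ks <- max(0, n_a + n_b - n_u):min(n_a, n_b)
  probs <- choose(n_a, ks) * choose(n_u - n_a, n_b - ks) / choose(n_u, n_b)
  list(p_enrich = sum(probs[ks >= obs]), p_deplete = sum(probs[ks <= obs]))
}

# ---- brute-force per-base genome labelling --------------------------
partition_oracle <- function(genes, chrom_sizes, repeats = NULL) {
  in_any <- function(pos, df, ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    any(pos >= d$start & pos < d$end)
  }
  spans <- gene_spans(genes)
  out <- list()
  for (ch in names(chrom_sizes)) {
    lab <- character(chrom_sizes[[ch]])
    for (p in seq_len(chrom_sizes[[ch]]) - 1L) {
      lab[p + 1] <- if (in_any(p, genes, ch)) "exonic"
        else if (in_any(p, spans, ch)) "intronic"
        else if (!is.null(repeats) && in_any(p, repeats, ch)) "repeat"
        else "intergenic"
    }
    out[[ch]] <- lab
  }
  out
}

# expand a partition table to per-base labels for comparison
partition_to_bases <- function(part, chrom_sizes) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    lab <- character(chrom_sizes[[ch]])
    d <- part[part$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      lab[(d$start[i] + 1):d$end[i]] <- d$label[i]
    }
    out[[ch]] <- lab
  }
  out
}

# ---- brute-force weighted aggregation -------------------------------
aggregate_oracle <- function(sites, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    sel <- sites$chrom == intervals$chrom[i] &
      sites$pos >= intervals$start[i] & sites$pos < intervals$end[i]
    tot <- sum(sites$n_meth[sel]) + sum(sites$n_unmeth[sel])
    if (tot == 0) NA_real_ else sum(sites$n_meth[sel]) / tot
  }, numeric(1))
}

# ---- brute-force profile binning ------------------------------------
# Per-site offsets computed one site at a time against every gene.
profile_oracle <- function(sites, genes, end, bin_width, span) {
  spans <- gene_spans(genes)
  acc_meth <- numeric(0); acc_tot <- numeric(0)
  bins <- seq(0, span - 1, by = bin_width)
  acc_meth <- setNames(rep(0, length(bins)), bins)
  acc_tot <- setNames(rep(0, length(bins)), bins)
  for (i in seq_len(nrow(sites))) {
    for (g in seq_len(nrow(spans))) {
      if (sites$chrom[i] != spans$chrom[g]) next
      if (sites$pos[i] < spans$start[g] || sites$pos[i] >= spans$end[g]) next
      off5 <- if (spans$strand[g] == "+") sites$pos[i] - spans$start[g]
        else spans$end[g] - 1 - sites$pos[i]
      off <- if (end == "5prime") off5
        else (spans$end[g] - spans$start[g] - 1) - off5
      if (off < 0 || off >= span) next
      b <- as.character((off %/% bin_width) * bin_width)
      acc_meth[b] <- acc_meth[b] + sites$n_meth[i]
      acc_tot[b] <- acc_tot[b] + sites$n_meth[i] + sites$n_unmeth[i]
    }
  }
  ifelse(acc_tot > 0, acc_meth / acc_tot, NA_real_)
}

# ---- brute-force context scan ---------------------------------------
context_oracle <- function(seq_str) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq_str, "", fixed = TRUE)[[1]]
  n <- length(chars)
  rows <- list()
  for (i in seq_len(n)) {
    if (chars[i] == "C" && i < n) {
      rows[[length(rows) + 1]] <- c(i - 1, "+", paste0("C", chars[i + 1]))
    }
    if (chars[i] == "G" && i > 1) {
      rows[[length(rows) + 1]] <- c(i - 1, "-",
                                    paste0("C", comp[[chars[i - 1]]]))
    }
  }
  df <- do.call(rbind, rows)
  tibble::tibble(pos = as.integer(df[, 1]), strand = df[, 2],
                 context = df[, 3])
}
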