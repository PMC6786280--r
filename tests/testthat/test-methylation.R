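test_that("aggregation is count-weighted, never a mean of fractions", {
  genes <- make_gene("gA", 0, 100)
  sites <- make_sites(pos = c(10, 20), n_meth = c(3, 0), n_unmeth = c(1, 4))
  m <- aggregate_methylation(sites, genes, feature = "exon")
  expect_equal(m$level, 3 / 8)            # not mean(0.75, 0) = 0.375... = 3/8
  expect_equal(m$informative, 8L)
  # the two definitions differ on unequal coverage
  sites2 <- make_sites(pos = c(10, 20), n_meth = c(3, 1), n_unmeth = c(0, 3))
  m2 <- aggregate_methylation(sites2, genes, feature = "exon")
  expect_equal(m2$level, 4 / 7)
  expect_false(isTRUE(all.equal(m2$level, mean(c(1, 0.25)))))
})

test_that("features without covered sites are missing, not zero", {
  genes <- dplyr::bind_rows(make_gene("gA", 0, 100),
                            make_gene("gB", 200, 300))
  sites <- make_sites(pos = 10, n_meth = 2, n_unmeth = 2)
  m <- aggregate_methylation(sites, genes, feature = "exon")
  expect_false("gB:e01" %in% m$feature_id)  # no row at all without sites
  # a covered feature with zero-coverage rows only -> NA level
  z <- make_sites(pos = 250, n_meth = 0, n_unmeth = 0)
  mz <- aggregate_methylation(z, genes, feature = "exon")
  expect_true(is.na(mz$level))
})

test_that("aggregation matches brute-force re-summation on a random genome", {
  set.seed(7)
  genes <- dplyr::bind_rows(
    make_gene("g1", c(100, 400), c(250, 600)),
    make_gene("g2", c(1000, 1500), c(1200, 1900), strand = "-")
  )
  sites <- make_sites(pos = sort(sample.int(2000, 200)),
                      n_meth = rpois(200, 4), n_unmeth = rpois(200, 4))
  m <- aggregate_methylation(sites, genes, feature = "exon")
  exons <- dplyr::mutate(genes,
                         feature_id = sprintf("%s:e%02d", gene_id, exon_rank))
  joined <- dplyr::left_join(exons, m, by = "feature_id")
  expect_equal(joined$level, aggregate_oracle(sites, exons),
               tolerance = 1e-12)
})

test_that("region filters split exonic and intronic sites", {
  genes <- make_gene("gA", c(0, 200), c(100, 300))
  sites <- make_sites(pos = c(50, 150, 250), n_meth = c(4, 4, 0),
                      n_unmeth = c(0, 0, 4))
  ex <- aggregate_methylation(sites, genes, feature = "gene",
                              region_filter = "exonic")
  int <- aggregate_methylation(sites, genes, feature = "gene",
                               region_filter = "intronic")
  expect_equal(ex$level, 0.5)    # sites at 50 and 250 only
  expect_equal(int$level, 1)     # intron site at 150
})

test_that("percent-methylation-change follows the two-branch formula", {
  expect_equal(percent_methylation_change(0.8, 0.6), 25)
  expect_equal(percent_methylation_change(0.6, 0.8), -25)
  expect_equal(percent_methylation_change(0.5, 0), 100)
  expect_equal(percent_methylation_change(0, 0.5), -100)
  expect_equal(percent_methylation_change(0, 0), 0)
  expect_true(is.na(percent_methylation_change(NA, 0.5)))
})

test_that("pmc is antisymmetric, bounded, and 100 only at a single zero", {
  g <- seq(0, 1, by = 0.01)
  grid <- expand.grid(a = g, b = g)
  v <- percent_methylation_change(grid$a, grid$b)
  v_rev <- percent_methylation_change(grid$b, grid$a)
  expect_equal(v, -v_rev)
  expect_true(all(v >= -100 & v <= 100))
  at100 <- abs(v) == 100
  one_zero <- xor(grid$a == 0, grid$b == 0)
  expect_equal(at100, one_zero)
})

test_that("Fisher p-values match closed-form and independent references", {
  # (10,0) vs (0,10): two-sided p = 2 / choose(20, 10)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # identical counts -> p = 1
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  # degenerate margins -> p = 1, never an exception
  expect_equal(fisher_exact_2x2(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1)
  # random tables against stats::fisher.test and the exact oracle
  set.seed(3)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 8), 2)
    p_ours <- fisher_exact_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    p_ref <- stats::fisher.test(tb)$p.value
    p_oracle <- fisher_oracle_p(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(p_ours, p_ref, tolerance = 1e-9)
    expect_equal(p_ours, p_oracle, tolerance = 1e-9)
  }
})

test_that("differential calls require concordance, eligibility and classify by pmc", {
  # strong change in both replicates, pooled 0.95 vs 0.05 -> full
  cnt <- pair_counts("f1", a1 = c(19, 1), a2 = c(19, 1),
                     b1 = c(1, 19), b2 = c(1, 19))
  dm <- call_differential_methylation(cnt, c("A", "B"), alpha = 0.001,
                                      min_informative = 10)
  expect_true(dm$is_dm)
  expect_equal(dm$pmc, 100 * (0.95 - 0.05) / 0.95, tolerance = 1e-12)
  expect_equal(dm$dm_class, "full")   # |pmc| ~= 94.7 >= 90

  # significant in only one replicate -> not differential
  cnt2 <- pair_counts("f1", a1 = c(19, 1), a2 = c(10, 10),
                      b1 = c(1, 19), b2 = c(10, 10))
  dm2 <- call_differential_methylation(cnt2, c("A", "B"), alpha = 0.001,
                                       min_informative = 10)
  expect_false(dm2$is_dm)
  expect_equal(dm2$dm_class, "none")

  # eligibility: low level in both samples blocks the call
  cnt3 <- pair_counts("f1", a1 = c(1, 99), a2 = c(1, 99),
                      b1 = c(0, 10), b2 = c(0, 10))
  dm3 <- call_differential_methylation(cnt3, c("A", "B"), alpha = 0.05,
                                       min_informative = 10)
  expect_false(dm3$eligible)
  expect_false(dm3$is_dm)

  # moderate change -> partial
  cnt4 <- pair_counts("f1", a1 = c(90, 10), a2 = c(90, 10),
                      b1 = c(60, 40), b2 = c(60, 40))
  dm4 <- call_differential_methylation(cnt4, c("A", "B"), alpha = 0.001,
                                       min_informative = 10)
  expect_true(dm4$is_dm)
  expect_equal(dm4$dm_class, "partial")
})

test_that("every eligible differential feature is exactly one of partial/full", {
  set.seed(11)
  cnt <- purrr::map_dfr(1:200, function(i) {
    pair_counts(sprintf("f%03d", i),
                a1 = rpois(2, 10), a2 = rpois(2, 10),
                b1 = rpois(2, 10), b2 = rpois(2, 10))
  })
  dm <- call_differential_methylation(cnt, c("A", "B"), alpha = 0.3,
                                      min_informative = 5)
  expect_true(all(dm$dm_class[dm$is_dm] %in% c("partial", "full")))
  expect_true(all(dm$dm_class[!dm$is_dm] == "none"))
})

test_that("exon state bins use the adopted edge reading", {
  m <- tibble::tibble(
    feature_id = c("e1", "e2", "e3", "e4"),
    tissue = "sperm",
    level = c(0.95, 0.10, 0.05, 0.90),
    informative = c(50L, 50L, 50L, 50L)
  )
  st <- classify_exon_states(m, min_level = 0, min_informative = 4)
  expect_equal(st$state[st$feature_id == "e1"], "full")
  expect_equal(st$state[st$feature_id == "e2"], "intermediate") # 0.1 inclusive
  expect_equal(st$state[st$feature_id == "e3"], "unmethylated")
  expect_equal(st$state[st$feature_id == "e4"], "intermediate") # 0.9 inclusive

  props <- state_proportions(st)
  expect_equal(sum(props$proportion), 1)
})

test_that("state-bin eligibility follows the 34% / 4-read rule", {
  m <- tibble::tibble(
    feature_id = c("e1", "e1", "e2", "e2"),
    tissue = c("sperm", "larva", "sperm", "larva"),
    level = c(0.5, 0.05, 0.3, 0.2),
    informative = c(10L, 10L, 100L, 100L)
  )
  st <- classify_exon_states(m)
  expect_setequal(unique(st$feature_id), "e1")   # e2 never reaches 34%
  expect_warning(
    classify_exon_states(dplyr::mutate(m, level = 0.1)),
    "no exons")
})

test_that("read classification partitions epialleles per CG class", {
  rec <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    feature_id = c("a", "a", "b", "b", "c"),
    states = c("M,M,M", "U,U,U", "M,U", "M,M", "U")
  )
  cl <- classify_reads(rec)
  get <- function(k, what) {
    cl$proportion[cl$cg_count == k & cl$read_class == what]
  }
  expect_equal(get(3, "fully"), 0.5)
  expect_equal(get(3, "unmethylated"), 0.5)
  expect_equal(get(2, "partially"), 0.5)
  expect_equal(get(1, "unmethylated"), 1)
  sums <- cl |>
    dplyr::group_by(cg_count) |>
    dplyr::summarise(s = sum(proportion))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # single-CG reads can never be partial
  expect_equal(get(1, "partially"), 0)
})

test_that("experiment- vs tissue-specific counts match the exhaustive truth table", {
  build_m <- function(bits) {
    # bits: (A_e1, A_e2, B_e1, B_e2)
    tibble::tibble(
      feature_id = "x",
      tissue = rep(c("A", "B"), each = 2),
      replicate = c(1L, 2L, 1L, 2L),
      level = ifelse(bits, 0.5, 0)
    )
  }
  truth <- function(bits) {
    a1 <- bits[1]; a2 <- bits[2]; b1 <- bits[3]; b2 <- bits[4]
    c(experiment_specific = (a1 && b1 && !a2 && !b2) ||
        (a2 && b2 && !a1 && !b1),
      tissue_specific = (a1 && a2 && !b1 && !b2) ||
        (b1 && b2 && !a1 && !a2))
  }
  for (i in 0:15) {
    bits <- as.logical(bitwAnd(i, c(1L, 2L, 4L, 8L)))
    res <- experiment_vs_tissue_counts(build_m(bits), "A", "B")
    expected <- truth(bits)
    expect_equal(res$n[res$category == "experiment_specific"],
                 as.integer(expected["experiment_specific"]), info = i)
    expect_equal(res$n[res$category == "tissue_specific"],
                 as.integer(expected["tissue_specific"]), info = i)
  }
  # the two worked examples
  ts <- experiment_vs_tissue_counts(build_m(c(TRUE, TRUE, FALSE, FALSE)),
                                    "A", "B")
  expect_equal(ts$n[ts$category == "tissue_specific"], 1L)
  es <- experiment_vs_tissue_counts(build_m(c(TRUE, FALSE, TRUE, FALSE)),
                                    "A", "B")
  expect_equal(es$n[es$category == "experiment_specific"], 1L)
  expect_error(
    experiment_vs_tissue_counts(
      dplyr::filter(build_m(rep(TRUE, 4)), replicate == 1), "A", "B"),
    "two experiments")
})
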