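# Generator behaviour: determinism, configured densities, class
# structure, and the statistical properties downstream recovery
# depends on. Small problem sizes keep these fast; the deeper
# parameter-recovery checks live in the acceptance suite.

small_cfg <- function(...) {
  sim_config(seed = 5, n_genes = 40, tissues = c("sperm", "embryo", "larva"),
             ...)
}

test_that("identical config and seed give identical output", {
  cfg <- small_cfg()
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$genome, a2$genome)
  m1 <- simulate_methylome(cfg, a1)
  m2 <- simulate_methylome(cfg, a2)
  expect_identical(m1$sites, m2$sites)
  # and byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cx_table(dplyr::filter(m1$sites, tissue == "embryo",
                               replicate == 1),
                 file.path(d1, "x.tsv"))
  write_cx_table(dplyr::filter(m2$sites, tissue == "embryo",
                               replicate == 1),
                 file.path(d2, "x.tsv"))
  expect_identical(readLines(file.path(d1, "x.tsv")),
                   readLines(file.path(d2, "x.tsv")))
})

test_that("degenerate geometry configs produce the requested structure", {
  cfg <- sim_config(seed = 1, n_genes = 1, exons_per_gene_lambda = 0,
                    exon_length_mean = 200, length_jitter = FALSE)
  ann <- simulate_annotation(cfg)
  expect_equal(dplyr::n_distinct(ann$genes$gene_id), 1)
  expect_equal(nrow(ann$genes), 1)
  expect_equal(ann$genes$end - ann$genes$start, 200L)
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(replicates = 0), "replicates")
  expect_error(sim_config(soma_drop = c(larva = 1, pupa = 0, head = 0)),
               "soma_drop")
})

test_that("CG site counts track the configured density", {
  cfg <- sim_config(seed = 21, n_genes = 50, cg_density = 0.05,
                    exons_per_gene_lambda = 0, exon_length_mean = 200,
                    length_jitter = FALSE)
  ann <- simulate_annotation(cfg)
  exonic_bp <- sum(ann$genes$end - ann$genes$start)
  expect_equal(exonic_bp, 10000)
  # count CG dinucleotides (plus-strand records) inside exons
  cg <- dplyr::filter(ann$sites, context == "CG", strand == "+")
  located <- dplyr::inner_join(
    cg, ann$genes, by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(pos >= start, pos < end)
  expected <- 0.05 * exonic_bp
  sd3 <- 3 * sqrt(exonic_bp * 0.05 * 0.95)
  expect_lt(abs(nrow(located) - expected), sd3)
})

test_that("unmethylated-class genes stay near zero in every tissue", {
  cfg <- small_cfg()
  me <- simulate_methylome(cfg, simulate_annotation(cfg))
  dy <- me$truth$dyads
  un <- dy[dy$class == "unmethylated", ]
  for (t in c("sperm", "embryo", "larva")) {
    expect_true(all(un[[paste0("p_", t)]] <= 0.01))
  }
})

test_that("a null generator (no drop, no experiment effect) centres pmc at zero", {
  cfg <- sim_config(seed = 9, n_genes = 60,
                    tissues = c("sperm", "embryo", "larva"),
                    soma_drop = c(larva = 0, pupa = 0, head = 0),
                    experiment_effect_sd = 0)
  ann <- simulate_annotation(cfg)
  me <- simulate_methylome(cfg, ann)
  dy <- me$truth$dyads
  expect_equal(dy$p_embryo, dy$p_larva)   # identical true levels
  cnt <- aggregate_counts(dplyr::filter(me$sites, context == "CG"),
                          ann$genes, feature = "exon")
  ci <- change_density_inputs(cnt, c("embryo", "larva"),
                              resolution = "exon")
  expect_lt(abs(median(ci$pmc)), 3)
})

test_that("somatic drop recovery: median exon change tracks the drop factor", {
  cfg <- sim_config(seed = 13, n_genes = 80,
                    tissues = c("sperm", "embryo", "larva"))
  ann <- simulate_annotation(cfg)
  me <- simulate_methylome(cfg, ann)
  cnt <- aggregate_counts(dplyr::filter(me$sites, context == "CG"),
                          ann$genes, feature = "exon")
  ci <- change_density_inputs(cnt, c("embryo", "larva"),
                              resolution = "exon")
  expect_lt(abs(median(ci$pmc) - 25), 3)
})

test_that("read simulation respects site probabilities and correlation", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  me <- simulate_methylome(cfg, ann)
  # force probability-1 sites: every read fully methylated
  me1 <- me
  for (t in c("sperm", "embryo", "larva")) {
    me1$truth$dyads[[paste0("p_", t)]] <- 1
  }
  rd <- simulate_reads(cfg, me1, reads_per_exon = 10)
  expect_false(any(grepl("U", rd$states)))
  expect_error(simulate_reads(cfg, me, reads_per_exon = 0), "positive")
})

test_that("rho = 0 reads have near-zero between-site covariance", {
  cfg <- sim_config(seed = 33, n_genes = 40,
                    tissues = c("sperm", "embryo", "larva"),
                    read_rho_germline = 0, read_rho_soma = 0)
  ann <- simulate_annotation(cfg)
  me <- simulate_methylome(cfg, ann)
  # fix all dyads at p = 0.5 for a clean covariance target
  for (t in c("sperm", "embryo", "larva")) {
    me$truth$dyads[[paste0("p_", t)]] <- 0.5
  }
  rd <- simulate_reads(cfg, me, reads_per_exon = 400, tissues = "embryo")
  two <- rd[stringr::str_count(rd$states, ",") == 1, ]
  s1 <- as.integer(substr(two$states, 1, 1) == "M")
  s2 <- as.integer(substr(two$states, 3, 3) == "M")
  n <- length(s1)
  # covariance of independent Bernoulli(0.5) pairs: sd ~ 0.25/sqrt(n)
  expect_lt(abs(cov(s1, s2)), 3 * 0.25 / sqrt(n))
})

test_that("germline reads are more often fully methylated than somatic reads", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  me <- simulate_methylome(cfg, ann)
  rd <- simulate_reads(cfg, me, reads_per_exon = 60)
  cl <- classify_reads(rd)
  fully <- cl[cl$read_class == "fully", ]
  for (k in 1:3) {
    f <- fully[fully$cg_count == k, ]
    expect_gt(f$proportion[f$tissue == "sperm"],
              f$proportion[f$tissue == "larva"])
  }
})

test_that("expression truth drives DE calls and responsiveness structure", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  me <- simulate_methylome(cfg, ann)
  ex <- simulate_expression(cfg, ann, me$truth$genes)
  joined <- dplyr::inner_join(ex$de_calls, ex$truth,
                              by = c("gene_id", "sample_a", "sample_b"))
  expect_true(all(joined$fold_change[joined$true_de] > 2))
  expect_true(all(joined$q_value[joined$true_de] < 0.05))
  expect_equal(joined$is_de, joined$true_de)

  # de_fraction = 0 -> all-zero responsiveness
  cfg0 <- small_cfg(de_fraction = 0)
  ex0 <- simulate_expression(cfg0, ann, me$truth$genes)
  resp0 <- gene_responsiveness(ex0$de_calls)
  expect_true(all(resp0$responsiveness == 0))

  # methylated genes are biased toward low responsiveness
  cfg2 <- sim_config(seed = 17, n_genes = 300)
  ann2 <- simulate_annotation(cfg2)
  me2 <- simulate_methylome(cfg2, ann2)
  ex2 <- simulate_expression(cfg2, ann2, me2$truth$genes)
  resp <- dplyr::inner_join(gene_responsiveness(ex2$de_calls),
                            me2$truth$genes, by = "gene_id")
  w <- wilcox.test(responsiveness ~ class, data = resp,
                   alternative = "less")
  expect_lt(w$p.value, 0.01)
})

test_that("splice-event truth yields the configured differential structure", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  ps <- simulate_psi(cfg, ann)
  expect_true(all(abs(ps$truth$true_dpsi[ps$truth$true_dpsi != 0]) >= 0.1))
  expect_true(all(ps$psi$psi >= 0 & ps$psi$psi <= 1, na.rm = TRUE))
  # every emitted event has exactly one truth row and vice versa
  expect_setequal(unique(ps$psi$event_id), ps$truth$event_id)
  expect_false(anyDuplicated(ps$truth$event_id) > 0)
})

test_that("truth ledger covers every emitted feature exactly once", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  me <- simulate_methylome(cfg, ann)
  # every emitted CG position belongs to exactly one truth dyad
  cg <- dplyr::filter(me$sites, context == "CG", tissue == "embryo",
                      replicate == 1)
  dyad <- ifelse(cg$strand == "+", cg$pos, cg$pos - 1L)
  expect_true(all(paste0(cg$chrom, ":", dyad) %in%
                    me$truth$dyads$dyad_id))
  expect_false(anyDuplicated(me$truth$dyads$dyad_id) > 0)
  # every annotated exon has one truth row (exons with no CG dyads are
  # absent from the dyad-derived exon table by construction)
  expect_false(anyDuplicated(me$truth$exons$exon_id) > 0)
  expect_true(all(me$truth$exons$exon_id %in%
                    sprintf("%s:e%02d", ann$genes$gene_id,
                            ann$genes$exon_rank)))
})

test_that("experiment effect separates experiments more than tissues", {
  cfg <- sim_config(seed = 29, n_genes = 120,
                    tissues = c("sperm", "embryo", "larva"),
                    experiment_effect_sd = 1.5,
                    soma_drop = c(larva = 0.02, pupa = 0, head = 0))
  ann <- simulate_annotation(cfg)
  me <- simulate_methylome(cfg, ann)
  m <- aggregate_methylation(dplyr::filter(me$sites, context == "CG"),
                             ann$genes, feature = "exon")
  w <- tidyr::pivot_wider(m, id_cols = feature_id,
                          names_from = c(tissue, replicate),
                          values_from = level)
  cc <- w[complete.cases(w), ]
  cor_cross_exp <- cor(cc$embryo_1, cc$embryo_2)
  cor_within_exp <- cor(cc$embryo_1, cc$larva_1)
  expect_gt(cor_within_exp, cor_cross_exp)
})

test_that("head CH methylation is confined to CG-methylated genes", {
  cfg <- sim_config(seed = 41, n_genes = 80,
                    tissues = c("sperm", "embryo", "larva", "head"))
  ann <- simulate_annotation(cfg)
  me <- simulate_methylome(cfg, ann)
  ch <- dplyr::filter(me$sites, context != "CG", tissue == "head")
  located <- beemethyl:::locate_sites(ch, ann$genes) |>
    dplyr::left_join(me$truth$genes[c("gene_id", "class")], by = "gene_id")
  in_meth <- located$class == "methylated" & !is.na(located$class)
  rate_meth <- with(located[in_meth & located$context == "CA", ],
                    sum(n_meth) / sum(n_meth + n_unmeth))
  rate_un <- with(located[!in_meth, ], sum(n_meth) / sum(n_meth + n_unmeth))
  expect_gt(rate_meth, 0.002)
  expect_equal(rate_un, 0)
  # larva carries no CH methylation anywhere
  ch_larva <- dplyr::filter(me$sites, context != "CG", tissue == "larva")
  expect_equal(sum(ch_larva$n_meth), 0L)
})

test_that("configuration round-trips through key=value text", {
  cfg <- sim_config(seed = 99, n_genes = 17, cg_density = 0.033,
                    soma_drop = c(larva = 0.3, pupa = 0.05, head = 0.11))
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_sim_config(cfg, tmp)
  back <- read_sim_config(tmp)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$n_genes, cfg$n_genes)
  expect_equal(back$cg_density, cfg$cg_density)
  expect_equal(back$soma_drop, cfg$soma_drop)
  expect_equal(back$tissues, cfg$tissues)
})
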