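## Synthetic methylome generator.
##
## Emulates the germline/soma methylome structure of honey bee
## development: bimodal (near-0 / near-1) site-level CG methylation in
## sperm and embryo, graded partial hypomethylation in somatic tissues,
## exon-level drop factors correlated across post-embryonic tissues,
## an experiment (replicate batch) effect shared across tissues, and
## head-restricted low-level CA/CT methylation confined to CG-methylated
## genes. Every emitted feature is recorded in a ground-truth ledger so
## that recovery tests can compare estimates against generative values.

GERMLINE_TISSUES <- c("sperm", "embryo")

#' Simulation configuration
#'
#' Returns a validated configuration list for the synthetic-data
#' generator. Defaults encode the study conditions the generator
#' emulates: ~40% of genes in the methylated class, site-level
#' methylation of methylated germline sites near 0.95 (sperm drawn from
#' Beta(18, 2), reproducing a ~0.9 sperm median), a mean 25% larval and
#' 10% pupa/head per-exon hypomethylation with drop factors correlated
#' at 0.8 across somatic tissues, 20x mean coverage with beta-binomial
#' overdispersion, two replicates collected as two experiments, and
#' head-only CA (0.004) / CT (0.002) methylation inside CG-methylated
#' genes.
#'
#' @param seed integer RNG seed; the same configuration and seed give
#'   byte-identical output.
#' @param n_genes number of genes to simulate.
#' @param genes_per_chrom genes laid per chromosome.
#' @param exons_per_gene_lambda exon count per gene is
#'   `1 + Poisson(lambda)`.
#' @param exon_length_mean,intron_length_mean,intergenic_length_mean
#'   mean element lengths in bp (elements have a fixed floor plus a
#'   Poisson remainder).
#' @param length_jitter draw element lengths stochastically (default);
#'   `FALSE` fixes every element at its configured mean, for
#'   deterministic toy geometries.
#' @param cg_density expected CG dinucleotide density per bp; the genome
#'   base composition is chosen so that random sequence attains it.
#' @param coverage mean per-site read depth (Poisson).
#' @param overdispersion intra-class correlation of the beta-binomial
#'   count noise (0 = pure binomial).
#' @param p_methylated_gene fraction of genes in the methylated class.
#' @param p_site_methylated_exon,p_site_methylated_intron probability
#'   that a CG dyad inside a methylated gene's exon (intron) is itself
#'   methylated; gene body methylation is exon-enriched.
#' @param germline_high mean embryo methylation of methylated sites.
#' @param germline_concentration Beta concentration of embryo site
#'   levels.
#' @param sperm_alpha,sperm_beta Beta parameters of sperm site levels
#'   (heavy point mass near 1).
#' @param soma_drop named vector of per-tissue mean multiplicative
#'   hypomethylation factors (values in `[0, 1)`).
#' @param drop_concentration Beta concentration of per-exon drop
#'   factors around the tissue mean.
#' @param change_correlation correlation of per-exon drop factors
#'   across somatic tissues (Gaussian copula).
#' @param experiment_effect_sd sd of the per-exon, per-experiment logit
#'   shift shared across all tissues of an experiment (emulates the
#'   experiment-1 vs experiment-2 divergence).
#' @param read_rho_germline,read_rho_soma within-read CG state
#'   correlation used by [simulate_reads()]. The real magnitude of
#'   within-read correlation is unknown; these defaults are
#'   assumptions.
#' @param head_ch_rate_ca,head_ch_rate_ct CA / CT methylation rates in
#'   head samples within CG-methylated genes; 0 elsewhere and for CC.
#' @param ch_site_subsample fraction of genic CH sites emitted
#'   (thinning for tractability; per-site rates are unaffected).
#' @param unmeth_max upper bound of true methylation at unmethylated
#'   sites.
#' @param de_fraction per-pair differential-expression probability for
#'   unmethylated genes.
#' @param de_meth_bias multiplier (< 1) on `de_fraction` for
#'   methylated-class genes, encoding their low responsiveness.
#' @param dse_fraction fraction of splice events made differential.
#' @param psi_events_per_gene expected AS events per gene.
#' @param psi_rep_sd replicate-level PSI noise sd.
#' @param psi_missing_rate probability a PSI observation is missing.
#' @param tissues developmental samples to emit (must include sperm,
#'   embryo and at least one somatic tissue for the full pipeline).
#' @param replicates biological replicates (= experiments).
#' @return a list of class `"bee_sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       genes_per_chrom = 100L,
                       exons_per_gene_lambda = 4,
                       exon_length_mean = 250,
                       intron_length_mean = 400,
                       intergenic_length_mean = 800,
                       length_jitter = TRUE,
                       cg_density = 0.02,
                       coverage = 20,
                       overdispersion = 0.08,
                       p_methylated_gene = 0.4,
                       p_site_methylated_exon = 0.9,
                       p_site_methylated_intron = 0.2,
                       germline_high = 0.95,
                       germline_concentration = 40,
                       sperm_alpha = 18,
                       sperm_beta = 2,
                       soma_drop = c(larva = 0.25, pupa = 0.10, head = 0.10),
                       drop_concentration = 20,
                       change_correlation = 0.8,
                       experiment_effect_sd = 0.35,
                       read_rho_germline = 0.8,
                       read_rho_soma = 0.3,
                       head_ch_rate_ca = 0.004,
                       head_ch_rate_ct = 0.002,
                       ch_site_subsample = 0.25,
                       unmeth_max = 0.01,
                       de_fraction = 0.3,
                       de_meth_bias = 0.3,
                       dse_fraction = 0.2,
                       psi_events_per_gene = 0.5,
                       psi_rep_sd = 0.02,
                       psi_missing_rate = 0.02,
                       tissues = c("sperm", "embryo", "larva", "pupa", "head"),
                       replicates = 2L) {
  config <- as.list(environment())
  validate_sim_config(config)
  structure(config, class = "bee_sim_config")
}

validate_sim_config <- function(config) {
  probs <- c("cg_density", "overdispersion", "p_methylated_gene",
             "p_site_methylated_exon", "p_site_methylated_intron",
             "germline_high", "change_correlation", "read_rho_germline",
             "read_rho_soma", "head_ch_rate_ca", "head_ch_rate_ct",
             "ch_site_subsample", "unmeth_max", "de_fraction",
             "de_meth_bias", "dse_fraction", "psi_missing_rate")
  for (p in probs) {
    v <- config[[p]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      abort(sprintf("sim_config: %s must lie in [0, 1]", p))
    }
  }
  if (config$n_genes < 1) abort("sim_config: n_genes must be at least 1")
  if (config$replicates < 1) abort("sim_config: replicates must be at least 1")
  if (any(config$soma_drop < 0) || any(config$soma_drop >= 1)) {
    abort("sim_config: soma_drop values must lie in [0, 1)")
  }
  if (config$coverage <= 0) abort("sim_config: coverage must be positive")
  somatic <- setdiff(config$tissues, GERMLINE_TISSUES)
  missing <- setdiff(somatic, names(config$soma_drop))
  if (length(missing)) {
    abort(sprintf("sim_config: soma_drop lacks entries for: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(config)
}

## sequence base probabilities so that E[CG dinucleotides per bp] equals
## cg_density: pC = pG = sqrt(cg_density), AT-rich remainder split evenly
base_probs <- function(cg_density) {
  q <- sqrt(cg_density)
  if (2 * q >= 1) abort("cg_density too high for a valid base composition")
  c(A = (1 - 2 * q) / 2, C = q, G = q, T = (1 - 2 * q) / 2)
}

## scan one chromosome sequence for cytosines on both strands
scan_contexts <- function(seq_chars, chrom) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(seq_chars)
  plus <- which(seq_chars == "C")
  plus <- plus[plus < n]                      # need a downstream base
  minus <- which(seq_chars == "G")
  minus <- minus[minus > 1]
  dplyr::bind_rows(
    tibble(chrom = chrom, pos = plus - 1L, strand = "+",
           context = paste0("C", seq_chars[plus + 1L])),
    tibble(chrom = chrom, pos = minus - 1L, strand = "-",
           context = paste0("C", comp[seq_chars[minus - 1L]]))
  ) |>
    dplyr::filter(.data$context %in% VALID_CONTEXTS) |>
    dplyr::arrange(.data$pos, .data$strand)
}

#' Simulate a genome, gene models and cytosine site map
#'
#' Lays genes with Poisson-sized exon/intron structure along
#' chromosomes, generates random sequence whose base composition
#' attains the configured CG density, and derives the strand-resolved
#' cytosine context map from that sequence, so context annotation and
#' simulation are mutually consistent.
#'
#' @param config a [sim_config()] object.
#' @return list of class `"bee_sim_annotation"`: `genes` (exon tibble as
#'   from [read_annotation()]), `chrom_sizes`, `sites` (chrom, pos,
#'   strand, context map), `genome` (named character sequences).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_genes)
  jit <- isTRUE(config$length_jitter)
  rlen <- function(k, mean, floor_) {
    if (jit) floor_ + rpois(k, mean - floor_) else rep(as.integer(mean), k)
  }
  n_exons <- 1L + rpois(n, config$exons_per_gene_lambda)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom_of <- paste0("chr", (seq_len(n) - 1L) %/% config$genes_per_chrom + 1L)

  genes <- vector("list", n)
  cursor <- list()  # per-chrom cursor
  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    at <- cursor[[ch]] %||% 0L
    gap <- rlen(1, config$intergenic_length_mean, 100L)
    at <- at + gap
    ne <- n_exons[i]
    ex_len <- rlen(ne, config$exon_length_mean, 50L)
    in_len <- if (ne > 1) rlen(ne - 1L, config$intron_length_mean, 80L)
              else integer(0)
    starts <- at + cumsum(c(0L, head(ex_len, -1) + in_len))
    genes[[i]] <- tibble(
      gene_id = sprintf("g%04d", i), chrom = ch, strand = strand[i],
      start = as.integer(starts), end = as.integer(starts + ex_len),
      exon_rank = seq_len(ne)
    )
    cursor[[ch]] <- as.integer(max(genes[[i]]$end))
  }
  genes <- dplyr::bind_rows(genes)
  chrom_sizes <- genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(size = max(.data$end) + 200L, .groups = "drop")
  chrom_sizes <- setNames(as.integer(chrom_sizes$size), chrom_sizes$chrom)

  bp <- base_probs(config$cg_density)
  genome <- vapply(names(chrom_sizes), function(ch) {
    paste(sample(names(bp), chrom_sizes[[ch]], replace = TRUE, prob = bp),
          collapse = "")
  }, character(1))
  sites <- purrr::map_dfr(names(genome), function(ch) {
    scan_contexts(strsplit(genome[[ch]], "", fixed = TRUE)[[1]], ch)
  })
  structure(
    list(genes = genes, chrom_sizes = chrom_sizes, sites = sites,
         genome = genome, config = config),
    class = "bee_sim_annotation"
  )
}

## assign sites to exon / intron / intergenic compartments
locate_sites <- function(sites, genes) {
  s_gr <- sites_granges(sites)
  ex_gr <- to_granges(genes)
  hits <- GenomicRanges::findOverlaps(s_gr, ex_gr, ignore.strand = TRUE,
                                      select = "first")
  span <- gene_spans(genes)
  sp_gr <- to_granges(span)
  ghits <- GenomicRanges::findOverlaps(s_gr, sp_gr, ignore.strand = TRUE,
                                       select = "first")
  exon_ids <- sprintf("%s:e%02d", genes$gene_id, genes$exon_rank)
  sites |>
    dplyr::mutate(
      exon_id = ifelse(is.na(hits), NA_character_, exon_ids[hits]),
      gene_id = ifelse(is.na(ghits), NA_character_, span$gene_id[ghits]),
      region = dplyr::case_when(
        !is.na(hits) ~ "exonic",
        !is.na(ghits) ~ "intronic",
        TRUE ~ "intergenic"
      )
    )
}

clamp01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

## beta-binomial draw: n trials, mean p, intra-class correlation icc
rbetabinom <- function(n_trials, p, icc) {
  if (icc <= 0) return(rbinom(length(p), n_trials, p))
  s <- (1 - icc) / icc
  pstar <- rbeta(length(p), clamp01(p) * s, (1 - clamp01(p)) * s)
  rbinom(length(p), n_trials, pstar)
}

#' Simulate per-cytosine methylation count tables with ground truth
#'
#' Draws site-level methylation states per the generative model in
#' [sim_config()] and emits Bismark-style count rows per tissue and
#' replicate, together with a truth ledger (gene classes, per-exon drop
#' factors, per-dyad tissue methylation probabilities).
#'
#' Methylated-class sites in sperm and embryo sit near
#' `germline_high` with a heavy point mass near 1 in sperm; somatic
#' tissue `t` has per-exon expected methylation
#' `embryo * (1 - drop[t, exon])`, with drop factors correlated across
#' tissues; counts are beta-binomial at the configured coverage. CG
#' methylation is symmetric: both cytosines of a dyad share one true
#' level.
#'
#' @param config a [sim_config()] object.
#' @param annotation output of [simulate_annotation()].
#' @param tissues,replicates override the configured samples.
#' @return list of class `"bee_sim_methylome"`: `sites` (long tibble
#'   `tissue`, `replicate`, chrom, pos, strand, context, n_meth,
#'   n_unmeth), `truth` (list: `genes`, `exons`, `dyads`).
#' @export
simulate_methylome <- function(config, annotation,
                               tissues = config$tissues,
                               replicates = config$replicates) {
  validate_sim_config(config)
  if (replicates < 1) abort("replicates must be at least 1")
  if (!all(GERMLINE_TISSUES %in% tissues) ||
      length(setdiff(tissues, GERMLINE_TISSUES)) < 1) {
    abort("tissues must include sperm, embryo and at least one somatic tissue")
  }
  set.seed(config$seed + 1000L)
  genes <- annotation$genes
  somatic <- setdiff(tissues, GERMLINE_TISSUES)

  ## gene classes
  gene_tbl <- gene_spans(genes) |>
    dplyr::mutate(class = ifelse(runif(dplyr::n()) < config$p_methylated_gene,
                                 "methylated", "unmethylated"))

  ## per-exon drop factors, correlated across somatic tissues
  exons <- genes |>
    dplyr::mutate(exon_id = sprintf("%s:e%02d", .data$gene_id, .data$exon_rank)) |>
    dplyr::left_join(gene_tbl[c("gene_id", "class")], by = "gene_id")
  rho <- config$change_correlation
  z_shared <- rnorm(nrow(exons))
  for (t in somatic) {
    mu <- unname(config$soma_drop[[t]])
    if (mu <= 0) {
      exons[[paste0("drop_", t)]] <- 0
    } else {
      z_t <- sqrt(rho) * z_shared + sqrt(1 - rho) * rnorm(nrow(exons))
      a <- mu * config$drop_concentration
      b <- (1 - mu) * config$drop_concentration
      exons[[paste0("drop_", t)]] <- qbeta(pnorm(z_t), a, b)
    }
  }

  ## CG dyads: one true methylation trajectory per dyad
  cg <- dplyr::filter(annotation$sites, .data$context == "CG") |>
    locate_sites(genes) |>
    dplyr::mutate(dyad = ifelse(.data$strand == "+", .data$pos, .data$pos - 1L),
                  dyad_id = paste0(.data$chrom, ":", .data$dyad))
  ## one truth row per dyad; at compartment boundaries the two strand
  ## mates may straddle regions — the dyad takes the more genic label
  dyads <- cg |>
    dplyr::distinct(.data$dyad_id, .data$chrom, .data$dyad, .data$gene_id,
                    .data$exon_id, .data$region) |>
    dplyr::mutate(rk = match(.data$region,
                             c("exonic", "intronic", "intergenic"))) |>
    dplyr::arrange(.data$dyad_id, .data$rk) |>
    dplyr::distinct(.data$dyad_id, .keep_all = TRUE) |>
    dplyr::select(-"rk") |>
    dplyr::left_join(gene_tbl[c("gene_id", "class")], by = "gene_id") |>
    dplyr::mutate(class = .data$class %na% "unmethylated")

  p_site <- ifelse(dyads$region == "exonic", config$p_site_methylated_exon,
                   ifelse(dyads$region == "intronic",
                          config$p_site_methylated_intron, 0))
  dyads$site_class <- ifelse(
    dyads$class == "methylated" & runif(nrow(dyads)) < p_site,
    "methylated", "unmethylated")

  nm <- sum(dyads$site_class == "methylated")
  gc <- config$germline_concentration
  p_embryo <- runif(nrow(dyads), 0, config$unmeth_max)
  p_embryo[dyads$site_class == "methylated"] <-
    rbeta(nm, config$germline_high * gc, (1 - config$germline_high) * gc)
  p_sperm <- runif(nrow(dyads), 0, config$unmeth_max)
  p_sperm[dyads$site_class == "methylated"] <-
    rbeta(nm, config$sperm_alpha, config$sperm_beta)

  ## per-gene mean drop for intron sites
  truth_p <- dyads["dyad_id"]
  truth_p$p_sperm <- p_sperm
  truth_p$p_embryo <- p_embryo
  for (t in somatic) {
    dcol <- paste0("drop_", t)
    gene_drop <- exons |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(gdrop = mean(.data[[dcol]]), .groups = "drop")
    d <- dplyr::left_join(dyads, exons[c("exon_id", dcol)], by = "exon_id") |>
      dplyr::left_join(gene_drop, by = "gene_id")
    drop <- dplyr::coalesce(d[[dcol]], d$gdrop, 0)
    truth_p[[paste0("p_", t)]] <- p_embryo * (1 - drop)
  }
  dyads <- dplyr::bind_cols(dyads, truth_p[setdiff(names(truth_p), "dyad_id")])

  ## experiment (replicate batch) effects: per exon x experiment logit
  ## shift shared across tissues; intron sites inherit a per-gene shift
  eff_exon <- matrix(rnorm(nrow(exons) * replicates,
                           sd = config$experiment_effect_sd),
                     nrow = nrow(exons))
  rownames(eff_exon) <- exons$exon_id
  gene_ids <- unique(genes$gene_id)
  eff_gene <- matrix(rnorm(length(gene_ids) * replicates,
                           sd = config$experiment_effect_sd),
                     nrow = length(gene_ids))
  rownames(eff_gene) <- gene_ids

  cg_obs <- dplyr::left_join(
    cg, dyads[c("dyad_id", "site_class",
                paste0("p_", tissues))], by = "dyad_id")

  out <- vector("list", length(tissues) * replicates)
  k <- 0L
  for (t in tissues) {
    p_base <- cg_obs[[paste0("p_", t)]]
    for (r in seq_len(replicates)) {
      k <- k + 1L
      delta <- numeric(nrow(cg_obs))
      has_ex <- !is.na(cg_obs$exon_id)
      delta[has_ex] <- eff_exon[cg_obs$exon_id[has_ex], r]
      in_only <- !has_ex & !is.na(cg_obs$gene_id)
      delta[in_only] <- eff_gene[cg_obs$gene_id[in_only], r]
      p_adj <- plogis(qlogis(clamp01(p_base)) + delta)
      n_tot <- rpois(nrow(cg_obs), config$coverage)
      n_meth <- rbetabinom(n_tot, p_adj, config$overdispersion)
      out[[k]] <- tibble(
        tissue = t, replicate = r,
        chrom = cg_obs$chrom, pos = cg_obs$pos, strand = cg_obs$strand,
        context = "CG", n_meth = as.integer(n_meth),
        n_unmeth = as.integer(n_tot - n_meth)
      )
    }
  }
  site_rows <- dplyr::bind_rows(out)

  ## CH sites: emitted within gene spans only, thinned by subsampling;
  ## methylated only in head samples inside CG-methylated genes
  ch <- dplyr::filter(annotation$sites, .data$context != "CG") |>
    locate_sites(genes) |>
    dplyr::filter(.data$region != "intergenic")
  if (nrow(ch) > 0 && config$ch_site_subsample < 1) {
    keep <- runif(nrow(ch)) < config$ch_site_subsample
    ch <- ch[keep, , drop = FALSE]
  }
  if (nrow(ch) > 0) {
    ch <- dplyr::left_join(ch, gene_tbl[c("gene_id", "class")], by = "gene_id")
    ch_rows <- purrr::map_dfr(tissues, function(t) {
      purrr::map_dfr(seq_len(replicates), function(r) {
        rate <- rep(0, nrow(ch))
        if (grepl("head", t)) {
          in_meth <- ch$class == "methylated"
          rate[in_meth & ch$context == "CA"] <- config$head_ch_rate_ca
          rate[in_meth & ch$context == "CT"] <- config$head_ch_rate_ct
        }
        n_tot <- rpois(nrow(ch), config$coverage)
        n_meth <- rbinom(nrow(ch), n_tot, rate)
        tibble(tissue = t, replicate = r, chrom = ch$chrom, pos = ch$pos,
               strand = ch$strand, context = ch$context,
               n_meth = as.integer(n_meth),
               n_unmeth = as.integer(n_tot - n_meth))
      })
    })
    site_rows <- dplyr::bind_rows(site_rows, ch_rows)
  }
  site_rows <- dplyr::arrange(site_rows, .data$tissue, .data$replicate,
                              .data$chrom, .data$pos, .data$strand)

  ## truth ledger
  exon_truth <- dyads |>
    dplyr::filter(!is.na(.data$exon_id)) |>
    dplyr::group_by(.data$exon_id, .data$gene_id) |>
    dplyr::summarise(
      n_dyads = dplyr::n(),
      true_embryo = mean(.data$p_embryo),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      exons[c("exon_id", "class", paste0("drop_", somatic))], by = "exon_id") |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(paste0("drop_", somatic)),
      ~ .x > 0 & class == "methylated",
      .names = "true_dm_{sub('drop_', '', .col)}"
    ))

  structure(
    list(sites = site_rows,
         truth = list(genes = gene_tbl, exons = exon_truth, dyads = dyads),
         tissues = tissues, replicates = replicates),
    class = "bee_sim_methylome"
  )
}

#' Simulate single bisulfite reads over small exons
#'
#' For exons carrying 1-3 CG dyads, draws per-read CG state vectors
#' from the dyad methylation probabilities of the requested tissue,
#' with exchangeable within-read correlation `rho` (germline and soma
#' values from the configuration): with probability `rho` a read's
#' sites share one latent uniform (comonotone states), otherwise states
#' are independent.
#'
#' @param config a [sim_config()] object.
#' @param methylome output of [simulate_methylome()] (for its truth
#'   ledger).
#' @param reads_per_exon reads drawn per exon and tissue.
#' @param tissues samples to draw reads for.
#' @return tibble `read_id`, `feature_id`, `tissue`, `states`
#'   (comma-joined `M`/`U`).
#' @export
simulate_reads <- function(config, methylome, reads_per_exon = 50,
                           tissues = methylome$tissues) {
  if (reads_per_exon <= 0) abort("reads_per_exon must be positive")
  set.seed(config$seed + 2000L)
  dyads <- methylome$truth$dyads |>
    dplyr::filter(!is.na(.data$exon_id)) |>
    dplyr::group_by(.data$exon_id) |>
    dplyr::filter(dplyr::n() <= 3) |>
    dplyr::arrange(.data$dyad, .by_group = TRUE) |>
    dplyr::ungroup()
  if (nrow(dyads) == 0) abort("no exons with 1-3 CG dyads to draw reads from")
  split_p <- split(dyads, dyads$exon_id)
  out <- purrr::map_dfr(tissues, function(t) {
    rho <- if (t %in% GERMLINE_TISSUES) config$read_rho_germline else
      config$read_rho_soma
    pcol <- paste0("p_", t)
    purrr::imap_dfr(split_p, function(d, exon_id) {
      p <- d[[pcol]]
      states <- vapply(seq_len(reads_per_exon), function(i) {
        if (runif(1) < rho) {
          u <- runif(1)
          s <- u < p
        } else {
          s <- runif(length(p)) < p
        }
        paste(ifelse(s, "M", "U"), collapse = ",")
      }, character(1))
      tibble(
        read_id = sprintf("%s_%s_r%04d", exon_id, t, seq_len(reads_per_exon)),
        feature_id = exon_id, tissue = t, states = states
      )
    })
  })
  out
}

#' Simulate expression tables and differential-expression calls
#'
#' Emits a long FPKM table and a per-pair DE call table over all
#' pairwise comparisons of the configured samples. Methylated-class
#' genes are biased toward low responsiveness (their per-pair DE
#' probability is `de_fraction * de_meth_bias`). Truth-DE pairs get
#' `q < 0.05` and fold change > 2; others get `q >= 0.05`.
#'
#' @param config a [sim_config()] object.
#' @param annotation output of [simulate_annotation()].
#' @param gene_classes truth gene table (from
#'   [simulate_methylome()]`$truth$genes`).
#' @param stages sample labels to treat as developmental stages.
#' @return list: `expression`, `de_calls` (with `is_de`), `truth`.
#' @export
simulate_expression <- function(config, annotation, gene_classes,
                                stages = config$tissues) {
  set.seed(config$seed + 3000L)
  genes <- gene_classes$gene_id
  meth <- gene_classes$class == "methylated"
  pairs <- utils::combn(stages, 2)
  de_p <- config$de_fraction * ifelse(meth, config$de_meth_bias, 1)

  de_calls <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    is_de <- runif(length(genes)) < de_p
    tibble(
      gene_id = genes, sample_a = pairs[1, j], sample_b = pairs[2, j],
      q_value = ifelse(is_de, runif(length(genes), 0, 0.049),
                       runif(length(genes), 0.05, 1)),
      fold_change = ifelse(is_de, 2 + rexp(length(genes), 1),
                           exp(abs(rnorm(length(genes), 0, 0.3)))),
      true_de = is_de
    )
  }) |>
    dplyr::mutate(is_de = .data$q_value < 0.05 & .data$fold_change > 2)

  base <- stats::rlnorm(length(genes), meanlog = 3, sdlog = 1)
  expression <- tidyr::crossing(
    tibble(gene_id = genes, base = base),
    sample = stages, replicate = seq_len(config$replicates)
  ) |>
    dplyr::mutate(fpkm = .data$base *
                    stats::rlnorm(dplyr::n(), 0, 0.2)) |>
    dplyr::select("gene_id", "sample", "replicate", "fpkm")

  list(expression = expression,
       de_calls = dplyr::select(de_calls, -"true_de"),
       truth = dplyr::select(de_calls, "gene_id", "sample_a", "sample_b",
                             "true_de"))
}

#' Simulate percent-spliced-in tables
#'
#' Places alternative-splicing events (SE, RI, A5, A3) inside simulated
#' genes and emits replicate-level PSI values. A `dse_fraction` of
#' events is made truly differential between embryo and one somatic
#' target tissue with |true delta PSI| >= 0.1; a small fraction of
#' observations is missing (as for zero-expression events).
#'
#' @inheritParams simulate_expression
#' @return list: `psi` (long tibble), `truth` (event_id, gene_id,
#'   target tissue, true_dpsi).
#' @export
simulate_psi <- function(config, annotation, stages = config$tissues) {
  set.seed(config$seed + 4000L)
  span <- gene_spans(annotation$genes)
  n_ev <- max(1L, round(config$psi_events_per_gene * nrow(span)))
  idx <- sample(nrow(span), n_ev, replace = TRUE)
  ev_len <- pmin(50L + rpois(n_ev, 100), span$end[idx] - span$start[idx] - 1L)
  ev_start <- span$start[idx] +
    floor(runif(n_ev) * (span$end[idx] - span$start[idx] - ev_len))
  somatic <- setdiff(stages, GERMLINE_TISSUES)
  is_dse <- runif(n_ev) < config$dse_fraction
  target <- sample(somatic, n_ev, replace = TRUE)
  true_dpsi <- ifelse(is_dse,
                      sample(c(-1, 1), n_ev, replace = TRUE) *
                        (0.1 + 0.2 * runif(n_ev)), 0)
  events <- tibble(
    event_id = sprintf("ev%05d", seq_len(n_ev)),
    event_type = sample(c("SE", "RI", "A5", "A3"), n_ev, replace = TRUE,
                        prob = c(0.4, 0.3, 0.15, 0.15)),
    gene_id = span$gene_id[idx], chrom = span$chrom[idx],
    start = as.integer(ev_start), end = as.integer(ev_start + ev_len),
    base_psi = 0.15 + 0.7 * rbeta(n_ev, 5, 2),
    target = target, true_dpsi = true_dpsi
  )
  psi <- tidyr::crossing(events, sample = stages,
                         replicate = seq_len(config$replicates)) |>
    dplyr::mutate(
      mu = .data$base_psi +
        ifelse(.data$sample == .data$target, .data$true_dpsi, 0),
      psi = pmin(pmax(.data$mu + rnorm(dplyr::n(), 0, config$psi_rep_sd),
                      0), 1),
      psi = ifelse(runif(dplyr::n()) < config$psi_missing_rate,
                   NA_real_, .data$psi)
    ) |>
    dplyr::select("event_id", "event_type", "chrom", "start", "end",
                  "sample", "replicate", "psi")
  list(psi = psi,
       truth = dplyr::select(events, "event_id", "gene_id", "event_type",
                             "target", "true_dpsi"))
}

#' Simulate read-level records for CH error-rate estimation
#'
#' Emulates the upstream read layer that flags, for each read
#' overlapping a reference CH site, whether its base pattern indicates
#' a CG dinucleotide there (a polymorphism relative to the reference).
#'
#' @param n_sites number of reference CH sites assessed.
#' @param coverage reads per site (Poisson mean).
#' @param polymorphism_rate probability a site is a true C>G variant
#'   (all its reads then indicate CG).
#' @param samples sample labels to emit.
#' @param seed RNG seed.
#' @return tibble `sample`, `site_id`, `read_id`, `indicates_cg`.
#' @export
simulate_ch_error_records <- function(n_sites = 1000, coverage = 50,
                                      polymorphism_rate = 0.02,
                                      samples = "head", seed = 1L) {
  set.seed(seed)
  purrr::map_dfr(samples, function(s) {
    is_var <- runif(n_sites) < polymorphism_rate
    depth <- rpois(n_sites, coverage)
    tibble(
      sample = s,
      site_id = rep(sprintf("chs%05d", seq_len(n_sites)), depth),
      indicates_cg = rep(is_var, depth)
    ) |>
      dplyr::mutate(read_id = sprintf("%s_rd%06d", .data$site_id,
                                      dplyr::row_number()))
  })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: annotation, methylome, read-level records,
#' expression and PSI tables, all from one configuration and seed.
#'
#' @param config a [sim_config()] object.
#' @param reads_per_exon passed to [simulate_reads()].
#' @return list of class `"bee_simulation"` with components
#'   `annotation`, `methylome`, `reads`, `expression`, `splicing` and
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(), reads_per_exon = 50) {
  annotation <- simulate_annotation(config)
  methylome <- simulate_methylome(config, annotation)
  reads <- simulate_reads(config, methylome, reads_per_exon = reads_per_exon)
  expression <- simulate_expression(config, annotation,
                                    methylome$truth$genes)
  splicing <- simulate_psi(config, annotation)
  structure(
    list(annotation = annotation, methylome = methylome, reads = reads,
         expression = expression, splicing = splicing, config = config),
    class = "bee_simulation"
  )
}

#' Write or read a simulation configuration as key=value text
#'
#' @param config a [sim_config()] object.
#' @param path output path.
#' @return `path` (write) or a `"bee_sim_config"` object (read).
#' @export
write_sim_config <- function(config, path) {
  fmt <- function(v) {
    if (is.null(names(v)) || all(names(v) == "")) {
      paste(v, collapse = ",")
    } else {
      paste(sprintf("%s:%s", names(v), v), collapse = ",")
    }
  }
  lines <- vapply(names(unclass(config)), function(k) {
    sprintf("%s=%s", k, fmt(config[[k]]))
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  parse_val <- function(s) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (all(grepl(":", parts, fixed = TRUE))) {
      nm <- sub(":.*", "", parts)
      v <- as.numeric(sub(".*:", "", parts))
      return(setNames(v, nm))
    }
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v)) parts else v
  }
  vals <- lapply(kv, function(x) parse_val(paste(x[-1], collapse = "=")))
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  int_fields <- c("seed", "n_genes", "genes_per_chrom", "replicates")
  for (f in intersect(int_fields, names(vals))) {
    vals[[f]] <- as.integer(vals[[f]])
  }
  do.call(sim_config, vals)
}

#' Write all simulation tables to a directory
#'
#' Emits exactly the package's on-disk layouts: gzip CX tables per
#' tissue and replicate, a GFF3 annotation, a FASTA genome, read-level,
#' expression, DE-call and PSI TSVs, the truth ledger, and the
#' configuration as key=value text.
#'
#' @param sim a `"bee_simulation"` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_sim_config(sim$config, p("config.txt"))
  write_genome_fasta(sim$annotation$genome, p("genome.fa"))
  write_annotation_gff3(sim$annotation$genes, p("annotation.gff3"))
  sm <- sim$methylome$sites
  for (t in unique(sm$tissue)) {
    for (r in unique(sm$replicate)) {
      sub <- dplyr::filter(sm, .data$tissue == t, .data$replicate == r)
      write_cx_table(sub, p(sprintf("meth_%s_rep%d.tsv.gz", t, r)))
    }
  }
  write_read_level(sim$reads, p("reads.tsv"))
  write_expression(sim$expression$expression, p("expression.tsv"))
  write_de_calls(sim$expression$de_calls, p("de_calls.tsv"))
  write_psi(sim$splicing$psi, p("psi.tsv"))
  readr::write_tsv(sim$methylome$truth$genes, p("truth_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$methylome$truth$exons, p("truth_exons.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$methylome$truth$dyads, p("truth_dyads.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$splicing$truth, p("truth_events.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' @param genes exon tibble (as from [read_annotation()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(genes, path) {
  span <- gene_spans(genes)
  gene_lines <- sprintf(
    "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    span$chrom, span$start + 1L, span$end, span$strand, span$gene_id)
  exon_lines <- sprintf(
    "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
    genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id)
  ord <- order(c(span$chrom, genes$chrom), c(span$start, genes$start),
               c(rep(0L, nrow(span)), rep(1L, nrow(genes))))
  readr::write_lines(c("##gff-version 3", c(gene_lines, exon_lines)[ord]),
                     path)
  invisible(path)
}
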