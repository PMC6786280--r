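## End-to-end orchestration: simulate (or load) inputs, aggregate,
## call differential methylation, build profiles, integrate expression
## and splicing, run the non-CG analysis, and write a machine-readable
## summary. Stages run in a fixed dependency order; every output
## directory records the configuration hash and seed, and reruns with
## an identical configuration are byte-identical for deterministic
## stages. Record counts are logged at every filter so threshold
## effects stay auditable.

#' Run the full analysis pipeline on a synthetic dataset
#'
#' @param config a [sim_config()] object; all randomness flows from
#'   its seed.
#' @param out_dir output directory (created; stage outputs, a
#'   `summary.json` and a `log.txt` are written there).
#' @param pairs list of 2-vectors of tissues to compare; default
#'   embryo vs each somatic tissue.
#' @param alpha_site,alpha_feature per-replicate Fisher significance
#'   levels at site and exon/gene resolution.
#' @param write_tables also write the simulated input tables to
#'   `out_dir/inputs` (default TRUE).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, pairs = NULL,
                         alpha_site = 0.001, alpha_feature = 0.05,
                         write_tables = TRUE) {
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  unlink(log_path)
  logline <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    inform(msg)
  }
  cfg_hash <- rlang::hash(unclass(config))
  logline("run: seed=%d config_hash=%s", config$seed, cfg_hash)

  logline("stage simulate")
  sim <- simulate_dataset(config)
  if (write_tables) write_simulation(sim, file.path(out_dir, "inputs"))
  genes <- sim$annotation$genes
  sites <- sim$methylome$sites
  cg <- dplyr::filter(sites, .data$context == "CG")
  logline("  %d CG site rows, %d genes", nrow(cg), dplyr::n_distinct(genes$gene_id))

  somatic <- setdiff(config$tissues, GERMLINE_TISSUES)
  if (is.null(pairs)) pairs <- lapply(somatic, function(t) c("embryo", t))

  logline("stage aggregate")
  exon_counts <- aggregate_counts(cg, genes, feature = "exon")
  gene_counts <- aggregate_counts(cg, genes, feature = "gene")
  exon_m_rep <- aggregate_methylation(cg, genes, feature = "exon")
  readr::write_tsv(exon_m_rep, file.path(out_dir, "exon_methylation.tsv"),
                   progress = FALSE)

  logline("stage dmcall")
  dm <- purrr::map(pairs, function(p) {
    list(
      sites = call_differential_methylation(
        aggregate_counts(dplyr::filter(cg, .data$tissue %in% p), genes,
                         feature = "site"),
        p, alpha = alpha_site, min_informative = 10),
      exons = call_differential_methylation(exon_counts, p,
                                            alpha = alpha_feature,
                                            min_informative = 20),
      genes = call_differential_methylation(gene_counts, p,
                                            alpha = alpha_feature,
                                            min_informative = 20)
    )
  })
  names(dm) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  for (nm in names(dm)) {
    readr::write_tsv(tidy(dm[[nm]]$exons),
                     file.path(out_dir, sprintf("dme_%s.tsv", nm)),
                     progress = FALSE)
  }
  dm_summary <- purrr::imap_dfr(dm, function(d, nm) {
    dplyr::bind_rows(
      dplyr::mutate(glance(d$sites), resolution = "site"),
      dplyr::mutate(glance(d$exons), resolution = "exon"),
      dplyr::mutate(glance(d$genes), resolution = "gene")
    ) |> dplyr::mutate(pair = nm, .before = 1)
  })
  logline("  %d comparisons x 3 resolutions", length(dm))

  logline("stage metaplot")
  embryo <- pool_replicates(dplyr::filter(cg, .data$tissue == "embryo"))
  prof <- gene_aligned_profile(embryo, genes, end = "5prime",
                               bin_width = 100,
                               region_filter = "exonic")
  readr::write_tsv(as_tibble(prof),
                   file.path(out_dir, "embryo_exonic_profile_5p.tsv"),
                   progress = FALSE)

  logline("stage classify")
  pooled_exon_m <- pool_replicates(exon_counts) |>
    dplyr::select("feature_id", "tissue", "level", "informative")
  states <- classify_exon_states(pooled_exon_m)
  state_props <- state_proportions(states)
  readr::write_tsv(state_props, file.path(out_dir, "exon_state_bins.tsv"),
                   progress = FALSE)
  read_props <- classify_reads(sim$reads)
  readr::write_tsv(read_props, file.path(out_dir, "read_classes.tsv"),
                   progress = FALSE)

  logline("stage integrate")
  resp <- gene_responsiveness(sim$expression$de_calls)
  readr::write_tsv(resp, file.path(out_dir, "responsiveness.tsv"),
                   progress = FALSE)
  gene_levels <- pool_replicates(gene_counts)
  methylated_genes <- gene_levels |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(meth = any(.data$level >= 0.1, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(.data$meth) |>
    dplyr::pull("feature_id")
  overlaps <- purrr::imap_dfr(dm, function(d, nm) {
    p <- strsplit(nm, "_vs_")[[1]]
    dmg <- d$genes$feature_id[d$genes$is_dm]
    deg <- sim$expression$de_calls |>
      dplyr::filter((.data$sample_a == p[1] & .data$sample_b == p[2]) |
                      (.data$sample_a == p[2] & .data$sample_b == p[1]),
                    .data$is_de) |>
      dplyr::pull("gene_id")
    all_genes <- unique(gene_levels$feature_id)
    both <- dplyr::bind_rows(
      dplyr::mutate(tidy(overlap_representation(
        dmg, intersect(deg, all_genes), all_genes)), universe = "all"),
      dplyr::mutate(tidy(overlap_representation(
        intersect(dmg, methylated_genes),
        intersect(deg, methylated_genes), methylated_genes)),
        universe = "methylated")
    )
    dplyr::mutate(both, pair = nm, .before = 1)
  })
  readr::write_tsv(overlaps, file.path(out_dir, "overlap_factors.tsv"),
                   progress = FALSE)
  dse <- purrr::map(pairs, function(p) call_dse(sim$splicing$psi, p))
  names(dse) <- names(dm)
  dse_summary <- purrr::imap_dfr(dse, function(d, nm) {
    dplyr::mutate(glance(d), pair = nm, .before = 1)
  })
  ## sample structure over methylated exons (level >= 0.1 in any sample)
  meth_exons <- pool_replicates(exon_counts) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(meth = any(.data$level >= 0.1, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(.data$meth)
  structure_res <- sample_structure(
    dplyr::semi_join(exon_m_rep, meth_exons, by = "feature_id"))

  logline("stage noncg")
  head_tissue <- grep("head", config$tissues, value = TRUE)
  noncg <- if (length(head_tissue)) {
    hs <- pool_replicates(dplyr::filter(sites,
                                        .data$tissue == head_tissue[1]))
    context_summary(hs)
  } else tibble()
  if (nrow(noncg)) {
    readr::write_tsv(noncg, file.path(out_dir, "context_summary.tsv"),
                     progress = FALSE)
  }

  summary <- list(
    config_hash = cfg_hash, seed = config$seed,
    n_genes = dplyr::n_distinct(genes$gene_id),
    n_cg_rows = nrow(cg),
    dm = dm_summary,
    state_bins = state_props,
    overlap = overlaps,
    dse = dse_summary,
    has_psi = TRUE
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("done")
  invisible(list(sim = sim, dm = dm, profile = prof, states = states,
                 state_proportions = state_props,
                 read_classes = read_props, responsiveness = resp,
                 overlaps = overlaps, dse = dse,
                 structure = structure_res, noncg = noncg,
                 summary = summary))
}

#' Build a plain-text report from a completed run directory
#'
#' Every reported number is read back from a stage output file, so the
#' report is regenerable and idempotent. Missing stages are marked
#' absent rather than failing.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return the report path, invisibly.
#' @export
make_report <- function(run_dir) {
  p <- function(...) file.path(run_dir, ...)
  lines <- c("methylation dynamics run report",
             strrep("=", 32))
  if (file.exists(p("summary.json"))) {
    s <- jsonlite::read_json(p("summary.json"))
    lines <- c(lines,
               sprintf("seed: %s  config: %s", s$seed, s$config_hash),
               sprintf("genes: %s  CG site rows: %s", s$n_genes, s$n_cg_rows))
  } else {
    lines <- c(lines, "summary.json: ABSENT (incomplete run)")
  }
  section <- function(file, title) {
    if (!file.exists(p(file))) {
      return(c("", sprintf("%s: ABSENT", title)))
    }
    tbl <- readr::read_tsv(p(file), col_types = readr::cols(),
                           progress = FALSE)
    c("", title, strrep("-", nchar(title)),
      utils::capture.output(print(as.data.frame(tbl), row.names = FALSE)))
  }
  lines <- c(lines,
             section("exon_state_bins.tsv", "exon methylation state bins"),
             section("read_classes.tsv", "single-read epiallele classes"),
             section("overlap_factors.tsv",
                     "DMG x DEG overlap representation factors"),
             section("context_summary.tsv", "non-CG context summary"))
  out <- p("report.txt")
  readr::write_lines(lines, out)
  invisible(out)
}
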