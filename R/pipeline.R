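# End-to-end orchestration of the two analyses with logging and a
# machine-readable run manifest.

stage_log <- function(manifest, stage, ...) {
  entry <- list(...)
  manifest$stages[[stage]] <- entry
  msg <- paste0("[", stage, "] ",
                paste(names(entry), vapply(entry, function(x)
                  paste(format(x), collapse = ","), character(1)),
                  sep = "=", collapse = " "))
  message(msg)
  manifest
}

new_manifest <- function(config, seeds) {
  list(package_version = as.character(packageVersion("divergesim")),
       config_digest = digest_config(config),
       seeds = seeds, stages = list())
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the demographic-inference pipeline
#'
#' Stages: locus extraction and filtering from the variant table, per-locus
#' summaries, reference-table construction for the eight models, model
#' choice (pooled across all eight, and the two-stage protocol that first
#' compares within the constant-Ne and changing-Ne groups and then the two
#' group winners), neural-network regression adjustment for the winning
#' model, and a posterior report (median/mean/mode and 2.5%/97.5% quantiles
#' per parameter).
#'
#' @param vt A `variant_table` of the observed (or pseudo-observed) data.
#' @param coverage Named callable-fraction-per-scaffold vector for locus
#'   extraction.
#' @param config A `run_config` (see [default_config()]); fields
#'   `n_retain_per_model` and `n_retain_best` set the reference-table sizes.
#' @param out_dir Optional output directory for the manifest and report.
#' @return List with `obs_summary`, `tables`, `model_choice` (pooled),
#'   `model_choice_two_stage`, `best_model`, `posterior`, `report` and
#'   `manifest`.
#' @export
run_demographic_inference <- function(vt, coverage, config = default_config(),
                                      out_dir = NULL) {
  cfg <- config
  manifest <- new_manifest(cfg, seeds = cfg$seed)
  lc <- locus_config(n_K = cfg$n_K, n_W = cfg$n_W, L = cfg$locus_length,
                     mu = cfg$mu, g = cfg$g)
  ex <- extract_abc_loci(vt, coverage, seed = cfg$seed,
                         n_target = cfg$n_loci,
                         locus_length = cfg$locus_length,
                         min_distance = cfg$locus_min_distance,
                         min_coverage = cfg$scaffold_min_coverage,
                         max_missing_individual = cfg$locus_missing_individual,
                         max_missing_mean = cfg$locus_missing_mean,
                         fst_max = cfg$locus_fst_max,
                         d_range = cfg$locus_d_range)
  if (is.null(ex$stats) || nrow(ex$stats) < 2)
    stop("locus extraction yielded fewer than 2 loci [stage extract_loci]")
  manifest <- stage_log(manifest, "extract_loci",
                        n_loci = nrow(ex$stats), excluded = ex$excluded)
  obs <- summarize_dataset(ex$stats)
  manifest <- stage_log(manifest, "summarize", n_stats = length(obs))
  n_retain <- cfg$n_retain_per_model
  if (is.null(n_retain)) n_retain <- 500
  n_loci_sim <- nrow(ex$stats)
  tables <- list()
  for (m in model_set()) {
    tables[[m]] <- build_reference_table(
      m, cfg$priors, n_loci = n_loci_sim, lc = lc,
      seed = cfg$seed + match(m, model_set()),
      n_retain = n_retain)
    manifest <- stage_log(manifest, paste0("reference_table_", m),
                          retained = nrow(tables[[m]]$stats),
                          executed = tables[[m]]$n_executed,
                          excluded = tables[[m]]$n_excluded)
  }
  mc <- abc_model_choice(obs, tables, cfg$tolerance_model_choice)
  manifest <- stage_log(manifest, "model_choice",
                        best = names(which.max(mc$mnlogistic)))
  # two-stage protocol: within group A, within group B, then the winners;
  # the tolerance is rescaled so each stage accepts the same number of rows
  # as the pooled comparison
  n_total <- sum(vapply(tables, function(x) nrow(x$stats), integer(1)))
  stage_tol <- function(tabs) {
    n <- sum(vapply(tabs, function(x) nrow(x$stats), integer(1)))
    min(1, cfg$tolerance_model_choice * n_total / n)
  }
  grp <- function(g) tables[paste0(MODEL_SCENARIOS, "-", g)]
  mc_A <- abc_model_choice(obs, grp("A"), stage_tol(grp("A")))
  mc_B <- abc_model_choice(obs, grp("B"), stage_tol(grp("B")))
  finalists <- c(names(which.max(mc_A$mnlogistic)),
                 names(which.max(mc_B$mnlogistic)))
  mc_final <- abc_model_choice(obs, tables[finalists],
                               stage_tol(tables[finalists]))
  manifest <- stage_log(manifest, "model_choice_two_stage",
                        finalists = finalists,
                        best = names(which.max(mc_final$mnlogistic)))
  best <- names(which.max(mc$mnlogistic))
  best_table <- tables[[best]]
  n_best <- cfg$n_retain_best
  if (!is.null(n_best) && n_best > nrow(best_table$stats)) {
    best_table <- build_reference_table(
      best, cfg$priors, n_loci = n_loci_sim, lc = lc,
      seed = cfg$seed + 100, n_retain = n_best)
    manifest <- stage_log(manifest, "reference_table_best",
                          retained = nrow(best_table$stats))
  }
  post <- nn_regression_adjust(obs, best_table, cfg$tolerance_estimate,
                               n_networks = cfg$n_networks,
                               seed = cfg$seed)
  manifest <- stage_log(manifest, "nn_regression",
                        n_accepted = nrow(post$adjusted))
  report <- post$summary
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(report, file.path(out_dir, "posterior_report.tsv"),
                sep = "\t", quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
  }
  list(obs_summary = obs, tables = tables, model_choice = mc,
       model_choice_group_A = mc_A, model_choice_group_B = mc_B,
       model_choice_two_stage = mc_final, best_model = best,
       posterior = post, report = report, manifest = manifest)
}

#' Run the divergence-scan pipeline
#'
#' Stages: SNP prefilter, 50-kb window scan, per-gene coding-region
#' statistics, stratified percentile outlier calling (F_ST high per
#' stratum; Tajima's D high/low per species per stratum), and permutation
#' GO enrichment on each gene-level outlier set against the stratum's
#' known-location genes.
#'
#' @param vt A `variant_table`.
#' @param genes A `gene_annotation`.
#' @param map A `scaffold_map`.
#' @param go A `go_annotation`.
#' @param config A `run_config`.
#' @param out_dir Optional output directory.
#' @return List with `windows`, `genes`, `outliers` (named list of
#'   `outlier_set`s), `enrichment` (named list of result tables) and
#'   `manifest`.
#' @export
run_divergence_scan <- function(vt, genes, map, go, config = default_config(),
                                out_dir = NULL) {
  cfg <- config
  manifest <- new_manifest(cfg, seeds = cfg$seed)
  vf <- snp_prefilter(vt, max_missing = cfg$snp_max_missing,
                      min_maf = cfg$snp_min_maf,
                      window = cfg$snp_window, window_max = cfg$snp_window_max)
  manifest <- stage_log(manifest, "snp_prefilter",
                        n_in = n_sites(vt), n_out = n_sites(vf),
                        removed = attr(vf, "n_removed"))
  win <- window_scan(vf, map, window_size = cfg$window_size,
                     min_length = cfg$window_min_length)
  manifest <- stage_log(manifest, "window_scan",
                        n_windows = nrow(win),
                        excluded_short = attr(win, "n_excluded_short"))
  gs <- per_gene_stats(vf, genes, map)
  manifest <- stage_log(manifest, "per_gene_stats", n_genes = nrow(gs))
  outliers <- list()
  for (stratum in c("autosome", "Z")) {
    outliers[[paste0("fst_", stratum)]] <-
      try(call_outliers(gs, "fst", cfg$fst_percentile, "high", stratum,
                        id_col = "gene_id"), silent = TRUE)
    for (sp in c("K", "W")) {
      st_col <- paste0("D_", sp)
      outliers[[paste0("d_high_", sp, "_", stratum)]] <-
        try(call_outliers(gs, st_col, cfg$d_high_percentile, "high", stratum,
                          signed_subset = TRUE, id_col = "gene_id"),
            silent = TRUE)
      outliers[[paste0("d_low_", sp, "_", stratum)]] <-
        try(call_outliers(gs, st_col, cfg$d_low_percentile, "low", stratum,
                          signed_subset = TRUE, id_col = "gene_id"),
            silent = TRUE)
    }
  }
  outliers <- Filter(function(x) !inherits(x, "try-error"), outliers)
  manifest <- stage_log(manifest, "outliers",
                        sets = length(outliers),
                        sizes = vapply(outliers, function(o)
                          length(o$members), integer(1)))
  enrich <- list()
  for (nm in names(outliers)) {
    o <- outliers[[nm]]
    stratum_genes <- gs$gene_id[gs$class == o$stratum & gs$known_location]
    members <- intersect(o$members, stratum_genes)
    if (length(members) == 0) {
      manifest <- stage_log(manifest, paste0("enrichment_", nm),
                            skipped = "empty outlier set")
      next
    }
    enrich[[nm]] <- permutation_enrichment(members, stratum_genes, go,
                                           seed = cfg$seed)
    manifest <- stage_log(manifest, paste0("enrichment_", nm),
                          n_genes = length(members),
                          significant = sum(enrich[[nm]]$significant))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_window_stats(win, bed_path = file.path(out_dir, "windows.bed"),
                       tsv_path = file.path(out_dir, "windows.tsv"))
    write.table(gs, file.path(out_dir, "gene_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in names(enrich))
      write.table(enrich[[nm]],
                  file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
  }
  list(windows = win, genes = gs, outliers = outliers, enrichment = enrich,
       manifest = manifest)
}
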