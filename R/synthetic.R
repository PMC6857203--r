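# Synthetic-data generation with known ground truth: pseudo-observed locus
# sets under any of the eight demographic models, and toy multi-scaffold
# genomes (VCF + GFF3 + scaffold map + GO table) with planted divergence
# islands and a planted enriched GO category.

#' Generate a pseudo-observed locus dataset
#'
#' Simulates `n_loci` independent loci under the requested model, pairs
#' haplotypes sequentially into diploids, injects per-genotype missingness,
#' and (optionally) writes a VCF in which each locus occupies its own
#' locus-length scaffold together with a sample-population map. The truth
#' ledger records everything needed to regenerate the dataset bit for bit.
#'
#' @param model Model label.
#' @param params A `parameter_set` (e.g. study posterior medians).
#' @param n_loci Number of loci.
#' @param lc A [locus_config()].
#' @param missingness Per-genotype missing probability (scalar or one value
#'   per diploid individual); must be < 1.
#' @param seed Integer seed.
#' @param vcf_path,popmap_path Optional output paths.
#' @return List with `vt` (the `variant_table`), `loci` (the simulated
#'   `haplotype_data` list), `stats` (per-locus statistics from the phased
#'   data), and `ledger` (a `truth_ledger`).
#' @export
make_pseudo_observed <- function(model, params, n_loci, lc,
                                 missingness = 0, seed,
                                 vcf_path = NULL, popmap_path = NULL) {
  n_ind <- (lc$n_K + lc$n_W) / 2
  if (lc$n_K %% 2 || lc$n_W %% 2)
    stop("need even haplotype counts to build diploids")
  miss <- rep(missingness, length.out = n_ind)
  if (any(miss >= 1) || any(miss < 0)) stop("missingness rates must be in [0, 1)")
  loci <- simulate_dataset(model, params, n_loci, lc, seed,
                           output = "haplotypes")
  stats <- vapply(loci, function(h) attr(h, "stats"), numeric(10))
  ids <- c(paste0("K_", seq_len(lc$n_K / 2)), paste0("W_", seq_len(lc$n_W / 2)))
  pops <- rep(c("K", "W"), c(lc$n_K / 2, lc$n_W / 2))
  set.seed(seed)
  scaffold <- character(0); pos <- integer(0)
  dos_all <- NULL
  for (i in seq_along(loci)) {
    h <- loci[[i]]
    dos <- diploidize(h$mat)
    if (ncol(dos)) {
      mask <- matrix(rbinom(length(dos), 1, rep(miss, ncol(dos))) == 1,
                     nrow = nrow(dos))
      dos[mask] <- NA
    }
    scaffold <- c(scaffold, rep(sprintf("locus_%03d", i), ncol(dos)))
    pos <- c(pos, h$positions + 1L)
    dos_all <- cbind(dos_all, dos)
  }
  contigs <- setNames(rep(lc$L, n_loci), sprintf("locus_%03d", seq_len(n_loci)))
  # deterministic ref/alt alleles derived from position
  ref <- c("A", "C", "G", "T")[pos %% 4 + 1]
  alt <- c("C", "G", "T", "A")[pos %% 4 + 1]
  vt <- variant_table(ids, pops, scaffold, pos, dos_all, ref, alt, contigs)
  ledger <- structure(list(kind = "pseudo_observed", model = model,
                           params = unclass(params), n_loci = n_loci,
                           locus_config = unclass(lc),
                           missingness = miss, seed = seed),
                      class = "truth_ledger")
  if (!is.null(vcf_path)) write_vcf(vt, vcf_path)
  if (!is.null(popmap_path))
    write.table(data.frame(ids, pops), popmap_path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  list(vt = vt, loci = loci, stats = stats, ledger = ledger)
}

#' Regenerate a pseudo-observed dataset from its truth ledger
#'
#' @param ledger A `truth_ledger` of kind `pseudo_observed`.
#' @param vcf_path,popmap_path Optional output paths.
#' @return As [make_pseudo_observed()].
#' @export
regenerate_pseudo_observed <- function(ledger, vcf_path = NULL,
                                       popmap_path = NULL) {
  stopifnot(inherits(ledger, "truth_ledger"), ledger$kind == "pseudo_observed")
  make_pseudo_observed(ledger$model,
                       structure(ledger$params, class = "parameter_set"),
                       ledger$n_loci,
                       structure(ledger$locus_config, class = "locus_config"),
                       ledger$missingness, ledger$seed,
                       vcf_path = vcf_path, popmap_path = popmap_path)
}

# Mean Weir-Cockerham F_ST across simulated loci for a symmetric two-island
# configuration at migration M (2NM per direction).
island_mean_fst <- function(M, Ne, T_years, lc, n_loci, seed) {
  p <- structure(list(T = T_years, Ne_K = Ne, Ne_W = Ne, Ne_A = Ne,
                      M_WtoK = M, M_KtoW = M), class = "parameter_set")
  st <- simulate_dataset("IM-A", p, n_loci, lc, seed, output = "stats")
  mean(st["fst", ], na.rm = TRUE)
}

# Mean within-population diversity per site for the same configuration.
island_mean_pi <- function(M, Ne, T_years, lc, n_loci, seed) {
  p <- structure(list(T = T_years, Ne_K = Ne, Ne_W = Ne, Ne_A = Ne,
                      M_WtoK = M, M_KtoW = M), class = "parameter_set")
  st <- simulate_dataset("IM-A", p, n_loci, lc, seed, output = "stats")
  mean(c(st["pi_K", ], st["pi_W", ]), na.rm = TRUE)
}

#' Tune the migration rate to hit a target F_ST
#'
#' Uses the monotone decreasing relationship between migration and mean
#' Weir-Cockerham F_ST in a symmetric two-population model at a deep split:
#' bisection on log10(M) with a fixed number of simulated loci per
#' evaluation.
#'
#' @param fst_target Target mean F_ST (must be below ~0.9 for the default
#'   sample sizes).
#' @param Ne Population size of both demes (diploids).
#' @param lc A [locus_config()].
#' @param T_years Split time (deep; default 8 Ne generations).
#' @param n_loci Loci per bisection evaluation.
#' @param seed Integer seed.
#' @param iters Bisection iterations.
#' @return The tuned migration rate M (2NM units).
#' @export
tune_migration_for_fst <- function(fst_target, Ne, lc,
                                   T_years = 8 * Ne * lc$g,
                                   n_loci = 500, seed = 1, iters = 12) {
  lo <- -3; hi <- 3 # log10(M)
  f_lo <- island_mean_fst(10^lo, Ne, T_years, lc, n_loci, seed)
  if (fst_target > f_lo)
    stop("F_ST target ", fst_target, " unreachable (maximum ~",
         round(f_lo, 3), " with this sample size)")
  f_hi <- island_mean_fst(10^hi, Ne, T_years, lc, n_loci, seed + 1)
  if (fst_target < f_hi) return(10^hi)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    f_mid <- island_mean_fst(10^mid, Ne, T_years, lc, n_loci, seed + 1 + i)
    if (f_mid > fst_target) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}

#' Generate a toy multi-scaffold genome with planted truth
#'
#' Background 50-kb windows are simulated under a high-migration symmetric
#' two-population coalescent tuned to the background F_ST target; island
#' windows use a reduced migration rate tuned to the island target, so the
#' elevated divergence arises mechanistically and all statistics co-vary
#' realistically. Genes are tiled across the scaffolds with multi-interval
#' CDS; a chosen GO category is preferentially assigned to island genes.
#'
#' @param n_scaffolds Number of scaffolds (last two are classed `Z` and
#'   `unassigned`; the rest autosomes).
#' @param scaffold_length Length of each scaffold in bp.
#' @param n_genes Total genes tiled over the scaffolds.
#' @param island_windows Data frame (scaffold index, window index) of
#'   planted islands, or an integer count placed deterministically on
#'   autosomes.
#' @param background_pi Target background nucleotide diversity per site.
#' @param fst_background,fst_island Target mean F_ST of the two strata.
#' @param go_spec List: `n_bp`, `n_cc` category counts per domain,
#'   `annot_rate` per-category membership probability, `planted_rate_island`
#'   and `planted_rate_background` membership probabilities of the planted
#'   category (`planted_cat`, domain `cellular_component`).
#' @param missingness Per-genotype missing probability.
#' @param n_ind Diploid individuals per population.
#' @param mu,g Mutation rate and generation time.
#' @param window_size Window/locus size in bp.
#' @param blocks_per_window Number of independent linkage blocks per window:
#'   each window is assembled from this many free-recombining coalescent
#'   blocks, emulating intra-window recombination so window statistics
#'   concentrate around the stratum targets.
#' @param seed Integer seed.
#' @param dir Output directory (created); set NULL to skip writing.
#' @return List with the file paths, the `variant_table`, annotations, the
#'   tuned migration rates and a `truth_ledger`.
#' @export
make_toy_genome <- function(n_scaffolds = 10, scaffold_length = 1e6,
                            n_genes = 1000, island_windows = 2,
                            background_pi = 2.6e-3,
                            fst_background = 0.046, fst_island = 0.6,
                            go_spec = list(n_bp = 8, n_cc = 8,
                                           annot_rate = 0.10,
                                           planted_cat = "GO:9000001",
                                           planted_rate_island = 0.85,
                                           planted_rate_background = 0.06),
                            missingness = 0.02, n_ind = 10,
                            mu = 0.8e-8, g = 2.5, window_size = 50000,
                            blocks_per_window = 10, seed = 1, dir = NULL) {
  block_size <- window_size / blocks_per_window
  lc <- locus_config(n_K = 2 * n_ind, n_W = 2 * n_ind, L = block_size,
                     mu = mu, g = g)
  # Initial size guess from the panmictic relation pi = 4*Ne*mu, then one
  # exact linear correction: at fixed 2NM migration every coalescent rate
  # scales as 1/Ne, so within-population diversity is exactly proportional
  # to Ne under the background demography.
  Ne0 <- background_pi / (4 * mu)
  M_bg <- tune_migration_for_fst(fst_background, Ne0, lc, seed = seed)
  pi0 <- island_mean_pi(M_bg, Ne0, 8 * Ne0 * g, lc, 300, seed + 2000)
  Ne <- Ne0 * background_pi / pi0
  windows_per_scaffold <- floor(scaffold_length / window_size)
  scaffs <- sprintf("scaffold_%02d", seq_len(n_scaffolds))
  classes <- c(rep("autosome", n_scaffolds - 2), "Z", "unassigned")
  # planted island windows (on autosomes, spread across scaffolds)
  if (is.numeric(island_windows) && length(island_windows) == 1) {
    n_isl <- island_windows
    island_windows <- data.frame(
      scaffold = seq_len(max(1, n_scaffolds - 2))[seq_len(n_isl)],
      window = 1 + (seq_len(n_isl) * 3) %% windows_per_scaffold)
  }
  # The migration -> F_ST mapping is invariant to Ne at fixed 2NM (both the
  # lineage-migration and coalescence rates scale as 1/Ne), so M_bg needs no
  # re-tuning after the size correction.
  M_isl <- tune_migration_for_fst(fst_island, Ne, lc, seed = seed + 1000)
  T_deep <- 8 * Ne * g
  p_bg <- structure(list(T = T_deep, Ne_K = Ne, Ne_W = Ne, Ne_A = Ne,
                         M_WtoK = M_bg, M_KtoW = M_bg),
                    class = "parameter_set")
  p_isl <- structure(list(T = T_deep, Ne_K = Ne, Ne_W = Ne, Ne_A = Ne,
                          M_WtoK = M_isl, M_KtoW = M_isl),
                     class = "parameter_set")
  tl_bg <- build_timeline(p_bg, "IM-A", g = g)
  tl_isl <- build_timeline(p_isl, "IM-A", g = g)
  theta <- locus_theta(mu, block_size)
  ids <- c(paste0("K_", seq_len(n_ind)), paste0("W_", seq_len(n_ind)))
  pops <- rep(c("K", "W"), each = n_ind)
  set.seed(seed)
  scaffold <- character(0); pos <- integer(0); dos_all <- list()
  island_coords <- NULL
  w_idx <- 0L
  for (s in seq_len(n_scaffolds)) {
    for (w in seq_len(windows_per_scaffold)) {
      w_idx <- w_idx + 1L
      isl <- any(island_windows$scaffold == s & island_windows$window == w) &&
        classes[s] == "autosome"
      tl <- if (isl) tl_isl else tl_bg
      # a window is a set of independent linkage blocks laid end to end
      hap <- NULL
      wpos <- integer(0)
      for (b in seq_len(blocks_per_window)) {
        res <- .sim_locus_haplotypes_cpp(
          unclass(tl), lc$n_K, lc$n_W, theta, block_size,
          as.double(derive_seed_r(seed, w_idx * 1000 + b)))
        if (ncol(res$haplotypes) == 0) next
        hap <- cbind(hap, res$haplotypes)
        wpos <- c(wpos, (b - 1L) * as.integer(block_size) + res$positions)
      }
      if (is.null(hap) || ncol(hap) == 0) next
      dos <- diploidize(hap)
      if (missingness > 0) {
        mask <- matrix(rbinom(length(dos), 1, missingness) == 1, nrow(dos))
        dos[mask] <- NA
      }
      start <- (w - 1L) * window_size
      scaffold <- c(scaffold, rep(scaffs[s], ncol(dos)))
      pos <- c(pos, start + wpos + 1L)
      dos_all[[length(dos_all) + 1L]] <- dos
      if (isl) island_coords <- rbind(island_coords,
        data.frame(scaffold = scaffs[s], start = start + 1L,
                   end = start + window_size))
    }
  }
  dos_all <- do.call(cbind, dos_all)
  ref <- c("A", "C", "G", "T")[pos %% 4 + 1]
  alt <- c("C", "G", "T", "A")[pos %% 4 + 1]
  contigs <- setNames(rep(scaffold_length, n_scaffolds), scaffs)
  vt <- variant_table(ids, pops, scaffold, pos, dos_all, ref, alt, contigs)
  smap <- scaffold_map(data.frame(scaffold = scaffs,
                                  chrom = c(paste0("chr", seq_len(n_scaffolds - 2)),
                                            "chrZ", "chrUn"),
                                  class = classes,
                                  index = seq_len(n_scaffolds)))
  # genes tiled evenly; 3 CDS exons of 600 bp within a 6-kb body
  genes_per_scaffold <- ceiling(n_genes / n_scaffolds)
  gene_rows <- list()
  gid <- 0L
  for (s in seq_len(n_scaffolds)) {
    step <- floor(scaffold_length / genes_per_scaffold)
    for (k in seq_len(genes_per_scaffold)) {
      if (gid >= n_genes) break
      gid <- gid + 1L
      gstart <- (k - 1L) * step + 1000L
      name <- sprintf("gene_%04d", gid)
      for (e in 0:2) {
        gene_rows[[length(gene_rows) + 1L]] <-
          data.frame(gene_id = name, scaffold = scaffs[s],
                     strand = if (k %% 2) "+" else "-",
                     start = gstart + e * 2000L, end = gstart + e * 2000L + 599L)
      }
    }
  }
  genes <- gene_annotation(do.call(rbind, gene_rows))
  # island genes: CDS overlapping a planted island window
  island_genes <- character(0)
  if (!is.null(island_coords)) {
    for (r in seq_len(nrow(island_coords))) {
      ov <- genes$scaffold == island_coords$scaffold[r] &
        genes$start <= island_coords$end[r] &
        genes$end >= island_coords$start[r]
      island_genes <- union(island_genes, genes$gene_id[ov])
    }
  }
  all_genes <- unique(genes$gene_id)
  # GO annotation: per-domain categories with random membership; the planted
  # category is enriched among island genes at the configured rates
  go_rows <- list()
  add_cats <- function(prefix, n_cat, domain) {
    for (ci in seq_len(n_cat)) {
      cat_id <- sprintf("GO:%s%04d", prefix, ci)
      memb <- all_genes[runif(length(all_genes)) < go_spec$annot_rate]
      if (length(memb))
        go_rows[[length(go_rows) + 1L]] <<-
          data.frame(gene = memb, category = cat_id, domain = domain)
    }
  }
  add_cats("10", go_spec$n_bp, "biological_process")
  add_cats("20", go_spec$n_cc, "cellular_component")
  pr <- ifelse(all_genes %in% island_genes,
               go_spec$planted_rate_island, go_spec$planted_rate_background)
  planted <- all_genes[runif(length(all_genes)) < pr]
  if (length(planted))
    go_rows[[length(go_rows) + 1L]] <-
      data.frame(gene = planted, category = go_spec$planted_cat,
                 domain = "cellular_component")
  go_df <- do.call(rbind, go_rows)
  go <- go_annotation(go_df, universe = all_genes)
  ledger <- structure(list(kind = "toy_genome", seed = seed,
                           n_scaffolds = n_scaffolds,
                           scaffold_length = scaffold_length,
                           n_genes = n_genes,
                           island_windows = island_windows,
                           island_coords = island_coords,
                           island_genes = island_genes,
                           background_pi = background_pi,
                           fst_background = fst_background,
                           fst_island = fst_island,
                           M_background = M_bg, M_island = M_isl,
                           Ne = Ne,
                           planted_category = go_spec$planted_cat,
                           go_spec = go_spec, missingness = missingness,
                           n_ind = n_ind, mu = mu, g = g,
                           window_size = window_size,
                           blocks_per_window = blocks_per_window),
                      class = "truth_ledger")
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "toy.vcf"),
                  popmap = file.path(dir, "popmap.tsv"),
                  gff = file.path(dir, "genes.gff3"),
                  scaffold_map = file.path(dir, "scaffold_map.tsv"),
                  go = file.path(dir, "go.tsv"),
                  ledger = file.path(dir, "truth.yaml"))
    write_vcf(vt, paths$vcf)
    write.table(data.frame(ids, pops), paths$popmap, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    gff <- c("##gff-version 3",
             sprintf("%s\tdivergesim\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                     genes$scaffold, genes$start, genes$end, genes$strand,
                     genes$gene_id))
    writeLines(gff, paths$gff)
    write.table(as.data.frame(smap), paths$scaffold_map, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(go_df, paths$go, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    yaml::write_yaml(lapply(unclass(ledger), function(x)
      if (is.data.frame(x)) as.list(x) else x), paths$ledger)
  }
  list(vt = vt, genes = genes, scaffold_map = smap, go = go,
       island_genes = island_genes, paths = paths, ledger = ledger,
       M_background = M_bg, M_island = M_isl)
}
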