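# Genome scan: SNP prefilter, 50-kb window statistics, per-gene coding-region
# statistics, stratified percentile outlier calling, and extraction of 10-kb
# loci for the demographic analysis.

#' SNP prefilter
#'
#' Keeps sites with missing fraction at most `max_missing` and minor-allele
#' frequency strictly above `min_maf`, then scans each scaffold left to
#' right and, whenever more than `window_max` retained SNPs fall within any
#' `window`-bp span, removes the rightmost excess site (greedy).
#'
#' @param vt A `variant_table`.
#' @param max_missing Maximum missing genotype fraction per site (0.10).
#' @param min_maf Minor-allele-frequency threshold, strict (0.05).
#' @param window Span in bp for the density rule (10).
#' @param window_max Maximum SNPs per span (3).
#' @return Filtered `variant_table` with attribute `n_removed` (per rule).
#' @export
snp_prefilter <- function(vt, max_missing = 0.10, min_maf = 0.05,
                          window = 10, window_max = 3) {
  if (n_sites(vt) == 0) stop("empty variant table")
  n <- length(vt$sample_ids)
  miss <- colSums(is.na(vt$dos)) / n
  called <- 2 * colSums(!is.na(vt$dos))
  alt <- colSums(vt$dos, na.rm = TRUE)
  p <- alt / called
  maf <- pmin(p, 1 - p)
  keep1 <- miss <= max_missing
  keep2 <- maf > min_maf
  keep <- keep1 & keep2
  # density rule on the surviving sites, per scaffold, greedy rightmost removal
  removed_density <- 0L
  idx_keep <- which(keep)
  final <- logical(length(keep))
  for (sc in unique(vt$scaffold)) {
    ii <- idx_keep[vt$scaffold[idx_keep] == sc]
    pos <- vt$pos[ii]
    sel <- rep(TRUE, length(ii))
    # a site is dropped (rightmost excess) when the window_max most recent
    # kept sites all lie within the same `window`-bp span as it
    recent <- integer(window_max) # ring buffer of last kept positions
    n_kept <- 0L
    for (i in seq_along(pos)) {
      if (n_kept >= window_max) {
        oldest <- recent[(n_kept %% window_max) + 1L]
        if (pos[i] - oldest <= window - 1L) {
          sel[i] <- FALSE
          removed_density <- removed_density + 1L
          next
        }
      }
      recent[(n_kept %% window_max) + 1L] <- pos[i]
      n_kept <- n_kept + 1L
    }
    final[ii[sel]] <- TRUE
  }
  out <- vt_subset(vt, which(final))
  attr(out, "n_removed") <- c(missing = sum(!keep1),
                              maf = sum(keep1 & !keep2),
                              density = removed_density)
  out
}

# Per-window or per-gene statistics from a dosage slice of a variant table.
region_stats <- function(vt, idx, length) {
  if (length(idx) == 0 || length == 0) {
    return(c(S = 0, pi_K = 0, pi_W = 0, D_K = NA, D_W = NA, D_pool = NA,
             fst = NA, dxy = 0, df = 0, r2 = NA))
  }
  locus_stats(vt$dos[, idx, drop = FALSE], pop = vt$pop, length = length,
              type = "dosage")
}

#' Windowed genome scan
#'
#' Tiles every scaffold with non-overlapping windows starting at position 1,
#' computes the per-locus statistics in each window, and drops windows whose
#' span within the scaffold is shorter than `min_length` (terminal
#' truncation; the scaffold length comes from the table's contig headers or,
#' failing that, the last SNP position). W-chromosome scaffolds are excluded
#' from the scan.
#'
#' @param vt Prefiltered `variant_table`.
#' @param map A `scaffold_map`.
#' @param window_size Window size in bp (50,000).
#' @param min_length Minimum window span in bp (25,000).
#' @return Data frame of windows (scaffold, start, end 1-based inclusive,
#'   class, the statistics) with attribute `n_windows` per class and
#'   `n_excluded_short`.
#' @export
window_scan <- function(vt, map, window_size = 50000, min_length = 25000) {
  rows <- list()
  n_short <- 0L
  sites_by_sc <- split(seq_len(n_sites(vt)), vt$scaffold)
  for (sc in unique(vt$scaffold)) {
    cls <- scaffold_class(map, sc)
    if (cls == "W") next
    len <- if (!is.null(vt$contig_lengths) && sc %in% names(vt$contig_lengths))
      vt$contig_lengths[[sc]] else max(vt$pos[vt$scaffold == sc])
    sc_sites <- sites_by_sc[[sc]]
    sc_pos <- vt$pos[sc_sites]
    starts <- seq(1L, len, by = window_size)
    for (st in starts) {
      en <- min(st + window_size - 1L, len)
      if (en - st + 1L < min_length) { n_short <- n_short + 1L; next }
      idx <- sc_sites[sc_pos >= st & sc_pos <= en]
      stats <- region_stats(vt, idx, en - st + 1L)
      rows[[length(rows) + 1L]] <-
        data.frame(scaffold = sc, start = st, end = en, class = cls,
                   as.list(stats))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_windows") <- table(out$class)
  attr(out, "n_excluded_short") <- n_short
  out
}

#' Per-gene coding-region statistics
#'
#' Statistics over the merged CDS sites of each gene. Genes on scaffolds
#' classed `unassigned` are flagged (`known_location = FALSE`) and excluded
#' from percentile analyses downstream; genes without CDS SNPs are retained
#' with undefined statistics.
#'
#' @param vt Prefiltered `variant_table`.
#' @param genes A `gene_annotation`.
#' @param map A `scaffold_map`.
#' @return Data frame, one row per gene (gene_id, scaffold, class,
#'   known_location, cds_length, the statistics).
#' @export
per_gene_stats <- function(vt, genes, map) {
  sites_by_sc <- split(seq_len(n_sites(vt)), vt$scaffold)
  cls_by_sc <- setNames(suppressWarnings(scaffold_class(map, names(sites_by_sc))),
                        names(sites_by_sc))
  rows <- lapply(split(seq_len(nrow(genes)), genes$gene_id), function(ii) {
    g <- genes[ii, , drop = FALSE]
    sc <- g$scaffold[1]
    cls <- if (sc %in% names(cls_by_sc)) cls_by_sc[[sc]] else
      scaffold_class(map, sc)
    cds_len <- sum(g$end - g$start + 1L)
    sc_sites <- sites_by_sc[[sc]]
    idx <- integer(0)
    if (!is.null(sc_sites)) {
      p <- vt$pos[sc_sites]
      for (r in seq_len(nrow(g)))
        idx <- c(idx, sc_sites[p >= g$start[r] & p <= g$end[r]])
    }
    idx <- sort(unique(idx))
    stats <- region_stats(vt, idx, cds_len)
    data.frame(gene_id = g$gene_id[1], scaffold = sc, class = cls,
               known_location = cls != "unassigned",
               cds_length = cds_len, n_snps = length(idx), as.list(stats))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call percentile outliers within a stratum
#'
#' The cutoff is the empirical type-7 quantile (linear interpolation, R's
#' default) of the defined values within the requested stratum; members lie
#' strictly beyond it. For Tajima's D the convention is: high outliers from
#' the 95th percentile of the positive values, low outliers from the 5th
#' percentile of the negative values.
#'
#' @param stats Data frame from [window_scan()] or [per_gene_stats()].
#' @param statistic Column to threshold (e.g. `"fst"`, `"D_K"`).
#' @param percentile Quantile level in (0,1).
#' @param direction `"high"` or `"low"`.
#' @param stratum Chromosome class to analyse (`"autosome"` or `"Z"`).
#' @param signed_subset For Tajima's D: restrict the quantile computation to
#'   positive (`direction = "high"`) or negative (`"low"`) values first.
#' @param min_defined Minimum defined values required in the stratum.
#' @param id_col Column identifying members.
#' @return An `outlier_set`: list with `statistic`, `cutoff`, `direction`,
#'   `members`, `percentile`, `stratum`.
#' @export
call_outliers <- function(stats, statistic, percentile,
                          direction = c("high", "low"), stratum,
                          signed_subset = FALSE, min_defined = 20,
                          id_col = NULL) {
  direction <- match.arg(direction)
  df <- stats[stats$class == stratum, , drop = FALSE]
  if (!is.null(df$known_location)) df <- df[df$known_location, , drop = FALSE]
  v <- df[[statistic]]
  ok <- !is.na(v)
  vv <- v[ok]
  if (signed_subset) vv <- if (direction == "high") vv[vv > 0] else vv[vv < 0]
  if (length(vv) < min_defined)
    stop("fewer than ", min_defined, " defined values in stratum ", stratum)
  cutoff <- unname(quantile(vv, percentile, type = 7))
  sel <- ok & if (direction == "high") v > cutoff else v < cutoff
  ids <- if (!is.null(id_col)) df[[id_col]][sel] else which(sel)
  structure(list(statistic = statistic, cutoff = cutoff,
                 direction = direction, members = ids,
                 percentile = percentile, stratum = stratum,
                 n_defined = sum(ok)),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat("<outlier_set> ", x$statistic, " ", x$direction, " of ",
      signif(x$cutoff, 4), " (", x$percentile * 100, "th pct, ", x$stratum,
      "): ", length(x$members), " members\n", sep = "")
  invisible(x)
}

#' Extract candidate 10-kb loci for the demographic analysis
#'
#' Random non-overlapping loci on scaffolds with callable coverage above
#' `min_coverage`, pairwise distance above `min_distance` within a scaffold,
#' deterministic given the seed. Loci violating the missingness rules (over
#' `max_missing_individual` in any individual or `max_missing_mean` on
#' average) are dropped, then loci with F_ST above `fst_max` or pooled
#' Tajima's D outside `d_range`.
#'
#' @param vt Prefiltered `variant_table`.
#' @param coverage Named vector: callable fraction per scaffold.
#' @param seed Integer seed.
#' @param n_target Stop after this many retained loci (Inf = all).
#' @param locus_length Locus length in bp (10,000).
#' @param min_distance Minimum distance between locus starts (500,000).
#' @param min_coverage Scaffold coverage threshold (0.80).
#' @param max_missing_individual,max_missing_mean Missingness rules.
#' @param fst_max,d_range Statistic filter.
#' @return List with `loci` (data frame scaffold/start/end), `stats` (matrix
#'   of per-locus statistics), and `excluded` (tallies per rule).
#' @export
extract_abc_loci <- function(vt, coverage, seed, n_target = Inf,
                             locus_length = 1e4, min_distance = 5e5,
                             min_coverage = 0.80,
                             max_missing_individual = 0.40,
                             max_missing_mean = 0.30,
                             fst_max = 0.159, d_range = c(0, 1)) {
  set.seed(seed)
  scaffs <- names(coverage)[coverage > min_coverage]
  scaffs <- intersect(scaffs, unique(vt$scaffold))
  if (length(scaffs) == 0) stop("no scaffold passes the coverage threshold")
  excl <- c(missing_individual = 0L, missing_mean = 0L, stat_filter = 0L,
            no_snps = 0L)
  loci <- list()
  stats <- list()
  sites_by_sc <- split(seq_len(n_sites(vt)), vt$scaffold)
  for (sc in sample(scaffs)) {
    len <- if (!is.null(vt$contig_lengths) && sc %in% names(vt$contig_lengths))
      vt$contig_lengths[[sc]] else max(vt$pos[vt$scaffold == sc])
    if (len < locus_length) next
    sc_sites <- sites_by_sc[[sc]]
    sc_pos <- vt$pos[sc_sites]
    n_starts <- len - locus_length + 1L
    # candidate starts, capped: spacing allows only ~len/min_distance loci
    n_cand <- min(n_starts, max(50L, 20L * ceiling(len / min_distance)))
    cand <- if (n_cand == n_starts) sample.int(n_starts) else
      sample.int(n_starts, n_cand)
    chosen <- integer(0)
    for (st in cand) {
      if (length(loci) + 0 >= n_target) break
      if (any(abs(st - chosen) < min_distance + locus_length)) next
      en <- st + locus_length - 1L
      idx <- sc_sites[sc_pos >= st & sc_pos <= en]
      if (length(idx) == 0) { excl["no_snps"] <- excl["no_snps"] + 1L;
        chosen <- c(chosen, st); next }
      dos <- vt$dos[, idx, drop = FALSE]
      miss_ind <- rowSums(is.na(dos)) / ncol(dos)
      chosen <- c(chosen, st)
      if (any(miss_ind > max_missing_individual)) {
        excl["missing_individual"] <- excl["missing_individual"] + 1L; next }
      if (mean(miss_ind) > max_missing_mean) {
        excl["missing_mean"] <- excl["missing_mean"] + 1L; next }
      st_vec <- region_stats(vt, idx, locus_length)
      if ((!is.na(st_vec["fst"]) && st_vec["fst"] > fst_max) ||
          (!is.na(st_vec["D_pool"]) &&
           (st_vec["D_pool"] < d_range[1] || st_vec["D_pool"] > d_range[2]))) {
        excl["stat_filter"] <- excl["stat_filter"] + 1L; next }
      loci[[length(loci) + 1L]] <- data.frame(scaffold = sc, start = st,
                                              end = en)
      stats[[length(stats) + 1L]] <- st_vec
    }
    if (length(loci) >= n_target) break
  }
  list(loci = do.call(rbind, loci),
       stats = if (length(stats)) do.call(rbind, stats) else NULL,
       excluded = excl)
}

#' Write window statistics as BED and TSV
#'
#' BED uses 0-based half-open coordinates; the TSV mirror is 1-based
#' inclusive.
#'
#' @param windows Data frame from [window_scan()].
#' @param bed_path,tsv_path Output paths (NULL to skip).
#' @return Invisibly, the window data frame.
#' @export
write_window_stats <- function(windows, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    ic <- to_internal_coords(windows$start, windows$end)
    bed <- data.frame(windows$scaffold, ic$start, ic$end,
                      paste0("window_", seq_len(nrow(windows))),
                      round(ifelse(is.na(windows$fst), 0, windows$fst), 6))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    write.table(windows, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(windows)
}
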