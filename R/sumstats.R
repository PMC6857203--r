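# Per-locus population-genetic summary statistics.
#
# Two input flavours share one core: phased binary haplotype matrices
# (simulated data; rows = haplotypes) and unphased allele-dosage matrices
# (observed data; rows = diploid individuals, entries 0/1/2/NA). Missing data
# are handled by pairwise-complete per-site allele counts.

# Per-site derived-allele count c and called chromosome count m.
allele_counts <- function(x, type = c("haplotype", "dosage")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  called <- colSums(!is.na(x))
  if (type == "haplotype") {
    list(c = colSums(x, na.rm = TRUE), m = called)
  } else {
    list(c = colSums(x, na.rm = TRUE), m = 2 * called)
  }
}

#' Nucleotide diversity per site
#'
#' Average number of pairwise differences per site: at each site with at
#' least two called chromosomes the unbiased estimator `2*c*(m-c)/(m*(m-1))`
#' is accumulated and the sum divided by the callable length.
#'
#' @param x Haplotype (0/1) or dosage (0/1/2) matrix; `NA` = missing.
#' @param length Callable length in bp over which the sites were ascertained.
#' @param type `"haplotype"` (rows are haplotypes) or `"dosage"` (rows are
#'   diploid individuals).
#' @return Diversity per site.
#' @export
nucleotide_diversity <- function(x, length, type = c("haplotype", "dosage")) {
  if (length <= 0) stop("length must be positive")
  ac <- allele_counts(x, type)
  ok <- ac$m >= 2
  sum(2 * ac$c[ok] * (ac$m[ok] - ac$c[ok]) / (ac$m[ok] * (ac$m[ok] - 1))) / length
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (pi_hat - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' constants; `pi_hat` is the summed (not per-site) mean pairwise difference.
#' The nominal chromosome count of the sample is used in the constants;
#' missing genotypes enter only through the per-site allele counts.
#'
#' @inheritParams nucleotide_diversity
#' @return D, or `NA` when fewer than 3 segregating sites or fewer than 4
#'   chromosomes make it undefined.
#' @export
tajimas_d <- function(x, type = c("haplotype", "dosage")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  n <- if (type == "haplotype") nrow(x) else 2 * nrow(x)
  if (n < 4) return(NA_real_)
  ac <- allele_counts(x, type)
  seg <- ac$c > 0 & ac$c < ac$m
  S <- sum(seg)
  if (S < 3) return(NA_real_)
  ok <- seg & ac$m >= 2
  pi_hat <- sum(2 * ac$c[ok] * (ac$m[ok] - ac$c[ok]) / (ac$m[ok] * (ac$m[ok] - 1)))
  k <- tajima_constants(n)
  (pi_hat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Pair phased haplotypes into diploid individuals
#'
#' Rows `1,2` form individual 1, rows `3,4` individual 2, and so on;
#' the result is a dosage matrix. Simulated phased data are passed through
#' this before the diploid F_ST estimator so simulated and observed data
#' flow through the identical code.
#'
#' @param hap Binary haplotype matrix with an even number of rows.
#' @return Dosage matrix (individuals x sites).
#' @export
diploidize <- function(hap) {
  n <- nrow(hap)
  if (n %% 2 != 0) stop("need an even number of haplotypes to diploidize")
  hap[seq(1, n, by = 2), , drop = FALSE] + hap[seq(2, n, by = 2), , drop = FALSE]
}

#' Weir-Cockerham F_ST
#'
#' Per-site variance components of Weir & Cockerham (1984) for two
#' populations of diploids (`a` among populations, `b` among individuals
#' within populations, `c` within individuals), aggregated as the ratio of
#' sums `sum(a) / sum(a+b+c)`. Sites with fewer than two called genotypes in
#' either population are dropped; negative estimates are reported as-is.
#'
#' @param dosages Dosage matrix (individuals x sites, 0/1/2, `NA` missing);
#'   phased haplotype matrices should be passed through [diploidize()] first.
#' @param pop Population label per individual (two levels).
#' @return List with `fst` and the per-site component matrix `components`
#'   (columns `a`, `b`, `c`); `fst` is `NA` when no site is informative.
#' @export
wc_fst <- function(dosages, pop) {
  dosages <- as.matrix(dosages)
  pop <- as.character(pop)
  lv <- unique(pop)
  if (length(lv) != 2) stop("wc_fst needs exactly two populations")
  g1 <- dosages[pop == lv[1], , drop = FALSE]
  g2 <- dosages[pop == lv[2], , drop = FALSE]
  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  keep <- n1 >= 2 & n2 >= 2
  comp <- matrix(NA_real_, ncol(dosages), 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  if (any(keep)) {
    n1 <- n1[keep]; n2 <- n2[keep]
    p1 <- colSums(g1[, keep, drop = FALSE], na.rm = TRUE) / (2 * n1)
    p2 <- colSums(g2[, keep, drop = FALSE], na.rm = TRUE) / (2 * n2)
    h1 <- colSums(g1[, keep, drop = FALSE] == 1, na.rm = TRUE) / n1
    h2 <- colSums(g2[, keep, drop = FALSE] == 1, na.rm = TRUE) / n2
    nsum <- n1 + n2
    nbar <- nsum / 2
    nc <- nsum - (n1^2 + n2^2) / nsum
    pbar <- (n1 * p1 + n2 * p2) / nsum
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / nsum
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
    comp[keep, ] <- cbind(a, b, hbar / 2)
  }
  kept <- !is.na(comp[, 1])
  den <- sum(comp[kept, ])
  fst <- if (!any(kept) || den == 0) NA_real_ else sum(comp[kept, "a"]) / den
  list(fst = fst, components = comp)
}

#' Absolute divergence d_XY and fixed differences d_f
#'
#' `d_XY` is the mean per-site between-population pairwise difference (Nei):
#' `p1*(1-p2) + p2*(1-p1)` per site, summed and divided by length. `d_f`
#' counts sites where the two populations share no allele.
#'
#' @param x Haplotype or dosage matrix.
#' @param pop Population label per row.
#' @param length Callable length in bp.
#' @param type Input flavour, as in [nucleotide_diversity()].
#' @return List with `dxy` and `df`.
#' @export
dxy_and_df <- function(x, pop, length, type = c("haplotype", "dosage")) {
  type <- match.arg(type)
  if (length <= 0) stop("length must be positive")
  x <- as.matrix(x)
  pop <- as.character(pop)
  lv <- unique(pop)
  if (length(lv) != 2) stop("need exactly two populations")
  ac1 <- allele_counts(x[pop == lv[1], , drop = FALSE], type)
  ac2 <- allele_counts(x[pop == lv[2], , drop = FALSE], type)
  ok <- ac1$m >= 1 & ac2$m >= 1
  p1 <- ac1$c[ok] / ac1$m[ok]
  p2 <- ac2$c[ok] / ac2$m[ok]
  dxy <- sum(p1 * (1 - p2) + p2 * (1 - p1)) / length
  df <- sum((p1 == 1 & p2 == 0) | (p1 == 0 & p2 == 1))
  list(dxy = dxy, df = df)
}

#' Mean pairwise linkage disequilibrium r^2 within a locus
#'
#' Squared Pearson correlation of allele content across all pairs of
#' polymorphic sites, averaged. On dosages this is the standard unphased
#' genotype-correlation r^2; on haplotype matrices it is the classical
#' `D^2/(p_A q_A p_B q_B)`.
#'
#' @inheritParams nucleotide_diversity
#' @return Mean r^2, or `NA` with fewer than 2 polymorphic sites.
#' @export
mean_r2 <- function(x, type = c("haplotype", "dosage")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  ac <- allele_counts(x, type)
  poly <- ac$c > 0 & ac$c < ac$m
  if (sum(poly) < 2) return(NA_real_)
  cc <- suppressWarnings(cor(x[, poly, drop = FALSE],
                             use = "pairwise.complete.obs"))
  r2 <- cc[upper.tri(cc)]^2
  if (all(is.na(r2))) return(NA_real_)
  mean(r2, na.rm = TRUE)
}

STAT_ORDER <- c("S", "pi_K", "pi_W", "D_K", "D_W", "D_pool", "fst", "dxy",
                "df", "r2")

#' Compute the full per-locus statistic vector
#'
#' Assembles the ten per-locus statistics in the package's declared order
#' (`S, pi_K, pi_W, D_K, D_W, D_pool, fst, dxy, df, r2`). For phased input,
#' F_ST is computed on sequentially diploidized genotypes so simulated and
#' observed data flow through the identical estimator.
#'
#' @param x Haplotype matrix with `pop` per row, or dosage matrix with `pop`
#'   per individual, or a `haplotype_data` object (then `pop`/`length` are
#'   taken from it).
#' @param pop Population labels (`"K"`/`"W"`).
#' @param length Callable length in bp.
#' @param type Input flavour.
#' @param r2_type Which r^2 flavour to report: `"haplotype"` is only
#'   available for phased input; simulated reference tables use it, observed
#'   unphased data fall back to dosage correlation (the choice is recorded by
#'   the caller's configuration).
#' @return Named numeric vector of the ten statistics.
#' @export
locus_stats <- function(x, pop = NULL, length = NULL,
                        type = c("haplotype", "dosage"),
                        r2_type = NULL) {
  type <- match.arg(type)
  if (inherits(x, "haplotype_data")) {
    pop <- x$pop
    length <- x$L
    x <- x$mat
    type <- "haplotype"
  }
  x <- as.matrix(x)
  if (is.null(r2_type) || type == "dosage") r2_type <- type
  xK <- x[pop == "K", , drop = FALSE]
  xW <- x[pop == "W", , drop = FALSE]
  acK <- allele_counts(xK, type)
  acW <- allele_counts(xW, type)
  S <- sum((acK$c + acW$c) > 0 & (acK$c + acW$c) < (acK$m + acW$m))
  if (type == "haplotype") {
    dos <- rbind(diploidize(xK), diploidize(xW))
    dpop <- rep(c("K", "W"), c(nrow(xK) / 2, nrow(xW) / 2))
  } else {
    dos <- x
    dpop <- pop
  }
  dd <- dxy_and_df(x, pop, length, type)
  c(S = S,
    pi_K = nucleotide_diversity(xK, length, type),
    pi_W = nucleotide_diversity(xW, length, type),
    D_K = tajimas_d(xK, type),
    D_W = tajimas_d(xW, type),
    D_pool = tajimas_d(x, type),
    fst = wc_fst(dos, dpop)$fst,
    dxy = dd$dxy,
    df = dd$df,
    r2 = if (r2_type == "haplotype") mean_r2(x, "haplotype") else
      mean_r2(dos, "dosage"))
}

DEFAULT_SUMMARY_STATS <- c("pi_K", "pi_W", "D_K", "D_W", "fst", "dxy", "r2")

#' Across-locus summary vector for ABC
#'
#' Means and variances of the selected per-locus statistics, in a fixed
#' declared order (`mean_<stat>...` then `var_<stat>...`). Loci where a
#' statistic is undefined are excluded from that statistic's moments and
#' counted. The across-locus mean of pooled Tajima's D is attached as
#' attribute `mean_D_pool` for the simulation-level filter, and exclusion
#' counts as attribute `n_undefined`.
#'
#' @param stats Matrix of per-locus statistics: either 10 x n_loci (rows in
#'   `STAT_ORDER`, the simulator layout) or n_loci x 10.
#' @param select Statistics to summarize (default declared set).
#' @return Named summary vector (class `summary_vector`).
#' @export
summarize_dataset <- function(stats, select = DEFAULT_SUMMARY_STATS) {
  stats <- as.matrix(stats)
  if (!is.null(rownames(stats)) && all(STAT_ORDER %in% rownames(stats))) {
    stats <- t(stats[STAT_ORDER, , drop = FALSE])
  }
  if (is.null(colnames(stats))) stop("per-locus statistics must be named")
  if (nrow(stats) < 2) stop("need at least two loci")
  mis <- setdiff(select, colnames(stats))
  if (length(mis)) stop("unknown statistics: ", paste(mis, collapse = ", "))
  n_und <- integer(length(select))
  names(n_und) <- select
  mns <- vars <- numeric(length(select))
  for (i in seq_along(select)) {
    v <- stats[, select[i]]
    n_und[i] <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) < 2)
      stop("statistic undefined for (almost) all loci: ", select[i])
    mns[i] <- mean(v)
    vars[i] <- var(v)
  }
  out <- c(mns, vars)
  names(out) <- c(paste0("mean_", select), paste0("var_", select))
  dp <- stats[, "D_pool"]
  fst <- stats[, "fst"]
  structure(out, class = c("summary_vector", "numeric"),
            mean_D_pool = mean(dp[!is.na(dp)]),
            mean_fst = mean(fst[!is.na(fst)]),
            n_undefined = n_und)
}

#' Write per-locus statistics and a dataset summary as TSV
#'
#' One row per locus in the declared statistic order, and optionally a
#' one-row dataset file with the summary vector.
#'
#' @param stats Per-locus statistic matrix (either orientation, as accepted
#'   by [summarize_dataset()]).
#' @param locus_path Output TSV for the per-locus rows.
#' @param summary_path Optional TSV for the across-locus summary vector.
#' @param select Statistics entering the summary.
#' @return The summary vector, invisibly.
#' @export
write_locus_stats <- function(stats, locus_path, summary_path = NULL,
                              select = DEFAULT_SUMMARY_STATS) {
  m <- as.matrix(stats)
  if (!is.null(rownames(m)) && all(STAT_ORDER %in% rownames(m)))
    m <- t(m[STAT_ORDER, , drop = FALSE])
  df <- data.frame(locus = seq_len(nrow(m)), m, check.names = FALSE)
  write.table(df, locus_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sv <- summarize_dataset(stats, select = select)
  if (!is.null(summary_path))
    write.table(as.data.frame(t(unclass(sv))), summary_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(sv)
}
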