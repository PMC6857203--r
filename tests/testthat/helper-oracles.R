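# Independent brute-force oracles. These deliberately re-derive every
# statistic from first principles (pairwise loops, direct formulas) and stay
# independent of the package's vectorized/compiled implementations.

bf_pi <- function(hap, L) {
  n <- nrow(hap)
  if (!anyNA(hap)) {
    # complete data: plain mean over all haplotype pairs
    tot <- 0
    np <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      tot <- tot + sum(hap[i, ] != hap[j, ])
      np <- np + 1
    }
    return(tot / np / L)
  }
  # missing data: per-site mean over the pairs available at that site
  persite <- 0
  for (s in seq_len(ncol(hap))) {
    col <- hap[, s]
    col <- col[!is.na(col)]
    m <- length(col)
    if (m < 2) next
    d <- sum(col)
    persite <- persite + d * (m - d) / choose(m, 2)
  }
  persite / L
}

bf_tajima <- function(hap) {
  n <- nrow(hap)
  if (n < 4) return(NA_real_)
  cc <- colSums(hap)
  seg <- cc > 0 & cc < n
  S <- sum(seg)
  if (S < 3) return(NA_real_)
  # mean pairwise difference, direct double loop
  pi_hat <- 0
  np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi_hat <- pi_hat + sum(hap[i, ] != hap[j, ])
    np <- np + 1
  }
  pi_hat <- pi_hat / np
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) for two diploid populations, evaluated site by
# site from their published component formulas (r = 2).
bf_wc_fst <- function(dos, pop) {
  lv <- unique(pop)
  A <- B <- C <- 0
  for (s in seq_len(ncol(dos))) {
    g1 <- dos[pop == lv[1], s]; g1 <- g1[!is.na(g1)]
    g2 <- dos[pop == lv[2], s]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2 || n2 < 2) next
    r <- 2
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  if (A + B + C == 0) return(NA_real_)
  A / (A + B + C)
}

bf_dxy_df <- function(hap, pop, L) {
  lv <- unique(pop)
  h1 <- hap[pop == lv[1], , drop = FALSE]
  h2 <- hap[pop == lv[2], , drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(h1))) for (j in seq_len(nrow(h2)))
    tot <- tot + sum(h1[i, ] != h2[j, ])
  dxy <- tot / (nrow(h1) * nrow(h2)) / L
  df <- 0
  for (s in seq_len(ncol(hap)))
    if (length(intersect(unique(h1[, s]), unique(h2[, s]))) == 0) df <- df + 1
  list(dxy = dxy, df = df)
}

bf_mean_r2 <- function(mat) {
  poly <- apply(mat, 2, function(v) length(unique(v[!is.na(v)])) > 1)
  mat <- mat[, poly, drop = FALSE]
  k <- ncol(mat)
  if (k < 2) return(NA_real_)
  vals <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    vals <- c(vals, suppressWarnings(cor(mat[, i], mat[, j],
                                         use = "complete.obs"))^2)
  mean(vals, na.rm = TRUE)
}

# Step-up BH, spelled out from the definition.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Independent Monte-Carlo oracle constants (msprime + direct formulas),
# frozen from runs at 2e4 replicates:
#   neutral panmictic sample, n = 20 haplotypes, theta_locus = 5,
#   Tajima's D averaged over replicates with S >= 3.
ORACLE_NULL_D_MEAN <- -0.07515
ORACLE_NULL_D_SE <- 0.00644

# Table of posterior medians used as simulation truth for the recovery runs
# (split time in years, sizes in diploids, migration in 2NM individuals per
# generation).
truth_params <- function() {
  structure(list(T = 0.863e6, T1 = 0.059e6, Ne_K = 3.581e6, Ne_W = 0.649e6,
                 Ne_A = 0.752e6, N0_K = 0.086e6, N0_W = 0.082e6,
                 M_WtoK = 236.503, M_KtoW = 51.476),
            class = "parameter_set")
}

panmictic_timeline <- function(x = 1) {
  structure(rbind(c(0, x, 0, x, 0, 0, 0, 1)),
            class = c("timeline", "matrix"))
}

two_pop_params <- function(T = 2e6, Ne = 2e5, M = 0) {
  structure(list(T = T, Ne_K = Ne, Ne_W = Ne, Ne_A = Ne,
                 M_WtoK = M, M_KtoW = M), class = "parameter_set")
}

random_hap_matrix <- function(n, S, seed, miss = 0) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
    if (miss > 0) m[matrix(rbinom(n * S, 1, miss) == 1, n, S)] <- NA
    cs <- colSums(m, na.rm = TRUE)
    ncall <- colSums(!is.na(m))
    if (all(cs > 0 & cs < ncall)) return(m)
  }
}
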