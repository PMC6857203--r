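# Distributional and structural checks of the coalescent engine. The heavy
# closed-form calibrations (TMRCA, Watterson, neutral Tajima's D) live in
# test-acceptance.R; here the focus is correctness of the structured part.

test_that("isolated lineages cannot coalesce before the split", {
  p <- two_pop_params(T = 2e6, Ne = 1e5)
  tl <- build_timeline(p, "ISO-A")
  T_scaled <- p$T / 2.5 / (4e6)
  tm <- vapply(1:100, function(i)
    simulate_genealogy(tl, 1, 1, i)$tmrca, numeric(1))
  expect_true(all(tm > T_scaled))
  # and no lineage ever migrates under isolation
  nm <- vapply(1:100, function(i)
    simulate_genealogy(tl, 5, 5, i)$n_migrations, numeric(1))
  expect_true(all(nm == 0))
})

test_that("zero mutation parameter yields zero segregating sites", {
  tl <- panmictic_timeline()
  st <- divergesim:::.sim_locus_stats_cpp(unclass(tl), 10, 0, 0, 1e4, 1)
  expect_equal(st[["S"]], 0)
})

test_that("haplotype output satisfies the segregating-site invariants", {
  p <- two_pop_params(T = 1e6, Ne = 2e5, M = 2)
  tl <- build_timeline(p, "IM-A")
  lc <- locus_config(n_K = 10, n_W = 10, L = 1e4)
  for (seed in c(3, 17)) {
    h <- simulate_locus(tl, lc, seed, output = "haplotypes")
    cs <- colSums(h$mat)
    expect_true(all(cs > 0 & cs < nrow(h$mat))) # no invariant column
    expect_true(all(diff(h$positions) > 0))     # strictly increasing
    expect_true(all(h$positions >= 0 & h$positions < lc$L))
  }
})

test_that("the same seed reproduces a dataset bit for bit", {
  p <- truth_params()
  lc <- locus_config()
  a <- simulate_dataset("SC-B", p, 5, lc, 123)
  b <- simulate_dataset("SC-B", p, 5, lc, 123)
  expect_identical(a, b)
  ha <- simulate_dataset("SC-B", p, 2, lc, 123, output = "haplotypes")
  hb <- simulate_dataset("SC-B", p, 2, lc, 123, output = "haplotypes")
  expect_identical(lapply(ha, unclass), lapply(hb, unclass))
})

test_that("adding loci never perturbs earlier loci (counter-derived streams)", {
  p <- two_pop_params(M = 1)
  lc <- locus_config(n_K = 6, n_W = 6)
  small <- simulate_dataset("IM-A", p, 3, lc, 77)
  big <- simulate_dataset("IM-A", p, 6, lc, 77)
  expect_identical(small, big[, 1:3])
})

test_that("the fast stats path equals R statistics on the same haplotypes", {
  p <- truth_params()
  lc <- locus_config()
  st <- simulate_dataset("SC-B", p, 4, lc, 55)
  hp <- simulate_dataset("SC-B", p, 4, lc, 55, output = "haplotypes")
  for (i in 1:4) {
    expect_identical(st[, i], attr(hp[[i]], "stats"))
    expect_equal(locus_stats(hp[[i]]), st[, i], tolerance = 1e-12)
  }
})

test_that("label-symmetric parameters give exchangeable populations", {
  p <- two_pop_params(T = 1e6, Ne = 1e5, M = 5)
  tl <- build_timeline(p, "IM-A")
  lc <- locus_config(n_K = 10, n_W = 10)
  st <- divergesim:::.sim_dataset_stats_cpp(unclass(tl), 10, 10,
                                            locus_theta(lc$mu, lc$L), lc$L,
                                            600, 31)
  d <- st["pi_K", ] - st["pi_W", ]
  bt <- binom.test(sum(d > 0), sum(d != 0))
  expect_gt(bt$p.value, 0.01) # sign of pi_K - pi_W symmetric about 0
})

test_that("time rescaling: TMRCA in generations is invariant to the reference size", {
  # simulate at relative size x and 2x; TMRCA/x must match in distribution
  t1 <- vapply(1:2000, function(i)
    simulate_genealogy(panmictic_timeline(1), 8, 0, i)$tmrca, numeric(1))
  t2 <- vapply(1:2000, function(i)
    simulate_genealogy(panmictic_timeline(2), 8, 0, 10000 + i)$tmrca,
    numeric(1))
  ks <- suppressWarnings(ks.test(t1, t2 / 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("neutral site-frequency spectrum matches E[xi_i] = theta/i", {
  theta <- 5
  n <- 10
  lc <- locus_config(n_K = n, n_W = 0, L = 1e4,
                     mu = theta / (4e6 * 1e4))
  counts <- matrix(0, 1e4, n - 1)
  tl <- panmictic_timeline()
  for (r in seq_len(nrow(counts))) {
    h <- simulate_locus(tl, lc, r, output = "haplotypes")
    if (ncol(h$mat) == 0) next
    tab <- tabulate(colSums(h$mat), nbins = n - 1)
    counts[r, ] <- tab
  }
  xi <- colMeans(counts)
  se <- apply(counts, 2, sd) / sqrt(nrow(counts))
  expect_true(all(abs(xi - theta / seq_len(n - 1)) <= 3 * se))
})

test_that("segregating sites and diversity match an independent coalescent simulator", {
  # frozen reference sample: two-population IM (N = 1000 diploids everywhere,
  # split 2000 generations, 4Nm = 2 symmetric, theta_locus = 5, 10+10
  # haplotypes) simulated with msprime; KS on S and summed pairwise diversity
  oracle <- read.delim(test_path("oracle-im-msprime.tsv"))
  p <- structure(list(T = 2000 * 2.5, Ne_K = 1000, Ne_W = 1000, Ne_A = 1000,
                      M_WtoK = 1, M_KtoW = 1), class = "parameter_set")
  tl <- build_timeline(p, "IM-A")
  # theta_locus is 4*N*mu_locus = 5 with N = 1000 demes, i.e. mu_locus =
  # 1.25e-3; in the engine's fixed N_ref = 1e6 scaling that is theta = 5000
  theta <- locus_theta(mu = 1.25e-3 / 1e4, L = 1e4)
  st <- divergesim:::.sim_dataset_stats_cpp(unclass(tl), 10, 10, theta, 1e4,
                                            500, 2718)
  ks_S <- suppressWarnings(ks.test(st["S", ], oracle$S))
  expect_gt(ks_S$p.value, 0.01)
  # pooled summed pairwise diversity from the within/between decomposition:
  # C(10,2) pairs within each population and 100 between
  pi_sum <- (45 * st["pi_K", ] + 45 * st["pi_W", ] + 100 * st["dxy", ]) *
    1e4 / 190
  ks_pi <- suppressWarnings(ks.test(pi_sum, oracle$pi_sum))
  expect_gt(ks_pi$p.value, 0.01)
})

test_that("migration epochs act in the right period (secondary contact vs early)", {
  # enormous recent migration homogenizes (F_ST ~ 0); the same migration
  # confined to the ancient epoch leaves differentiation intact
  base <- list(T = 2e6, T1 = 0.5e6, Ne_K = 1e5, Ne_W = 1e5, Ne_A = 1e5,
               M_WtoK = 200, M_KtoW = 200)
  p <- structure(base, class = "parameter_set")
  lc <- locus_config(n_K = 10, n_W = 10)
  sc <- simulate_dataset("SC-A", p, 500, lc, 41)
  em <- simulate_dataset("EM-A", p, 500, lc, 42)
  m_sc <- mean(sc["fst", ], na.rm = TRUE)
  m_em <- mean(em["fst", ], na.rm = TRUE)
  expect_lt(m_sc, 0.02)
  expect_gt(m_em, m_sc + 0.1)
})

test_that("the R mutation dropper reproduces Watterson's expectation", {
  theta <- 5
  S <- vapply(1:500, function(i) {
    tr <- simulate_genealogy(panmictic_timeline(), 10, 0, i)
    ncol(drop_mutations(tr, theta, 1e4, seed = i)$mat)
  }, numeric(1))
  a1 <- sum(1 / (1:9))
  expect_lt(abs(mean(S) - theta * a1), 3 * sd(S) / sqrt(length(S)))
})
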