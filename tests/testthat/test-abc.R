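# Reference tables, rejection, model choice and regression adjustment.

toy_tables <- function(n = 300, sep = 4, seed = 1) {
  set.seed(seed)
  lapply(1:3, function(i) reference_table(
    paste0("m", i),
    data.frame(par = exp(rnorm(n))),
    cbind(s1 = rnorm(n, (i - 1) * sep), s2 = rnorm(n))))
}

test_that("the simulation filter implements the documented thresholds", {
  sv <- function(fst, d) structure(c(x = 1), mean_fst = fst, mean_D_pool = d)
  expect_false(filter_simulations(sv(0.2, 0.5)))   # F_ST above 0.159
  expect_true(filter_simulations(sv(0.05, 0.5)))
  expect_false(filter_simulations(sv(0.05, -0.01))) # D below 0
  expect_false(filter_simulations(sv(0.05, 1.01)))  # D above 1
  expect_true(filter_simulations(sv(0.159, 0)))     # boundary kept
})

test_that("reference tables are reproducible and respect point-mass priors", {
  pri <- default_priors()
  lc <- locus_config(n_K = 6, n_W = 6)
  t1 <- build_reference_table("IM-A", pri, n_sims = 3, n_loci = 4, lc = lc,
                              seed = 5, filter = FALSE)
  t2 <- build_reference_table("IM-A", pri, n_sims = 3, n_loci = 4, lc = lc,
                              seed = 5, filter = FALSE)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$stats, t2$stats)
  expect_equal(nrow(t1$stats), 3)
  # point-mass priors: parameters identical, statistics vary by simulation
  for (nm in names(pri)) pri[[nm]] <- list(dist = "point", value = 2e5)
  pri$T <- list(dist = "point", value = 1e6)
  pri$T1 <- list(dist = "point", value = 5e4)
  pri$M_WtoK <- list(dist = "point", value = 3)
  pri$M_KtoW <- list(dist = "point", value = 3)
  t3 <- build_reference_table("IM-A", pri, n_sims = 3, n_loci = 4, lc = lc,
                              seed = 6, filter = FALSE)
  expect_equal(nrow(unique(t3$params)), 1)
  expect_gt(nrow(unique(t3$stats)), 1)
})

test_that("retained-row mode draws until the target and reports exclusions", {
  lc <- locus_config(n_K = 6, n_W = 6)
  tb <- build_reference_table("IM-A", default_priors(), n_loci = 5, lc = lc,
                              seed = 2, n_retain = 20, max_draws = 5000)
  expect_equal(nrow(tb$stats), 20)
  expect_equal(tb$n_executed - tb$n_excluded, 20)
  # every retained row passes the filter
  expect_true(all(tb$stats[, "mean_fst"] <= 0.159 | is.na(tb$stats[, "mean_fst"])))
})

test_that("MAD standardization scales, is idempotent, and preserves distances", {
  set.seed(3)
  stats <- cbind(a = rnorm(200, 0, 2), b = runif(200, 0, 50))
  obs <- c(a = 0.5, b = 25)
  std <- standardize_stats(stats, obs)
  expect_equal(std$stats[, "a"], stats[, "a"] / mad(stats[, "a"]))
  expect_equal(unname(std$observed["a"]), 0.5 / mad(stats[, "a"]))
  # idempotence: re-scaling already-scaled data leaves it unchanged
  std2 <- standardize_stats(std$stats, std$observed)
  expect_equal(mad(std2$stats[, "a"]), 1, tolerance = 1e-12)
  # affine re-uniting of a raw statistic does not change scaled distances
  stats_b <- stats
  stats_b[, "b"] <- stats_b[, "b"] * 1000
  obs_b <- obs
  obs_b["b"] <- obs_b["b"] * 1000
  d1 <- divergesim:::abc_accept(std$stats, std$observed, 0.1)
  stdb <- standardize_stats(stats_b, obs_b)
  d2 <- divergesim:::abc_accept(stdb$stats, stdb$observed, 0.1)
  expect_equal(d1$idx, d2$idx)
  expect_equal(d1$dist, d2$dist, tolerance = 1e-9)
  # constant columns are dropped with a warning; all-constant is an error
  expect_warning(standardize_stats(cbind(a = rnorm(10), c = rep(1, 10)),
                                   c(a = 0, c = 1)), "constant")
  expect_error(standardize_stats(cbind(c = rep(1, 10)), c(c = 1)), "constant")
})

test_that("Epanechnikov weights peak at zero distance and vanish at the edge", {
  w <- divergesim:::epanechnikov_weights(c(0, 1, 2))
  expect_equal(w, c(1, 0.75, 0))
  expect_equal(divergesim:::epanechnikov_weights(c(0, 0)), c(1, 1))
})

test_that("model choice recovers separable models and the prior under no signal", {
  tabs <- toy_tables(n = 400, sep = 5)
  # with perfect separation the accepted set may contain a single model,
  # which abc_model_choice reports with a warning
  mc <- suppressWarnings(abc_model_choice(c(s1 = 0, s2 = 0), tabs,
                                          tolerance = 0.05))
  expect_equal(names(which.max(mc$mnlogistic)), "m1")
  expect_gt(mc$mnlogistic[["m1"]], 0.9)
  expect_equal(sum(mc$mnlogistic), 1, tolerance = 1e-9)
  expect_equal(sum(mc$rejection), 1, tolerance = 1e-12)
  # tolerance 1 with uninformative statistics: rejection ~ equal priors
  set.seed(8)
  flat <- lapply(1:3, function(i) reference_table(
    paste0("m", i), data.frame(par = exp(rnorm(400))),
    cbind(s1 = rnorm(400), s2 = rnorm(400))))
  mc2 <- abc_model_choice(c(s1 = 0, s2 = 0), flat, tolerance = 1)
  expect_true(all(abs(mc2$rejection - 1 / 3) < 0.05))
})

test_that("Bayes factors follow from posterior ratios under equal priors", {
  post <- structure(list(rejection = c(m1 = 0.95, m2 = 0.05),
                         mnlogistic = c(m1 = 0.95, m2 = 0.05)),
                    class = "model_posterior")
  expect_equal(bayes_factor(post, "m1", "m2"), 19)
  expect_equal(bayes_factor(post, "m1", "m2") * bayes_factor(post, "m2", "m1"),
               1)
  post$mnlogistic <- c(m1 = 1, m2 = 0)
  expect_identical(bayes_factor(post, "m1", "m2"), Inf)
})

test_that("weighted quantiles interpolate the cumulative weight grid", {
  x <- c(1, 2, 3, 4)
  w <- c(1, 1, 1, 1)
  expect_equal(divergesim:::weighted_quantile(x, w, 0.5), 2.5)
  # all weight on one value pins every quantile there
  expect_equal(divergesim:::weighted_quantile(x, c(0, 0, 1, 0), c(0.1, 0.9)),
               c(3, 3))
})

test_that("regression adjustment reproduces the conjugate-normal posterior", {
  # log-parameter ~ N(0,1); statistic s = log(par) + N(0, 0.5^2);
  # posterior after observing s: N(s/1.25, 0.2)
  set.seed(42)
  n <- 20000
  lpar <- rnorm(n)
  s <- lpar + rnorm(n, 0, 0.5)
  tab <- reference_table("toy", data.frame(par = exp(lpar)), cbind(stat = s))
  s_obs <- 1.2
  adj <- nn_regression_adjust(c(stat = s_obs), tab, tolerance = 0.05,
                              n_networks = 10, seed = 7)
  post_mean <- s_obs / 1.25
  post_sd <- sqrt(0.2)
  w <- adj$weights
  got_mean <- sum(w * log(adj$adjusted$par)) / sum(w)
  expect_lt(abs(got_mean - post_mean), 0.1)
  expect_lt(abs(log(adj$summary["median", "par"]) - post_mean), 0.1)
  # interval close to the analytic 95% band
  expect_lt(abs(log(adj$summary["q2.5", "par"]) - (post_mean - 1.96 * post_sd)),
            0.25)
  expect_lt(abs(log(adj$summary["q97.5", "par"]) - (post_mean + 1.96 * post_sd)),
            0.25)
})

test_that("coverage of the adjusted 95% interval is nominal on the toy problem", {
  set.seed(99)
  n <- 2000
  lpar <- rnorm(n)
  s <- lpar + rnorm(n, 0, 0.5)
  tab <- reference_table("toy", data.frame(par = exp(lpar)), cbind(stat = s))
  hits <- 0
  for (r in 1:100) {
    true_lpar <- rnorm(1)
    s_obs <- true_lpar + rnorm(1, 0, 0.5)
    adj <- suppressWarnings(
      nn_regression_adjust(c(stat = s_obs), tab, tolerance = 0.1,
                           n_networks = 3, seed = r))
    lo <- log(adj$summary["q2.5", "par"])
    hi <- log(adj$summary["q97.5", "par"])
    if (true_lpar >= lo && true_lpar <= hi) hits <- hits + 1
  }
  expect_gte(hits, 87) # binomial 99% band around 95/100
})

test_that("a zero-distance observation returns the matching row unadjusted", {
  set.seed(4)
  tab <- reference_table("toy", data.frame(par = exp(rnorm(50))),
                         cbind(stat = rnorm(50)))
  obs <- c(stat = tab$stats[17, "stat"])
  adj <- nn_regression_adjust(obs, tab, tolerance = 1 / 50, n_networks = 3)
  expect_equal(adj$summary["median", "par"], tab$params$par[17])
  expect_equal(adj$summary["q97.5", "par"], tab$params$par[17])
})

test_that("rejection-layer posteriors are exactly label-symmetric", {
  # swapping population labels consistently in observation and table swaps
  # the two size posteriors and the two migration posteriors
  set.seed(31)
  n <- 500
  params <- data.frame(Ne_K = exp(rnorm(n, 11)), Ne_W = exp(rnorm(n, 11)),
                       M_WtoK = runif(n, 0, 10), M_KtoW = runif(n, 0, 10))
  stats <- cbind(mean_pi_K = rnorm(n), mean_pi_W = rnorm(n),
                 mean_fst = rnorm(n))
  obs <- c(mean_pi_K = 0.3, mean_pi_W = -0.2, mean_fst = 0.1)
  swap_stats <- stats[, c("mean_pi_W", "mean_pi_K", "mean_fst")]
  colnames(swap_stats) <- c("mean_pi_K", "mean_pi_W", "mean_fst")
  obs_sw <- c(mean_pi_K = -0.2, mean_pi_W = 0.3, mean_fst = 0.1)
  std <- standardize_stats(stats, obs)
  std_sw <- standardize_stats(swap_stats, obs_sw)
  a <- divergesim:::abc_accept(std$stats, std$observed, 0.1)
  b <- divergesim:::abc_accept(std_sw$stats, std_sw$observed, 0.1)
  expect_equal(a$idx, b$idx)
  w <- divergesim:::epanechnikov_weights(a$dist)
  med <- function(v, idx) divergesim:::weighted_quantile(v[idx], w, 0.5)
  expect_equal(med(params$Ne_K, a$idx), med(params$Ne_K, b$idx))
})

test_that("cross-validated model choice is diagonal for separable models", {
  tabs <- toy_tables(n = 250, sep = 6, seed = 12)
  conf <- cross_validate_model_choice(tabs, n_pseudo = 5, tolerance = 0.1,
                                      seed = 3)
  expect_true(all(rowSums(conf) == 5))
  expect_equal(sum(diag(conf)), 15)
})

test_that("reference tables round-trip through TSV plus sidecar", {
  lc <- locus_config(n_K = 6, n_W = 6)
  tb <- build_reference_table("SC-A", default_priors(), n_sims = 5,
                              n_loci = 3, lc = lc, seed = 44, filter = FALSE)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ref.tsv")
  write_reference_table(tb, path)
  tb2 <- read_reference_table(path)
  expect_equal(tb2$model, tb$model)
  expect_equal(tb2$params, tb$params, tolerance = 1e-9)
  expect_equal(unname(tb2$stats), unname(tb$stats), tolerance = 1e-9)
  expect_equal(tb2$n_executed, tb$n_executed)
})

test_that("weighted HPD intervals concentrate around the weighted mass", {
  set.seed(2)
  x <- c(rnorm(500, 0, 1), rnorm(500, 10, 1))
  w <- c(rep(1, 500), rep(1e-6, 500))
  h <- weighted_hpd(x, w, 0.95)
  expect_gt(h[1], -3)
  expect_lt(h[2], 4) # the near-zero-weight mode is excluded
  expect_equal(weighted_hpd(rep(3, 5), rep(1, 5)), c(3, 3))
})
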