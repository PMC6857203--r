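test_that("nucleotide diversity matches brute-force pairwise counting", {
  # two identical haplotypes
  expect_equal(nucleotide_diversity(rbind(c(0, 1), c(0, 1)), 10), 0)
  # {00, 01, 11}: pairwise diffs (1, 2, 1), mean 4/3 over L = 10
  m <- rbind(c(0, 0), c(0, 1), c(1, 1))
  expect_equal(nucleotide_diversity(m, 10), (4 / 3) / 10)
  expect_equal(nucleotide_diversity(m, 10), bf_pi(m, 10))
  # random matrices, with and without missing data
  for (seed in 1:4) {
    h <- random_hap_matrix(8, 12, seed, miss = if (seed > 2) 0.15 else 0)
    expect_equal(nucleotide_diversity(h, 50), bf_pi(h, 50), tolerance = 1e-12)
  }
  expect_error(nucleotide_diversity(m, 0), "positive")
})

test_that("simulated neutral diversity is centred on theta per site", {
  theta_site <- 5e-4 # theta_locus = theta_site * L = 5
  st <- divergesim:::.sim_dataset_stats_cpp(unclass(panmictic_timeline()),
                                            10, 0, theta_site * 1e4,
                                            1e4, 1000, 8)
  pis <- st["pi_K", ]
  expect_lt(abs(mean(pis) - theta_site), 3 * sd(pis) / sqrt(length(pis)))
})

test_that("Tajima's D equals an independent implementation of the formula", {
  # every variant a singleton: excess of rare variants, D < 0
  m <- diag(10)
  expect_lt(tajimas_d(m), 0)
  # hand-sized example, n = 4
  m4 <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 0))
  expect_equal(tajimas_d(m4), bf_tajima(m4), tolerance = 1e-12)
  for (seed in 5:8) {
    h <- random_hap_matrix(10, 15, seed)
    expect_equal(tajimas_d(h), bf_tajima(h), tolerance = 1e-12)
  }
  # undefined below 3 segregating sites or 4 chromosomes
  expect_true(is.na(tajimas_d(random_hap_matrix(10, 2, 1))))
  expect_true(is.na(tajimas_d(random_hap_matrix(3, 10, 1))))
})

test_that("Weir-Cockerham F_ST components match the published formulas", {
  # complete differentiation: two populations fixed for alternative alleles
  dos <- rbind(matrix(0, 5, 4), matrix(2, 5, 4))
  pop <- rep(c("K", "W"), each = 5)
  expect_equal(wc_fst(dos, pop)$fst, 1)
  # identical allele and genotype counts -> a <= 0 and F_ST <= 0
  g <- rbind(c(0, 1), c(1, 2), c(2, 0), c(0, 1), c(1, 2), c(2, 0))
  r <- wc_fst(g, rep(c("K", "W"), each = 3))
  expect_true(all(r$components[, "a"] <= 0))
  expect_lte(r$fst, 0)
  # toy table from the specification: pop1 {0,0,1}, pop2 {2,2,1}
  toy <- matrix(c(0, 0, 1, 2, 2, 1), ncol = 1)
  tpop <- rep(c("K", "W"), each = 3)
  expect_equal(wc_fst(toy, tpop)$fst, bf_wc_fst(toy, tpop), tolerance = 1e-12)
  # random dosage tables with missingness
  for (seed in 1:4) {
    set.seed(seed)
    dd <- matrix(sample(c(0:2, NA), 60, replace = TRUE,
                        prob = c(.4, .3, .2, .1)), 10, 6)
    pp <- rep(c("K", "W"), each = 5)
    expect_equal(wc_fst(dd, pp)$fst, bf_wc_fst(dd, pp), tolerance = 1e-12)
  }
  # monomorphic table is undefined
  expect_true(is.na(wc_fst(matrix(0, 10, 3), rep(c("K", "W"), each = 5))$fst))
})

test_that("d_XY and fixed differences match direct counting", {
  # populations with identical content: no fixed differences
  h <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 1, 0), c(1, 0, 0))
  pop <- c("K", "K", "W", "W")
  r <- dxy_and_df(h, pop, 100)
  expect_equal(r$df, 0)
  # 3 fully fixed sites out of 100 bp
  h2 <- cbind(rbind(matrix(0, 4, 3), matrix(1, 4, 3)))
  r2 <- dxy_and_df(h2, rep(c("K", "W"), each = 4), 100)
  expect_equal(r2$df, 3)
  expect_equal(r2$dxy, 0.03)
  for (seed in 9:12) {
    hh <- random_hap_matrix(8, 10, seed)
    pp <- rep(c("K", "W"), each = 4)
    bf <- bf_dxy_df(hh, pp, 40)
    got <- dxy_and_df(hh, pp, 40)
    expect_equal(got$dxy, bf$dxy, tolerance = 1e-12)
    expect_equal(got$df, bf$df)
  }
})

test_that("d_XY of a region is the length-weighted mean over a partition", {
  h <- random_hap_matrix(8, 20, 42)
  pop <- rep(c("K", "W"), each = 4)
  whole <- dxy_and_df(h, pop, 200)$dxy
  left <- dxy_and_df(h[, 1:8], pop, 80)$dxy
  right <- dxy_and_df(h[, 9:20], pop, 120)$dxy
  expect_equal(whole, (80 * left + 120 * right) / 200, tolerance = 1e-12)
})

test_that("mean r^2 matches brute-force pairwise correlation", {
  # perfectly co-inherited pair of sites
  m <- cbind(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(mean_r2(m), 1)
  # all four gametes equally frequent: no association
  m2 <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(mean_r2(m2), 0)
  m5 <- random_hap_matrix(8, 5, 13)
  expect_equal(mean_r2(m5), bf_mean_r2(m5), tolerance = 1e-12)
  dd <- random_hap_matrix(8, 5, 14) + random_hap_matrix(8, 5, 15)
  expect_equal(mean_r2(dd, type = "dosage"), bf_mean_r2(dd), tolerance = 1e-12)
  expect_true(is.na(mean_r2(m[, 1, drop = FALSE])))
})

test_that("statistics are invariant to population relabelling and resorting", {
  h <- random_hap_matrix(12, 15, 21)
  pop <- rep(c("K", "W"), each = 6)
  s1 <- locus_stats(h, pop, 100)
  swapped <- locus_stats(h, ifelse(pop == "K", "W", "K"), 100)
  expect_equal(s1[["fst"]], swapped[["fst"]])
  expect_equal(s1[["dxy"]], swapped[["dxy"]])
  expect_equal(s1[["pi_K"]], swapped[["pi_W"]])
  expect_equal(s1[["D_K"]], swapped[["D_W"]])
  # permuting samples within populations leaves everything unchanged
  perm <- c(sample(1:6), sample(7:12))
  s2 <- locus_stats(h[perm, ], pop, 100)
  expect_equal(s2[["dxy"]], s1[["dxy"]])
  expect_equal(s2[["pi_K"]], s1[["pi_K"]])
})

test_that("a panmictic sample split into two labels has F_ST near zero", {
  tl <- panmictic_timeline()
  st <- divergesim:::.sim_dataset_stats_cpp(unclass(tl), 10, 10, 32, 1e4,
                                            1000, 99)
  f <- st["fst", ]
  f <- f[!is.na(f)]
  expect_lt(abs(mean(f)), 3 * sd(f) / sqrt(length(f)))
})

test_that("dataset summaries have the declared layout and invariances", {
  p <- two_pop_params(M = 2)
  st <- simulate_dataset("IM-A", p, 10, locus_config(n_K = 8, n_W = 8), 7)
  sv <- summarize_dataset(st)
  expect_length(sv, 2 * 7)
  expect_equal(names(sv)[1:2], c("mean_pi_K", "mean_pi_W"))
  # permutation invariance over loci
  sv2 <- summarize_dataset(st[, sample(ncol(st))])
  expect_equal(unclass(sv2), unclass(sv))
  # identical loci give exactly zero variances
  rep_st <- st[, rep(1, 5)]
  sv3 <- summarize_dataset(rep_st)
  expect_true(all(sv3[grep("^var_", names(sv3))] == 0))
  # a statistic undefined everywhere is an error naming it
  st_na <- st
  st_na["r2", ] <- NA
  expect_error(summarize_dataset(st_na), "r2")
})

test_that("locus statistics and summaries are written as readable TSV", {
  p <- two_pop_params(M = 2)
  st <- simulate_dataset("IM-A", p, 5, locus_config(n_K = 8, n_W = 8), 7)
  dir <- withr::local_tempdir()
  lp <- file.path(dir, "loci.tsv")
  sp <- file.path(dir, "summary.tsv")
  sv <- write_locus_stats(st, lp, sp)
  df <- read.delim(lp)
  expect_equal(nrow(df), 5)
  expect_true(all(c("pi_K", "fst", "r2") %in% names(df)))
  sm <- read.delim(sp)
  expect_equal(as.numeric(sm[1, ]), as.numeric(sv), tolerance = 1e-9)
})
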