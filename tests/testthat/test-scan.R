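make_vt <- function(scaffold, pos, dos, pop = NULL, lens = NULL) {
  n <- nrow(dos)
  if (is.null(pop)) pop <- rep(c("K", "W"), each = n / 2)
  scaffold <- rep(scaffold, length.out = length(pos))
  variant_table(paste0("s", seq_len(n)), pop, scaffold, pos, dos,
                rep("A", length(pos)), rep("T", length(pos)), lens)
}

test_that("the SNP prefilter applies the three documented rules", {
  # 20 samples; site 1: 3 missing (0.15 > 0.10, removed); site 2: fine;
  # site 3: MAF exactly 0.05 (removed, strict); site 4: MAF 0.075 kept
  dos <- matrix(1, 20, 4)
  dos[1:3, 1] <- NA
  dos[, 2] <- rep(c(0, 2), 10)
  dos[, 3] <- c(rep(0, 18), 1, 1)   # alt freq 2/40 = 0.05
  dos[, 4] <- c(rep(0, 17), 1, 1, 1) # alt freq 3/40 = 0.075
  vt <- make_vt("sc1", c(100, 200, 300, 400), dos)
  out <- snp_prefilter(vt)
  expect_equal(out$pos, c(200, 400))
  expect_equal(unname(attr(out, "n_removed")["missing"]), 1)
  expect_equal(unname(attr(out, "n_removed")["maf"]), 1)
  # density rule: 4 SNPs at 100,102,104,106 -> rightmost removed
  dos2 <- matrix(rep(c(0, 2), 20), 10, 4)
  vt2 <- make_vt("sc1", c(100, 102, 104, 106), dos2,
                 pop = rep(c("K", "W"), each = 5))
  out2 <- snp_prefilter(vt2)
  expect_equal(out2$pos, c(100, 102, 104))
  # a 4th SNP outside the 10-bp span survives
  vt3 <- make_vt("sc1", c(100, 102, 104, 110), dos2,
                 pop = rep(c("K", "W"), each = 5))
  expect_equal(snp_prefilter(vt3)$pos, c(100, 102, 104, 110))
})

test_that("windows tile from position 1 and short terminal windows are dropped", {
  set.seed(2)
  pos <- sort(sample(1:120000, 300))
  dos <- matrix(sample(0:2, 300 * 8, replace = TRUE), 8, 300)
  vt <- make_vt("sc1", pos, dos, lens = c(sc1 = 120000))
  map <- scaffold_map(data.frame(scaffold = "sc1", chrom = "chr1",
                                 class = "autosome", index = 1))
  win <- window_scan(vt, map)
  expect_equal(win$start, c(1, 50001))
  expect_equal(win$end, c(50000, 100000))
  expect_equal(attr(win, "n_excluded_short"), 1) # terminal 20 kb
  # a window with zero polymorphic sites reports pi 0 and undefined F_ST
  dos0 <- matrix(0, 8, 2)
  dos0[1, ] <- 2 # polymorphic only on sc2
  vt2 <- make_vt(c("sc1", "sc2"), c(100, 100), dos0,
                 lens = c(sc1 = 50000, sc2 = 50000))
  vt2$dos[, 1] <- 0 # sc1 site monomorphic
  win2 <- window_scan(vt2, scaffold_map(data.frame(
    scaffold = c("sc1", "sc2"), chrom = c("chr1", "chr2"),
    class = "autosome", index = 1:2)))
  w1 <- win2[win2$scaffold == "sc1", ]
  expect_equal(w1$pi_K, 0)
  expect_true(is.na(w1$fst))
})

test_that("window statistics are invariant to splitting the input by scaffold", {
  set.seed(9)
  pos <- c(sort(sample(1:100000, 200)), sort(sample(1:60000, 120)))
  sc <- rep(c("sc1", "sc2"), c(200, 120))
  dos <- matrix(sample(c(0:2, NA), 320 * 10, replace = TRUE,
                       prob = c(.4, .3, .25, .05)), 10, 320)
  vt <- make_vt(sc, pos, dos, lens = c(sc1 = 100000, sc2 = 60000))
  map <- scaffold_map(data.frame(scaffold = c("sc1", "sc2"),
                                 chrom = c("chr1", "chr2"),
                                 class = "autosome", index = 1:2))
  whole <- window_scan(vt, map)
  parts <- rbind(
    window_scan(divergesim:::vt_subset(vt, which(sc == "sc1")), map),
    window_scan(divergesim:::vt_subset(vt, which(sc == "sc2")), map))
  expect_equal(whole, parts, ignore_attr = TRUE)
  # per-window segregating sites account for every SNP inside a retained
  # window (sc2's terminal 10 kb is excluded)
  inwin <- (sc == "sc1") | (sc == "sc2" & pos <= 50000)
  cs <- colSums(vt$dos, na.rm = TRUE)
  seg <- cs > 0 & cs < 2 * colSums(!is.na(vt$dos))
  expect_equal(sum(whole$S), sum(seg & inwin))
})

test_that("per-gene statistics use merged CDS sites and flag unknown locations", {
  set.seed(11)
  pos <- sort(sample(1:5000, 60))
  dos <- matrix(sample(0:2, 60 * 10, replace = TRUE), 10, 60)
  vt <- make_vt(c(rep("sc1", 40), rep("scX", 20)), c(pos[1:40], pos[1:20]),
                dos, lens = c(sc1 = 5000, scX = 5000))
  genes <- gene_annotation(data.frame(
    gene_id = c("gA", "gA", "gB"), scaffold = c("sc1", "sc1", "scX"),
    strand = "+", start = c(1, 2000, 10), end = c(1500, 3000, 4000)))
  map <- scaffold_map(data.frame(scaffold = "sc1", chrom = "chr1",
                                 class = "autosome", index = 1))
  gs <- suppressWarnings(per_gene_stats(vt, genes, map))
  expect_equal(nrow(gs), 2)
  gA <- gs[gs$gene_id == "gA", ]
  expect_equal(gA$cds_length, 1500 + 1001)
  expect_true(gA$known_location)
  expect_false(gs$known_location[gs$gene_id == "gB"])
  # a gene whose two populations match in allele content has F_ST <= 0
  dos_same <- rbind(dos[1:5, ], dos[1:5, ])
  vt2 <- make_vt("sc1", pos, dos_same, lens = c(sc1 = 5000))
  gs2 <- per_gene_stats(vt2, genes[genes$gene_id == "gA", ], map)
  expect_lte(gs2$fst, 0)
})

test_that("percentile outliers use type-7 quantiles strictly within strata", {
  df <- data.frame(gene_id = paste0("g", 1:100), class = "autosome",
                   known_location = TRUE, fst = 1:100)
  out <- call_outliers(df, "fst", 0.95, "high", "autosome",
                       id_col = "gene_id")
  expect_equal(out$cutoff, unname(quantile(1:100, 0.95, type = 7)))
  expect_setequal(out$members, paste0("g", 96:100))
  # all values equal: empty outlier set
  df2 <- df
  df2$fst <- 1
  expect_length(call_outliers(df2, "fst", 0.95, "high", "autosome",
                              id_col = "gene_id")$members, 0)
  # injecting an extreme value in the other stratum leaves the cutoff alone
  df3 <- rbind(df, data.frame(gene_id = "gZ", class = "Z",
                              known_location = TRUE, fst = 1e6))
  out3 <- call_outliers(df3, "fst", 0.95, "high", "autosome",
                        id_col = "gene_id")
  expect_equal(out3$cutoff, out$cutoff)
  # signed subsets for Tajima's D: high from positives, low from negatives
  df4 <- data.frame(gene_id = paste0("g", 1:80), class = "autosome",
                    known_location = TRUE,
                    D_K = c(seq(-2, -0.1, length.out = 40),
                            seq(0.1, 2, length.out = 40)))
  hi <- call_outliers(df4, "D_K", 0.95, "high", "autosome",
                      signed_subset = TRUE, id_col = "gene_id")
  expect_equal(hi$cutoff, unname(quantile(df4$D_K[df4$D_K > 0], 0.95)))
  lo <- call_outliers(df4, "D_K", 0.05, "low", "autosome",
                      signed_subset = TRUE, id_col = "gene_id")
  expect_equal(lo$cutoff, unname(quantile(df4$D_K[df4$D_K < 0], 0.05)))
  expect_error(call_outliers(df[1:5, ], "fst", 0.95, "high", "autosome"),
               "fewer than")
})

test_that("candidate loci respect spacing, missingness and statistic filters", {
  lc <- locus_config(n_K = 10, n_W = 10)
  po <- make_pseudo_observed("IM-A", two_pop_params(T = 1e6, Ne = 1e5, M = 5),
                             6, lc, missingness = 0, seed = 21)
  vt <- po$vt
  cov <- setNames(rep(1, 6), sprintf("locus_%03d", 1:6))
  ex <- extract_abc_loci(vt, cov, seed = 1, locus_length = 1e4)
  # every locus-sized scaffold hosts exactly one candidate at position 1;
  # candidates are either retained or excluded by the statistic filter
  expect_equal(nrow(ex$loci) + sum(ex$excluded), 6)
  expect_true(all(ex$loci$start == 1))
  expect_gte(nrow(ex$loci), 1)
  # low-coverage scaffolds are ineligible
  cov2 <- cov
  cov2[3:6] <- 0.5
  ex2 <- extract_abc_loci(vt, cov2, seed = 1, locus_length = 1e4)
  expect_true(all(ex2$loci$scaffold %in% sprintf("locus_%03d", 1:2)))
  expect_error(extract_abc_loci(vt, cov * 0, seed = 1), "coverage")
  # an individual with excessive missingness disqualifies the locus
  vt3 <- vt
  idx1 <- which(vt3$scaffold == "locus_001")
  vt3$dos[1, idx1[seq_len(ceiling(0.45 * length(idx1)))]] <- NA
  ex3 <- extract_abc_loci(vt3, cov, seed = 1, locus_length = 1e4)
  expect_false("locus_001" %in% ex3$loci$scaffold)
  expect_gte(ex3$excluded["missing_individual"], 1)
  # spacing: two loci on one scaffold closer than 500 kb cannot both stay
  lc2 <- locus_config(n_K = 10, n_W = 10, L = 4e5)
  po2 <- make_pseudo_observed("IM-A", two_pop_params(M = 50), 1, lc2,
                              seed = 3)
  vt4 <- po2$vt
  ex4 <- extract_abc_loci(vt4, c(locus_001 = 1), seed = 2,
                          locus_length = 1e4)
  if (!is.null(ex4$loci) && nrow(ex4$loci) > 1) {
    d <- diff(sort(ex4$loci$start))
    expect_true(all(d > 5e5))
  } else succeed()
})
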