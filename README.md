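# divergesim

Coalescent-based demographic inference and genome-wide divergence scanning
for a pair of recently diverged populations — the analysis situation of two
parapatric shorebird lineages (labelled **K** and **W** throughout) whose
genomes show very low average differentiation but localized islands of
divergence, and whose history of gene flow (none, continuous, early, or
renewed after secondary contact) is the scientific question.

The package is aimed at population geneticists who want to run the complete
chain — simulation, approximate Bayesian computation, genome scan, GO
enrichment — on variant tables, and at methodologists who want a compact,
fully testable implementation with a synthetic-data generator carrying known
ground truth.

## What is inside

**Two-population structured-coalescent simulator** (Rcpp). Eight demographic
models: four gene-flow scenarios — isolation (ISO), isolation-with-migration
(IM), early migration (EM, gene flow only on the backward-time interval
`[T1, T)`), secondary contact (SC, gene flow only on `[0, T1)`) — crossed
with two effective-size regimes (A: constant; B: sizes shift at `T1` with
exponential interpolation to the present-day sizes `N0`). Parameters are in
natural units: split time `T` and size-change time `T1` in years, diploid
sizes `Ne`/`N0`, migration as `2NM` immigrant individuals per generation
into the recipient population (a lineage in population *i* migrates backward
at rate `M/(2 N_i)` per generation). Internally the engine uses the ms
scaling: time in units of `4 N_ref` generations with `N_ref = 1e6`, and
`theta = 4 N_ref mu L` per locus under infinite sites.

**Summary statistics.** Per-locus nucleotide diversity per population,
Tajima's *D* (per population and pooled), Weir–Cockerham (1984) *F*_ST with
ratio-of-sums aggregation, *d*_XY, fixed differences *d*_f, and mean
pairwise LD *r*². The simulator computes these directly from per-branch
descendant sets; an independent R implementation handles observed dosage
data with missingness, and the two agree to machine precision on phased
data.

**ABC machinery.** Prior-predictive reference tables with the
simulation-level filter (mean *F*_ST ≤ 0.159, mean pooled *D* in [0, 1]),
MAD-scaled Euclidean rejection, model choice by Epanechnikov-weighted
multinomial logistic regression, Bayes factors, leave-one-out
cross-validation, and posterior estimation by an ensemble of
single-hidden-layer neural networks regressing log-parameters on summary
statistics (Epanechnikov weights, homoscedastic adjustment, weighted
median/mean/mode and 2.5%/97.5% quantiles).

**Genome scan.** SNP prefilter (missing rate ≤ 0.10, minor-allele frequency
\> 0.05, at most 3 SNPs per 10 bp), 50-kb windows starting at position 1
with sub-25-kb terminal windows excluded, per-gene statistics on merged CDS
intervals, stratified percentile outliers (autosomes and Z separately;
Tajima's *D* high/low sets from the 95th percentile of positive and the 5th
percentile of negative values), and extraction of spaced 10-kb loci for the
demographic analysis.

**Permutation GO enrichment.** Observed category counts against 1,000
equally sized random gene sets, Z-scores, Benjamini–Hochberg correction,
and the small-category (< 50 genes) / uncharacterized grouping rules.

**Synthetic data.** `make_pseudo_observed()` produces locus sets (VCF +
population map) under any model with a truth ledger that regenerates them
byte for byte; `make_toy_genome()` builds a multi-scaffold genome with
planted divergence islands (produced mechanistically by reduced migration,
with *F*_ST and diversity tuned to targets by bisection) and a planted
enriched GO category.

## A worked example

Simulate data under the secondary-contact model at the study's posterior
medians and look at the summaries:

```r
library(divergesim)
lc <- locus_config()           # 20 + 20 haplotypes, 10-kb loci,
                               # mu = 0.8e-8 / site / generation, g = 2.5 y
truth <- structure(list(T = 0.863e6, T1 = 0.059e6, Ne_K = 3.581e6,
                        Ne_W = 0.649e6, Ne_A = 0.752e6, N0_K = 0.086e6,
                        N0_W = 0.082e6, M_WtoK = 236.503, M_KtoW = 51.476),
                   class = "parameter_set")
st <- simulate_dataset("SC-B", truth, n_loci = 30, lc, seed = 20260928)
sv <- summarize_dataset(st)
round(sv[1:7], 4)
#> mean_pi_K mean_pi_W  mean_D_K  mean_D_W  mean_fst  mean_dxy   mean_r2
#>    0.0285    0.0279   -0.2493   -0.1749   -0.0040    0.0281    0.1679
```

The near-zero mean F_ST is the model's own message: with ~236 immigrants
per generation into K, the two populations are almost panmictic at these
parameter values, and the negative Tajima's *D* reflects the inferred
expansion at the split. Model choice and posterior estimation then run as

```r
tab <- build_reference_table("SC-B", default_priors(), n_loci = 30, lc = lc,
                             seed = 99, n_retain = 4000)
post <- nn_regression_adjust(sv, tab, tolerance = 0.05, n_networks = 10,
                             seed = 5)
post$summary["median", "T"] / 1e6   # posterior median split time, Ma
#> [1] 0.8504
```

which recovers the true 0.863 Ma split time within the study's credible
interval. The toy-genome chain is a one-liner per stage:

```r
tg <- make_toy_genome(seed = 5)
scan <- run_divergence_scan(tg$vt, tg$genes, tg$scaffold_map, tg$go)
subset(scan$enrichment$fst_autosome, significant)
#>                domain   category observed expected    z p_adjusted
#>    cellular_component GO:9000001        7    2.475 3.15      0.016
```

— the planted category (GO:9000001) is the one enriched among high-F_ST
genes, at its planted odds.

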