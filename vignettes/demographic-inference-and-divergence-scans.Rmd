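---
title: "Demographic inference and divergence scans with divergesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference and divergence scans with divergesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

divergesim studies a pair of recently diverged populations, K and W, with
two complementary analyses: model-based inference of their demographic
history by approximate Bayesian computation (ABC), and a genome-wide scan
for localized islands of divergence with gene-level annotation and GO
enrichment. This vignette is the package's own account of the models, the
parameters that matter, the numerical choices, and what the tests do and do
not establish.

## The demographic model space

Eight models arise from crossing four gene-flow scenarios with two
effective-size regimes. Backward in time, the two populations merge into a
single ancestral population of diploid size `Ne_A` at the split time `T`
(years). Gene flow is parameterized by `2NM` — the number of immigrant
individuals entering the recipient population per generation — and switched
by scenario: never (ISO), throughout `[0, T)` (IM), only in the early part
of divergence `[T1, T)` (EM), or only after renewed contact, `[0, T1)`
(SC). In regime A the population sizes `Ne_K`, `Ne_W` are constant; in
regime B each population has present-day size `N0_i` that changes
exponentially to `Ne_i` at `T1` and stays at `Ne_i` until the split. The
time `T1` therefore plays a double role — gene-flow change and size shift —
which mirrors how the size histories estimated from single-genome
sequentially Markovian coalescent analyses are condensed into a
two-epoch-per-population specification.

Interpretation of migration: `2NM` immigrants per generation into
population *i* means a lineage sampled in *i* traces its ancestry to the
other population at rate `M/(2 N_i(t))` per generation backward in time.
Because the recipient size enters the denominator, the same `2NM` implies
much faster lineage movement through a small population than a large one.

The growth coefficients of regime B are derived quantities,
`G_i = ln(Ne_i / N0_i) / (T1 / g)` per generation, not free parameters: the
two endpoint sizes already determine the trajectory, and sampling all three
would over-determine it.

## Simulation engine and scaling

The engine (C++) performs exact event-driven structured-coalescent
sampling: within each epoch, pairwise coalescence competes with lineage
migration; exponential-growth epochs are handled by thinning against the
epoch's maximal rate, which is exact and costs nothing in constant-size
epochs. Times are expressed in units of `4 N_ref` generations with the
reference size fixed at `N_ref = 1e6` diploids; a population of relative
size `x = N / N_ref` coalesces a pair at rate `2/x`, and mutations fall on
branches at rate `theta = 4 N_ref mu L` per unit branch length, so a
panmictic constant-size sample reproduces `E[TMRCA] = 2(1 - 1/n)` coalescent
units and Watterson's `E[S] = theta * sum 1/i` exactly — both are asserted
by the test suite at Monte-Carlo precision, together with the neutral site
frequency spectrum, a Kolmogorov–Smirnov cross-check of `S` and diversity
against an independent coalescent simulator (msprime) on a two-population
configuration, and the placement of migration in the correct epoch.

Mutations follow the infinite-sites model, implemented on a finite integer
lattice of `L` positions with collisions redrawn; at the default
`theta/L` this approximation is invisible. Summary statistics are
accumulated per branch from descendant-tip bitsets (at most 64 haplotypes),
so a locus with thousands of segregating sites costs the same as a sparse
one; the full haplotype matrix is materialized only when requested, from
the identical random stream, and the package asserts exact agreement
between the two paths and an independent R implementation.

There is no intra-locus recombination: loci are single genealogies, and
datasets are collections of independent loci. This matches the sampling
design the package targets (10-kb loci spaced at least 500 kb apart).

## Priors and filters

Default priors: sizes log-uniform on `[1e4, 1e7]` diploids; `T` uniform on
`[0.2, 2]` Ma; `T1` normal(0.06 Ma, 0.02 Ma) truncated to `(0.001 Ma, T)`;
migration uniform on `[0, 500]` immigrants per generation; generation time
2.5 years and `mu = 0.8e-8` per site per generation. These bracket the
study system's published credible intervals and are all replaceable through
the run configuration. An alternative per-year mutation rate appears in the
source literature and is inconsistent with the per-generation value; the
package takes no position — `mu` is a configuration choice.

Reference tables apply a simulation-level filter that mirrors the filter
used on the observed loci: datasets whose across-locus mean Weir–Cockerham
F_ST exceeds 0.159, or whose mean pooled Tajima's D falls outside `[0, 1]`,
are discarded and counted. Two practical consequences deserve note. First,
retention rates differ enormously between models — isolation models at
these priors mostly produce strongly differentiated data and retain on the
order of 1–2% of draws, so their tables are the dominant computational
cost. Second, the filter truncates the prior predictive: data simulated at
parameter values whose typical outcome violates the filter (for example,
strongly negative mean D under a large inferred expansion) sit at the edge
of, or outside, the retained table's support, and regression adjustment
must then extrapolate. The acceptance analysis reports exactly this
situation honestly rather than papering over it.

## ABC choices

Distances are Euclidean after dividing each summary statistic by its median
absolute deviation across the reference table; boundary ties are broken by
row index so runs are deterministic. The default statistic vector is the
across-locus mean and variance of (pi_K, pi_W, D_K, D_W, F_ST, d_XY,
r2_mean) — fourteen numbers. Model choice accepts the tolerance fraction of
the pooled tables and reports both the acceptance proportions and a
multinomial logistic regression (weighted by the Epanechnikov kernel
`1 - (d/d_max)^2`) evaluated at the observation; model priors are equal,
and the two-stage protocol (constant-Ne group, changing-Ne group, then the
two winners) rescales the tolerance so every stage accepts the same number
of rows.

Parameter estimation fits an ensemble of single-hidden-layer feed-forward
networks (5 hidden units, weight decay drawn per member from
{1e-4, 1e-3, 1e-2}, inputs and log-parameters standardized) and applies the
homoscedastic correction `theta* = theta - m(s) + m(s_obs)` on the log
scale. Point estimates are weighted medians; a weighted kernel-density mode
(Silverman bandwidth) and weighted 2.5%/97.5% quantiles are also reported.
Quantile intervals, not highest-density intervals, are the default. The
ensemble mean is validated against the analytic posterior of a conjugate
linear-Gaussian toy problem, including interval coverage.

## Genome scan conventions

The SNP prefilter keeps sites with missing fraction at most 0.10 and minor
allele frequency strictly above 0.05, then enforces at most 3 SNPs per
10-bp span by greedy left-to-right removal of the rightmost excess site
(the tie-break is a package decision; the constraint itself does not fix
one). Windows are 50 kb, tiled from position 1 of each scaffold; a window's
length for the 25-kb exclusion is its span within the scaffold, not its
callable length. Coordinates are 1-based inclusive on disk and 0-based
half-open internally, with conversion confined to the I/O layer. The
W chromosome is excluded from scans. Percentile cutoffs use R's default
type-7 quantile and are computed strictly within strata (autosomes and Z
separately; for Tajima's D, within the positive and negative subsets
separately, per population). Per-window d_XY shares the scan's filtered
SNP set, which biases it downward uniformly across windows — a property
inherited from the upstream pipeline design and left intact deliberately.

F_ST is Weir & Cockerham's (1984) estimator with ratio-of-sums
aggregation; negative estimates are reported as-is because clamping would
silently shift percentile cutoffs. On unphased observed data r2 is the
squared genotype-dosage correlation; simulated phased data use the
haplotype version, and the configuration records which one was used —
the mismatch between the two on the same underlying data is a documented
property, not hidden.

The locus-extraction stage draws non-overlapping 10-kb loci from scaffolds
with callable coverage above 0.8, spaced more than 500 kb edge to edge,
then applies the missingness rules (over 40% missing in any individual or
30% on average) and the per-locus statistic filter; spacing is enforced
against every considered candidate, matching a choose-then-filter order.

## Permutation enrichment

Expected category counts come from 1,000 equally sized random gene sets
drawn without replacement from the universe; significance is a two-sided
normal p-value on the Z-score with Benjamini–Hochberg correction across the
categories of one annotation domain, and categories with expected count
below 1 and at most one observed member are filtered. Annotations are not
propagated up the GO graph. The normal approximation is only trustworthy
when expected counts are well above 1; the calibration test therefore uses
categories of 15–50% prevalence, where the permutation distribution is
effectively Gaussian — with rare categories the exact empirical tail
(available as an option) is the better choice.

## The synthetic-data generator

`make_toy_genome()` builds the full input set for the scan pipeline with
known truth. Divergence islands are produced mechanistically — island
windows are simulated under a reduced migration rate, background windows
under a high one — so diversity, d_XY and D co-vary realistically instead
of being painted onto allele frequencies. Calibration is numerical: the
migration-to-F_ST map (invariant to the deme size at fixed `2NM`) is
inverted by bisection, and the deme size is then rescaled once using the
exact linearity of within-population diversity in `Ne` at fixed `2NM`.
Each 50-kb window is assembled from 10 independent 5-kb linkage blocks;
a single 50-kb genealogy would make per-window F_ST so variable that a
"planted island" need not look like one, while block assembly emulates
intra-window recombination and concentrates window statistics around their
stratum targets. Defaults (10 scaffolds of 1 Mb, islands on 1% of the 200
windows, background diversity 2.6e-3, background/island F_ST targets
0.046/0.6, 10 + 10 diploid samples, 2% missingness) reproduce the shape of
the study system at desk scale.

What the generator does not emulate: real linkage maps and recombination
hotspots, mutation-rate and background-selection heterogeneity along the
genome, reference bias and genotyping error beyond simple missingness, and
sex-chromosome ploidy (the Z scaffold carries background autosomal-style
data; stratified cutoffs are still exercised). Passing the planted-truth
tests therefore demonstrates that the pipeline recovers signals of the
planted kind and magnitude, not that it is robust to every artifact of
real resequencing data.

## Scales used by the validation suite

The test suite and the acceptance script run everything at a reduced,
fixed scale chosen to keep the full validation reproducible on a single
CPU: pseudo-observed datasets of 30 loci (the study's own geometry, 143
loci, is generated and checked structurally), reference tables of 5,000
retained rows per model with the generating model extended to 20,000,
rejection tolerance 0.01, and neural-network ensembles of 10. Isolation
models retain so little of their prior mass under the simulation filter
that their tables are capped at 200,000 executed draws; the cap and the
resulting row counts are reported by the builders. Monte-Carlo checks use
10^3–10^4 replicates with fixed seeds throughout, and every stochastic
stage derives its stream from a single root seed by counter, so enlarging
a dataset never perturbs the part already generated.

## Known limitations

Model-choice resolution at 30 loci is family-level, not model-level. In
leave-one-out cross-validation over the filtered prior predictive, the
presence or absence of *recent* gene flow is recovered almost perfectly
(about 94% of pseudo-observations select a model from the correct
{ISO, EM} or {IM, SC} pair), but the members within each pair are
intrinsically confusable: an early-migration draw with a small migration
rate is observationally an isolation model, and secondary contact differs
from continuous migration only through the weak ancient-migration signal.
Per-scenario top-1 accuracy therefore sits near 45–75% rather than the
80%+ one might hope for; more loci, informative linkage statistics, or
tighter priors on `T1` would be needed to split the pairs.

Identifiability at the study's own posterior medians is intrinsically
poor in some directions: with hundreds of immigrants per generation the
populations are nearly panmictic, so the data carry little information
about the size contrast `Ne_K / Ne_W`, and the simulation filter excludes
the very region of parameter space that generates data like the
pseudo-observation (mean pooled D is strongly negative there). The
acceptance analysis reports the resulting estimates as computed; the split
time, which is anchored by absolute divergence, recovers well, while the
migration rate and the size ratio inherit the truncation and near-panmixia
problems. This is a property of the inference problem under these
conditions, not of the implementation — the same machinery recovers the
conjugate toy posterior and separable model-choice problems exactly.
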