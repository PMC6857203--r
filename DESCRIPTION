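Package: divergesim
Title: Demographic Inference and Genome Scans for Diverging Population Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coalescent-based demographic inference and genome-wide divergence
    scanning for a pair of recently diverged populations. Implements a
    two-population structured-coalescent simulator covering eight demographic
    models (isolation, isolation-with-migration, early migration and secondary
    contact, each with constant or changing effective population sizes),
    approximate Bayesian computation with multinomial-logistic model choice
    and neural-network regression posterior adjustment, per-locus population
    genetic summary statistics (nucleotide diversity, Tajima's D,
    Weir-Cockerham F_ST, d_XY, fixed differences, linkage disequilibrium),
    windowed and per-gene genome scans with stratified percentile outlier
    calling, permutation-based GO category enrichment, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    nnet,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
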