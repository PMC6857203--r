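# Shared expensive fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default-condition toy genome (10 scaffolds x 1 Mb, islands on 1% of the
# 200 windows, background pi 2.6e-3, F_ST targets 0.046 / 0.6).
get_toy_genome <- function() {
  memo("toy_genome", function() make_toy_genome(seed = 5))
}

# Full divergence-scan results on the toy genome.
get_scan_results <- function() {
  memo("scan_results", function() {
    tg <- get_toy_genome()
    suppressMessages(suppressWarnings(
      run_divergence_scan(tg$vt, tg$genes, tg$scaffold_map, tg$go)))
  })
}

# Model-choice reference tables at the reduced scale: 30 loci of 10 kb,
# 20 + 20 haplotypes, default priors, 5,000 executed prior draws per model
# with the simulation filter applied (retention varies per model).
get_choice_tables <- function() {
  memo("choice_tables", function() {
    lc <- locus_config()
    pri <- default_priors()
    tabs <- list()
    for (m in model_set()) {
      tabs[[m]] <- build_reference_table(
        m, pri, n_sims = 5000, n_loci = 30, lc = lc,
        seed = 52000 + match(m, model_set()))
    }
    tabs
  })
}

# The 20,000-retained-row table of the generating model used by the
# parameter-recovery run.
get_scb_20k <- function() {
  memo("scb_20k", function() {
    build_reference_table("SC-B", default_priors(), n_loci = 30,
                          lc = locus_config(), seed = 52008,
                          n_retain = 20000, max_draws = 400000)
  })
}

# One pseudo-observed dataset at the published posterior-median parameters.
get_truth_observation <- function() {
  memo("truth_obs", function() {
    lc <- locus_config()
    st <- simulate_dataset("SC-B", truth_params(), 30, lc, 424242)
    summarize_dataset(st)
  })
}
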