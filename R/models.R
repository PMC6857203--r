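# Demographic model set, priors and timeline construction.
#
# Eight models: four gene-flow scenarios (ISO, IM, EM, SC) crossed with two
# effective-size regimes (A = constant, B = changing at T1). All user-facing
# parameters are in natural units: times in years, sizes in diploid
# individuals, migration as 2NM immigrant individuals per generation into the
# recipient population.

MODEL_SCENARIOS <- c("ISO", "IM", "EM", "SC")
MODEL_REGIMES <- c("A", "B")

#' All eight demographic model labels
#'
#' Gene-flow scenarios: `ISO` (no gene flow), `IM` (gene flow throughout
#' divergence), `EM` (gene flow only in the early period of divergence, i.e.
#' the backward-time interval `[T1, T)`), `SC` (secondary contact: gene flow
#' only in the late period, `[0, T1)`). Size regimes: `A` constant Ne, `B`
#' Ne changing at `T1` with exponential interpolation to present-day sizes.
#'
#' @return Character vector of the eight model labels, e.g. `"SC-B"`.
#' @export
model_set <- function() {
  as.vector(outer(MODEL_SCENARIOS, MODEL_REGIMES, paste, sep = "-"))
}

parse_model <- function(model) {
  parts <- strsplit(model, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% MODEL_SCENARIOS ||
      !parts[2] %in% MODEL_REGIMES) {
    stop("unknown model label: ", model, " (expected e.g. 'SC-B')")
  }
  list(scenario = parts[1], regime = parts[2])
}

#' Parameter names drawn/estimated for a model
#'
#' Group A models have no present-day sizes (`N0_*`); the isolation scenario
#' has no migration parameters; `T1` is present whenever gene flow changes or
#' sizes shift at that time (all group B models, and SC/EM in group A).
#'
#' @param model Model label (see [model_set()]).
#' @return Character vector of parameter names.
#' @export
model_param_names <- function(model) {
  m <- parse_model(model)
  nm <- c("T", "Ne_K", "Ne_W", "Ne_A")
  if (m$regime == "B" || m$scenario %in% c("SC", "EM")) nm <- c(nm, "T1")
  if (m$regime == "B") nm <- c(nm, "N0_K", "N0_W")
  if (m$scenario != "ISO") nm <- c(nm, "M_WtoK", "M_KtoW")
  nm
}

#' Default prior specification
#'
#' Effective sizes (ancestral, epoch and present-day) are log-uniform on
#' `[1e4, 1e7]` diploids; the split time T is uniform on `[0.2, 2]` Ma; T1 is
#' normal(0.06 Ma, 0.02 Ma) truncated to `(0.001 Ma, T)`; both migration
#' rates are uniform on `[0, 500]` immigrant individuals per generation.
#' Every entry can be overridden through the run configuration.
#'
#' @return A named list of distribution specifications (class `prior_set`).
#' @export
default_priors <- function() {
  structure(list(
    T     = list(dist = "unif", min = 0.2e6, max = 2e6),
    T1    = list(dist = "tnorm", mean = 0.06e6, sd = 0.02e6, min = 1e3),
    Ne_K  = list(dist = "logunif", min = 1e4, max = 1e7),
    Ne_W  = list(dist = "logunif", min = 1e4, max = 1e7),
    Ne_A  = list(dist = "logunif", min = 1e4, max = 1e7),
    N0_K  = list(dist = "logunif", min = 1e4, max = 1e7),
    N0_W  = list(dist = "logunif", min = 1e4, max = 1e7),
    M_WtoK = list(dist = "unif", min = 0, max = 500),
    M_KtoW = list(dist = "unif", min = 0, max = 500)
  ), class = "prior_set")
}

draw_one <- function(spec, upper = NULL) {
  switch(spec$dist,
    unif = runif(1, spec$min, spec$max),
    logunif = 10^runif(1, log10(spec$min), log10(spec$max)),
    point = spec$value,
    tnorm = {
      lo <- spec$min
      hi <- if (is.null(upper)) Inf else upper
      for (i in seq_len(1000)) {
        x <- rnorm(1, spec$mean, spec$sd)
        if (x > lo && x < hi) return(x)
      }
      stop("truncated-normal prior: no mass in (", lo, ", ", hi,
           ") after 1000 rejections")
    },
    stop("unknown prior distribution: ", spec$dist)
  )
}

#' Draw one parameter set from the priors
#'
#' Draws only the parameters the model uses (see [model_param_names()]);
#' migration is fixed to exactly 0 under the isolation scenario, and T1 is
#' drawn from its truncated normal conditional on the drawn T.
#'
#' @param priors A `prior_set` (see [default_priors()]); `point` entries
#'   (`list(dist = "point", value = x)`) yield degenerate draws.
#' @param model Model label.
#' @param seed Optional integer; when given, the draw is deterministic.
#' @return Named list of parameters (class `parameter_set`), in natural units.
#' @export
sample_prior <- function(priors, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- parse_model(model)
  nm <- model_param_names(model)
  p <- list()
  p$T <- draw_one(priors$T)
  if ("T1" %in% nm) p$T1 <- draw_one(priors$T1, upper = p$T)
  for (s in c("Ne_K", "Ne_W", "Ne_A")) p[[s]] <- draw_one(priors[[s]])
  if (m$regime == "B") for (s in c("N0_K", "N0_W")) p[[s]] <- draw_one(priors[[s]])
  if (m$scenario == "ISO") {
    p$M_WtoK <- 0
    p$M_KtoW <- 0
  } else {
    p$M_WtoK <- draw_one(priors$M_WtoK)
    p$M_KtoW <- draw_one(priors$M_KtoW)
  }
  validate_parameter_set(p, model)
  structure(p, class = "parameter_set", model = model)
}

validate_parameter_set <- function(p, model) {
  m <- parse_model(model)
  stopifnot(p$T > 0, p$Ne_K > 0, p$Ne_W > 0, p$Ne_A > 0,
            p$M_WtoK >= 0, p$M_KtoW >= 0)
  if (!is.null(p$T1) && (p$T1 <= 0 || p$T1 >= p$T))
    stop("invalid parameter set: need 0 < T1 < T")
  if (m$regime == "B") stopifnot(p$N0_K > 0, p$N0_W > 0)
  invisible(p)
}

#' Per-epoch exponential growth coefficients (derived)
#'
#' Group B sizes are parameterized by their endpoints (`N0` at present, `Ne`
#' at `T1`); the growth coefficient is reported as the derived quantity
#' `ln(Ne/N0) / (T1/g)` per generation rather than drawn.
#'
#' @param params A `parameter_set` for a group B model.
#' @param g Generation time in years.
#' @return Named vector `c(G_K, G_W)`.
#' @export
growth_coefficients <- function(params, g = 2.5) {
  gen <- params$T1 / g
  c(G_K = log(params$Ne_K / params$N0_K) / gen,
    G_W = log(params$Ne_W / params$N0_W) / gen)
}

#' Build the backward-time epoch timeline for the coalescent engine
#'
#' Converts a parameter set in natural units into the internal scaled epochs
#' (time in units of `4 * N_ref` generations, sizes relative to `N_ref`,
#' which is fixed at 1e6 diploids). Migration is switched per scenario:
#' SC active on `[0, T1)`, EM on `[T1, T)`, IM on `[0, T)`, ISO never. Group
#' B epochs interpolate population sizes exponentially from the present-day
#' `N0` to the epoch size `Ne` at `T1`. From `T` backwards all lineages sit
#' in a single ancestral population of size `Ne_A`.
#'
#' @param params A `parameter_set`.
#' @param model Model label.
#' @param g Generation time in years.
#' @return A numeric epoch matrix (class `timeline`) with attributes
#'   `boundaries_gen` (epoch boundary times in generations) and `N_ref`.
#' @export
build_timeline <- function(params, model, g = 2.5) {
  m <- parse_model(model)
  scen <- m$scenario
  Ts <- params$T / g / (4 * N_REF)
  if (!is.finite(Ts)) stop("non-finite time conversion")
  mig_recent <- scen %in% c("SC", "IM")
  mig_early <- scen %in% c("EM", "IM")
  M01 <- params$M_WtoK  # forward immigrants into K (pop 0) from W
  M10 <- params$M_KtoW
  rows <- list()
  if (m$regime == "A") {
    xK <- params$Ne_K / N_REF
    xW <- params$Ne_W / N_REF
    if (scen %in% c("SC", "EM")) {
      T1s <- params$T1 / g / (4 * N_REF)
      rows[[1]] <- c(0, xK, 0, xW, 0,
                     if (mig_recent) M01 else 0, if (mig_recent) M10 else 0, 0)
      rows[[2]] <- c(T1s, xK, 0, xW, 0,
                     if (mig_early) M01 else 0, if (mig_early) M10 else 0, 0)
    } else {
      rows[[1]] <- c(0, xK, 0, xW, 0,
                     if (mig_recent || mig_early) M01 else 0,
                     if (mig_recent || mig_early) M10 else 0, 0)
    }
  } else {
    T1s <- params$T1 / g / (4 * N_REF)
    x0K <- params$N0_K / N_REF
    x0W <- params$N0_W / N_REF
    gK <- log(params$Ne_K / params$N0_K) / T1s
    gW <- log(params$Ne_W / params$N0_W) / T1s
    rows[[1]] <- c(0, x0K, gK, x0W, gW,
                   if (mig_recent) M01 else 0, if (mig_recent) M10 else 0, 0)
    rows[[2]] <- c(T1s, params$Ne_K / N_REF, 0, params$Ne_W / N_REF, 0,
                   if (mig_early) M01 else 0, if (mig_early) M10 else 0, 0)
  }
  rows[[length(rows) + 1]] <- c(Ts, params$Ne_A / N_REF, 0,
                                params$Ne_A / N_REF, 0, 0, 0, 1)
  ep <- do.call(rbind, rows)
  colnames(ep) <- c("t0", "x0_K", "g_K", "x0_W", "g_W",
                    "M_KfromW", "M_WfromK", "merged")
  if (any(!is.finite(ep))) stop("non-finite value in timeline")
  structure(ep, class = c("timeline", "matrix"),
            boundaries_gen = ep[, "t0"][-1] * 4 * N_REF,
            N_ref = N_REF, model = model)
}

#' Scaled mutation parameter for a locus
#'
#' `theta = 4 * N_ref * mu * L` in the internal scaling.
#'
#' @param mu Mutation rate per site per generation.
#' @param L Locus length in bp.
#' @return Scalar theta.
#' @export
locus_theta <- function(mu, L) {
  th <- 4 * N_REF * mu * L
  if (!is.finite(th) || th <= 0) stop("theta must be positive and finite")
  th
}
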