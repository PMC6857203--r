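# Approximate Bayesian computation: reference tables, rejection, model choice
# by multinomial logistic regression, neural-network regression adjustment of
# posteriors, Bayes factors and cross-validation.

#' Simulation-level filter for reference tables
#'
#' A simulated dataset is kept only when its across-locus mean Weir-Cockerham
#' F_ST is at most 0.159 and its mean pooled Tajima's D lies in `[0, 1]`,
#' mirroring the locus filter applied to the observed data.
#'
#' @param sv A `summary_vector` from [summarize_dataset()].
#' @param fst_max Upper F_ST bound (default 0.159).
#' @param d_range Allowed range for mean pooled Tajima's D.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_simulations <- function(sv, fst_max = 0.159, d_range = c(0, 1)) {
  fst <- attr(sv, "mean_fst")
  dp <- attr(sv, "mean_D_pool")
  if (is.null(fst) || is.null(dp)) stop("summary vector lacks filter attributes")
  if (is.na(fst) || is.na(dp)) return(FALSE)
  fst <= fst_max && dp >= d_range[1] && dp <= d_range[2]
}

#' Build a prior-predictive reference table for one model
#'
#' Each row is one draw from the priors, one simulated dataset of `n_loci`
#' loci, and its summary vector. Rows failing [filter_simulations()] are
#' excluded and counted. With `n_retain`, draws continue (in batches) until
#' that many rows pass the filter or `max_draws` is hit.
#'
#' @param model Model label.
#' @param priors A `prior_set`.
#' @param n_sims Number of prior draws to execute (ignored when `n_retain`
#'   is given).
#' @param n_loci Loci per simulated dataset.
#' @param lc A [locus_config()].
#' @param seed Integer seed; per-row streams are derived by counter.
#' @param n_retain Target number of retained rows (optional).
#' @param max_draws Safety cap on executed draws in `n_retain` mode.
#' @param select Statistics entering the summary vector.
#' @param filter Apply the simulation filter (default TRUE).
#' @return A `reference_table`: list with `model`, `params` (data frame),
#'   `stats` (matrix), `seeds`, `n_executed`, `n_excluded`.
#' @export
build_reference_table <- function(model, priors, n_sims = NULL, n_loci, lc,
                                  seed, n_retain = NULL,
                                  max_draws = if (is.null(n_retain)) NULL else
                                    200L * n_retain,
                                  select = DEFAULT_SUMMARY_STATS,
                                  filter = TRUE) {
  if (is.null(n_sims) && is.null(n_retain))
    stop("give n_sims or n_retain")
  pnames <- model_param_names(model)
  target <- if (is.null(n_retain)) NA_integer_ else n_retain
  budget <- if (is.null(n_retain)) n_sims else max_draws
  params <- list()
  stats <- list()
  seeds <- numeric(0)
  n_exec <- 0L
  n_excl <- 0L
  set.seed(seed %% .Machine$integer.max)
  while (n_exec < budget &&
         (is.na(target) || length(stats) < target)) {
    n_exec <- n_exec + 1L
    p <- sample_prior(priors, model)
    row_seed <- derive_seed_r(seed %% 2^31, n_exec)
    tl <- build_timeline(p, model, g = lc$g)
    theta <- locus_theta(lc$mu, lc$L)
    needs_r2 <- "r2" %in% select
    # two-phase evaluation: the filter needs only mean F_ST and pooled D,
    # so r^2 (the dominant per-locus cost when there are no migration
    # events) can be skipped and recomputed for survivors by replaying the
    # identical per-locus streams. This only pays off where retention is
    # very low, i.e. the isolation models.
    two_phase <- filter && needs_r2 &&
      parse_model(model)$scenario == "ISO"
    if (two_phase) {
      sm <- .sim_dataset_stats_cpp(unclass(tl), lc$n_K, lc$n_W, theta, lc$L,
                                   n_loci, as.double(row_seed), FALSE)
      sv <- summarize_dataset(sm, select = setdiff(select, "r2"))
      if (!filter_simulations(sv)) {
        n_excl <- n_excl + 1L
        next
      }
    }
    sm <- .sim_dataset_stats_cpp(unclass(tl), lc$n_K, lc$n_W, theta, lc$L,
                                 n_loci, as.double(row_seed), needs_r2)
    sv <- summarize_dataset(sm, select = select)
    if (filter && !two_phase && !filter_simulations(sv)) {
      n_excl <- n_excl + 1L
      next
    }
    params[[length(params) + 1L]] <- unlist(p[pnames])
    stats[[length(stats) + 1L]] <- as.numeric(sv)
    seeds <- c(seeds, row_seed)
  }
  if (n_exec > 0 && length(stats) == 0)
    stop("all simulations filtered: priors and filter appear incompatible")
  if (filter && n_excl / n_exec > 0.99)
    warning("more than 99% of simulations filtered for model ", model,
            "; priors and filter may be mismatched")
  sv_names <- c(paste0("mean_", select), paste0("var_", select))
  st <- do.call(rbind, stats)
  colnames(st) <- sv_names
  pm <- as.data.frame(do.call(rbind, params))
  names(pm) <- pnames
  structure(list(model = model, params = pm, stats = st, seeds = seeds,
                 n_executed = n_exec, n_excluded = n_excl,
                 select = select),
            class = "reference_table")
}

#' Assemble a reference table from components
#'
#' Constructor used by tests and toy problems that bypass the simulator.
#'
#' @param model Model label for every row.
#' @param params Data frame of parameter draws.
#' @param stats Matrix of summary statistics (rows match `params`).
#' @return A `reference_table`.
#' @export
reference_table <- function(model, params, stats) {
  stats <- as.matrix(stats)
  stopifnot(nrow(params) == nrow(stats))
  structure(list(model = model, params = as.data.frame(params), stats = stats,
                 seeds = rep(NA_real_, nrow(stats)),
                 n_executed = nrow(stats), n_excluded = 0L,
                 select = colnames(stats)),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("<reference_table> model ", x$model, ": ", nrow(x$stats),
      " retained rows (", x$n_excluded, " of ", x$n_executed,
      " draws filtered)\n", sep = "")
  invisible(x)
}

#' Scale summary statistics by their median absolute deviation
#'
#' Each statistic is divided by its MAD across the reference table (the
#' scaling convention of regression ABC); constant columns are dropped with
#' a warning. The observation is scaled by the same factors.
#'
#' @param stats Reference statistic matrix.
#' @param observed Observed summary vector (same columns).
#' @return List with `stats`, `observed`, `scale` (the MADs) and `kept`
#'   (retained column names).
#' @export
standardize_stats <- function(stats, observed) {
  stats <- as.matrix(stats)
  obs <- unclass(observed)
  if (!is.null(names(obs)) && !is.null(colnames(stats)) &&
      all(colnames(stats) %in% names(obs))) {
    observed <- as.numeric(obs[colnames(stats)])
  } else {
    if (length(obs) != ncol(stats))
      stop("observed summary vector does not match the table's statistics")
    observed <- as.numeric(obs)
  }
  names(observed) <- colnames(stats)
  sc <- apply(stats, 2, mad)
  keep <- sc > 0
  if (!any(keep)) stop("all summary statistics are constant across the table")
  if (any(!keep))
    warning("dropping constant statistics: ",
            paste(colnames(stats)[!keep], collapse = ", "))
  list(stats = sweep(stats[, keep, drop = FALSE], 2, sc[keep], "/"),
       observed = observed[keep] / sc[keep],
       scale = sc[keep], kept = colnames(stats)[keep])
}

# Scaled Euclidean distances and the accepted index set for a tolerance.
# Ties at the acceptance boundary are broken by row index (order() is stable).
abc_accept <- function(scaled_stats, scaled_obs, tolerance) {
  d <- sqrt(rowSums(sweep(scaled_stats, 2, scaled_obs)^2))
  n_acc <- max(1L, ceiling(tolerance * length(d)))
  idx <- order(d)[seq_len(n_acc)]
  list(idx = idx, dist = d[idx], all_dist = d)
}

# Epanechnikov weights on scaled distance: 1 - (d/d_max)^2, maximal (1) at
# zero distance. All weights 1 when every accepted distance is 0.
epanechnikov_weights <- function(d) {
  dmax <- max(d)
  if (dmax == 0) return(rep(1, length(d)))
  1 - (d / dmax)^2
}

#' ABC model choice
#'
#' Pools the reference tables of all candidate models, accepts the
#' `tolerance` fraction of rows nearest the observation in MAD-scaled
#' Euclidean distance, and reports both the rejection posterior (acceptance
#' proportions) and the multinomial-logistic posterior: a multinomial
#' logistic regression of model label on summary statistics over the
#' accepted rows, Epanechnikov-weighted by distance, evaluated at the
#' observation. Equal prior probabilities across models are assumed (equal
#' retained row counts per table are expected; a warning is issued
#' otherwise).
#'
#' @param observed Observed summary vector.
#' @param tables List of `reference_table`s (one per candidate model).
#' @param tolerance Accepted fraction of pooled rows.
#' @param method Posterior to report first: both are always computed.
#' @return A `model_posterior`: list with `rejection`, `mnlogistic` (named
#'   probability vectors), `tolerance`, `n_accepted`.
#' @export
abc_model_choice <- function(observed, tables, tolerance,
                             method = c("mnlogistic", "rejection")) {
  method <- match.arg(method)
  if (length(tables) < 2) stop("need at least two candidate models")
  models <- vapply(tables, function(x) x$model, character(1))
  if (anyDuplicated(models)) stop("duplicate model labels in tables")
  counts <- vapply(tables, function(x) nrow(x$stats), integer(1))
  if (length(unique(counts)) > 1)
    warning("unequal retained row counts across models (",
            paste(counts, collapse = ", "),
            "); rejection proportions assume equal model priors")
  stats <- do.call(rbind, lapply(tables, function(x) x$stats))
  label <- factor(rep(models, counts), levels = models)
  n_acc_target <- ceiling(tolerance * nrow(stats))
  if (n_acc_target < 50)
    stop("tolerance * total rows must be at least 50 (got ", n_acc_target, ")")
  std <- standardize_stats(stats, observed)
  acc <- abc_accept(std$stats, std$observed, tolerance)
  rej <- prop.table(table(label[acc$idx]))
  rejection <- setNames(as.numeric(rej), names(rej))
  w <- epanechnikov_weights(acc$dist)
  df <- data.frame(.label = droplevels(label[acc$idx]),
                   std$stats[acc$idx, , drop = FALSE], check.names = FALSE)
  mn <- rep(0, length(models))
  names(mn) <- models
  if (nlevels(df$.label) < 2) {
    mn[levels(df$.label)] <- 1
    warning("only one model present in the accepted set")
  } else {
    fit <- nnet::multinom(.label ~ ., data = df, weights = w,
                          maxit = 500, MaxNWts = 5000, trace = FALSE)
    newd <- as.data.frame(as.list(std$observed), check.names = FALSE)
    pr <- predict(fit, newdata = newd, type = "probs")
    if (length(pr) == 1) { # two-level fit returns only P(second level)
      pr <- c(1 - pr, pr)
      names(pr) <- levels(df$.label)
    }
    mn[names(pr)] <- pmax(as.numeric(pr), 0)
    absent <- setdiff(models, levels(df$.label))
    if (length(absent))
      warning("models absent from the accepted set get probability 0: ",
              paste(absent, collapse = ", "))
    mn <- mn / sum(mn)
  }
  structure(list(rejection = rejection, mnlogistic = mn, method = method,
                 tolerance = tolerance, n_accepted = length(acc$idx)),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("<model_posterior> tolerance ", x$tolerance, ", ", x$n_accepted,
      " accepted rows\n", sep = "")
  m <- rbind(rejection = x$rejection, mnlogistic = x$mnlogistic)
  print(round(m, 4))
  invisible(x)
}

#' Bayes factor between two models
#'
#' Ratio of posterior model probabilities, valid under the equal prior model
#' probabilities this package uses throughout.
#'
#' @param posterior A `model_posterior`.
#' @param model_i,model_j Model labels.
#' @param method Which posterior to use.
#' @return The Bayes factor (possibly `Inf` when `p_j` is 0).
#' @export
bayes_factor <- function(posterior, model_i, model_j,
                         method = c("mnlogistic", "rejection")) {
  method <- match.arg(method)
  p <- posterior[[method]]
  if (!model_i %in% names(p) || !model_j %in% names(p))
    stop("model not present in posterior")
  if (p[[model_j]] == 0) return(Inf)
  p[[model_i]] / p[[model_j]]
}

# Weighted quantile by linear interpolation over the cumulative-weight grid
# (midpoint convention), deterministic in the input order.
weighted_quantile <- function(x, w, probs) {
  keep <- w > 0
  x <- x[keep]
  w <- w[keep]
  if (length(x) == 1) return(rep(x, length(probs)))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  grid <- (cw - 0.5 * w) / sum(w)
  vapply(probs, function(p) {
    if (p <= grid[1]) return(x[1])
    if (p >= grid[length(grid)]) return(x[length(x)])
    stats::approx(grid, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

weighted_mode <- function(x, w) {
  if (length(unique(x)) == 1) return(x[1])
  # Silverman bandwidth from the unweighted sample; density() warns that bw
  # selection ignores weights, which is exactly the intended behaviour
  d <- suppressWarnings(density(x, weights = w / sum(w), bw = "nrd0"))
  d$x[which.max(d$y)]
}

#' Neural-network regression adjustment of an ABC posterior
#'
#' Accepts the `tolerance` fraction of rows nearest the observation,
#' weights them with the Epanechnikov kernel on scaled distance, fits an
#' ensemble of single-hidden-layer feed-forward networks regressing
#' log-parameters on scaled statistics, and adjusts each accepted draw by
#' the difference between the ensemble prediction at the observation and at
#' the draw's own statistics (homoscedastic correction). Point estimates and
#' quantiles are weighted and reported on the back-transformed (natural)
#' scale; medians are the headline point estimates.
#'
#' @param observed Observed summary vector.
#' @param table A `reference_table` for the chosen model.
#' @param tolerance Accepted fraction of rows.
#' @param n_networks Ensemble size (the study-scale analysis uses 50).
#' @param size Hidden units per network.
#' @param decay_grid Weight-decay values sampled per ensemble member.
#' @param maxit Training iterations per network.
#' @param seed Integer seed for network initialization.
#' @return An `adjusted_posterior`: list with `adjusted` (data frame of
#'   back-transformed adjusted draws), `weights`, `summary` (matrix with
#'   rows median/mean/mode/q2.5/q97.5), `accepted_params`, `tolerance`.
#' @export
nn_regression_adjust <- function(observed, table, tolerance, n_networks = 50,
                                 size = 5, decay_grid = c(1e-4, 1e-3, 1e-2),
                                 maxit = 500, seed = 1) {
  stats <- table$stats
  params <- as.matrix(table$params)
  if (any(params <= 0))
    stop("parameters must be strictly positive for the log transform")
  n_acc_target <- ceiling(tolerance * nrow(stats))
  if (n_acc_target < 2) {
    # degenerate acceptance: return the nearest row unadjusted
    std <- standardize_stats(stats, observed)
    acc <- abc_accept(std$stats, std$observed, tolerance)
    i <- acc$idx[1]
    est <- params[i, , drop = TRUE]
    summ <- rbind(median = est, mean = est, mode = est,
                  `q2.5` = est, `q97.5` = est)
    return(structure(list(adjusted = as.data.frame(t(est)), weights = 1,
                          summary = summ,
                          accepted_params = params[i, , drop = FALSE],
                          tolerance = tolerance),
                     class = "adjusted_posterior"))
  }
  if (n_acc_target < 100 && nrow(stats) >= 100)
    warning("fewer than 100 accepted rows; the regression fit will be noisy")
  std <- standardize_stats(stats, observed)
  acc <- abc_accept(std$stats, std$observed, tolerance)
  w <- epanechnikov_weights(acc$dist)
  # guard against an all-zero weight vector (single accepted distance value)
  if (sum(w) == 0) w <- rep(1, length(w))
  X <- std$stats[acc$idx, , drop = FALSE]
  Y <- log(params[acc$idx, , drop = FALSE])
  # center/scale for stable network training
  xm <- colMeans(X); xs <- apply(X, 2, sd); xs[xs == 0] <- 1
  ym <- colMeans(Y); ys <- apply(Y, 2, sd); ys[ys == 0] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  Ys <- sweep(sweep(Y, 2, ym), 2, ys, "/")
  obs_s <- (std$observed - xm) / xs
  set.seed(seed)
  pred_obs <- matrix(0, n_networks, ncol(Y))
  pred_X <- matrix(0, nrow(X), ncol(Y))
  failed <- 0L
  for (b in seq_len(n_networks)) {
    decay <- sample(decay_grid, 1)
    fit <- try(nnet::nnet(Xs, Ys, size = size, decay = decay, linout = TRUE,
                          weights = w, maxit = maxit, trace = FALSE,
                          MaxNWts = 10000), silent = TRUE)
    if (inherits(fit, "try-error")) { failed <- failed + 1L; next }
    pred_obs[b, ] <- predict(fit, rbind(obs_s))
    pred_X <- pred_X + predict(fit, Xs)
  }
  if (failed > n_networks / 2)
    stop("more than half of the network ensemble failed to train")
  ok <- n_networks - failed
  mu_obs <- colSums(pred_obs) / ok
  mu_X <- pred_X / ok
  # de-standardize predictions back to log-parameter scale
  mu_obs <- mu_obs * ys + ym
  mu_X <- sweep(sweep(mu_X, 2, ys, "*"), 2, ym, "+")
  adj_log <- sweep(Y - mu_X, 2, mu_obs, "+")
  adj <- exp(adj_log)
  colnames(adj) <- colnames(params)
  summ <- sapply(seq_len(ncol(adj)), function(j) {
    lx <- adj_log[, j]
    c(median = exp(weighted_quantile(lx, w, 0.5)),
      mean = sum(w * exp(lx)) / sum(w),
      mode = exp(weighted_mode(lx, w)),
      q2.5 = exp(weighted_quantile(lx, w, 0.025)),
      q97.5 = exp(weighted_quantile(lx, w, 0.975)))
  })
  colnames(summ) <- colnames(params)
  rownames(summ) <- c("median", "mean", "mode", "q2.5", "q97.5")
  structure(list(adjusted = as.data.frame(adj), weights = w, summary = summ,
                 accepted_params = params[acc$idx, , drop = FALSE],
                 tolerance = tolerance),
            class = "adjusted_posterior")
}

#' @export
print.adjusted_posterior <- function(x, ...) {
  cat("<adjusted_posterior> ", nrow(x$adjusted), " weighted draws\n", sep = "")
  print(signif(x$summary, 4))
  invisible(x)
}

#' Cross-validate ABC model choice
#'
#' Leave-one-out confusion matrix: pseudo-observations are drawn from each
#' model's reference table, removed from it, and classified with
#' [abc_model_choice()].
#'
#' @param tables List of `reference_table`s.
#' @param n_pseudo Pseudo-observations per model.
#' @param tolerance Acceptance fraction.
#' @param seed Integer seed.
#' @param method Posterior used to pick the winner.
#' @return Confusion matrix (true models in rows, selected in columns).
#' @export
cross_validate_model_choice <- function(tables, n_pseudo, tolerance, seed,
                                        method = c("mnlogistic", "rejection")) {
  method <- match.arg(method)
  set.seed(seed)
  models <- vapply(tables, function(x) x$model, character(1))
  conf <- matrix(0L, length(models), length(models),
                 dimnames = list(true = models, selected = models))
  for (i in seq_along(tables)) {
    rows <- sample(nrow(tables[[i]]$stats), n_pseudo)
    for (r in rows) {
      obs <- tables[[i]]$stats[r, ]
      tabs <- tables
      tabs[[i]]$params <- tabs[[i]]$params[-r, , drop = FALSE]
      tabs[[i]]$stats <- tabs[[i]]$stats[-r, , drop = FALSE]
      post <- suppressWarnings(abc_model_choice(obs, tabs, tolerance))
      win <- names(which.max(post[[method]]))
      conf[models[i], win] <- conf[models[i], win] + 1L
    }
  }
  conf
}

#' Persist a reference table as TSV with a YAML sidecar
#'
#' The TSV holds one row per retained simulation (parameters, then summary
#' statistics, then the row seed); the sidecar records the model, statistic
#' order and build provenance.
#'
#' @param table A `reference_table`.
#' @param tsv_path Output TSV path (sidecar written next to it as
#'   `<path>.yaml`).
#' @return `tsv_path`, invisibly.
#' @export
write_reference_table <- function(table, tsv_path) {
  df <- cbind(table$params, as.data.frame(table$stats), .seed = table$seeds)
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(model = table$model,
                        parameters = names(table$params),
                        statistics = colnames(table$stats),
                        select = table$select,
                        n_executed = table$n_executed,
                        n_excluded = table$n_excluded),
                   paste0(tsv_path, ".yaml"))
  invisible(tsv_path)
}

#' Read a reference table written by [write_reference_table()]
#'
#' @param tsv_path TSV path (with its `.yaml` sidecar alongside).
#' @return A `reference_table`.
#' @export
read_reference_table <- function(tsv_path) {
  meta <- yaml::read_yaml(paste0(tsv_path, ".yaml"))
  df <- read.delim(tsv_path, check.names = FALSE)
  tab <- reference_table(meta$model,
                         df[, meta$parameters, drop = FALSE],
                         as.matrix(df[, meta$statistics, drop = FALSE]))
  tab$seeds <- df$.seed
  tab$select <- meta$select
  tab$n_executed <- meta$n_executed
  tab$n_excluded <- meta$n_excluded
  tab
}

#' Weighted highest-posterior-density interval
#'
#' HPD interval from a weighted kernel density on the (log-scale) sample:
#' the smallest density region containing the requested mass, returned as
#' the interval spanned by the retained grid.
#'
#' @param x Draws (e.g. adjusted log-parameters).
#' @param w Weights.
#' @param level Interval mass (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
weighted_hpd <- function(x, w, level = 0.95) {
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(unique(x)) == 1) return(c(x[1], x[1]))
  d <- suppressWarnings(density(x, weights = w / sum(w), bw = "nrd0"))
  o <- order(d$y, decreasing = TRUE)
  mass <- cumsum(d$y[o]) / sum(d$y)
  sel <- o[seq_len(which(mass >= level)[1])]
  range(d$x[sel])
}
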