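# R interface to the coalescent engine.

#' Locus configuration
#'
#' Bundles the per-locus simulation geometry: haplotype sample sizes of the
#' two populations, locus length, mutation rate per site per generation and
#' generation time in years.
#'
#' @param n_K,n_W Haplotype sample sizes (10 diploids each by default).
#' @param L Locus length in bp.
#' @param mu Mutation rate per site per generation.
#' @param g Generation time in years.
#' @return A named list (class `locus_config`).
#' @export
locus_config <- function(n_K = 20, n_W = 20, L = 1e4, mu = 0.8e-8, g = 2.5) {
  stopifnot(n_K >= 0, n_W >= 0, n_K + n_W >= 2, L > 0, mu > 0, g > 0)
  structure(list(n_K = n_K, n_W = n_W, L = L, mu = mu, g = g),
            class = "locus_config")
}

#' Simulate one structured-coalescent genealogy
#'
#' Exact event-driven sampling: within each epoch, pairwise coalescence
#' (rate `2/x` per pair in a population of relative size `x`, with
#' time-rescaling by thinning in exponential-growth epochs) competes with
#' backward lineage migration at rate `2*M/x` per lineage; at the terminal
#' epoch all lineages merge into the ancestral population.
#'
#' @param timeline Epoch matrix from [build_timeline()].
#' @param n_K,n_W Haplotype sample sizes (tips `1..n_K` belong to K).
#' @param seed Integer seed (the engine keeps its own RNG stream).
#' @return List with `parent` (1-based; `NA` for the root), `time` (node
#'   times in units of 4*N_ref generations), `tmrca`, `n_tips` and
#'   `n_migrations`.
#' @export
simulate_genealogy <- function(timeline, n_K, n_W, seed) {
  tr <- .sim_tree_cpp(unclass(timeline), n_K, n_W, as.double(seed))
  parent <- tr$parent + 1L
  parent[parent == 0L] <- NA_integer_
  list(parent = parent, time = tr$time, tmrca = max(tr$time),
       n_tips = tr$n_tips, n_migrations = tr$n_migrations)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Pure-R mutation sprinkler used for oracle-style checks: each branch gets
#' `Poisson(length * theta / 2)` mutations, each mutation a unique integer
#' position uniform on `[0, L)` (collisions redrawn, the finite-L
#' approximation to the infinite-sites model). The production simulation path
#' couples tree and mutations inside the compiled engine; this function
#' exists so the mutation model itself can be tested independently.
#'
#' @param tree A genealogy from [simulate_genealogy()].
#' @param theta Scaled mutation parameter `4*N_ref*mu*L` for the locus.
#' @param L Locus length in bp.
#' @param pop Population label per tip (`"K"`/`"W"`), recycled from counts if
#'   missing.
#' @param seed Optional integer seed for R's RNG.
#' @return A `haplotype_data` object: binary matrix (haplotypes x sites),
#'   strictly increasing 0-based `positions`, `pop` labels and `L`.
#' @export
drop_mutations <- function(tree, theta, L, pop = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (theta < 0) stop("theta must be >= 0")
  n <- tree$n_tips
  n_nodes <- length(tree$time)
  # descendant sets
  desc <- vector("list", n_nodes)
  for (v in seq_len(n)) desc[[v]] <- v
  for (v in seq_len(n_nodes - 1)) {
    p <- tree$parent[v]
    desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  cols <- list()
  pos <- integer(0)
  used <- integer(0)
  for (v in seq_len(n_nodes - 1)) {
    len <- tree$time[tree$parent[v]] - tree$time[v]
    m <- rpois(1, len * theta)
    if (m == 0) next
    if (length(used) + m > L) stop("locus length too short for theta")
    for (j in seq_len(m)) {
      repeat {
        p <- as.integer(floor(runif(1, 0, L)))
        if (!p %in% used) break
      }
      used <- c(used, p)
      col <- integer(n)
      col[desc[[v]][desc[[v]] <= n]] <- 1L
      cols[[length(cols) + 1]] <- col
      pos <- c(pos, p)
    }
  }
  if (is.null(pop)) pop <- rep("K", n)
  ord <- order(pos)
  mat <- if (length(cols)) do.call(cbind, cols)[, ord, drop = FALSE] else
    matrix(integer(0), nrow = n, ncol = 0)
  haplotype_data(mat, pos[ord], pop, L)
}

#' Construct a haplotype dataset object
#'
#' @param mat Binary matrix, haplotypes in rows, segregating sites in columns.
#' @param positions 0-based site positions within the locus, strictly
#'   increasing.
#' @param pop Population label per haplotype (`"K"` or `"W"`).
#' @param L Locus length in bp.
#' @return A `haplotype_data` object.
#' @export
haplotype_data <- function(mat, positions, pop, L) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(positions), nrow(mat) == length(pop), L > 0)
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (ncol(mat) > 0) {
    cs <- colSums(mat)
    if (any(cs == 0 | cs == nrow(mat)))
      stop("invariant column in haplotype matrix")
  }
  structure(list(mat = mat, positions = as.integer(positions),
                 pop = as.character(pop), L = L),
            class = "haplotype_data")
}

#' @export
print.haplotype_data <- function(x, ...) {
  cat("<haplotype_data> ", nrow(x$mat), " haplotypes (",
      sum(x$pop == "K"), " K / ", sum(x$pop == "W"), " W), ",
      ncol(x$mat), " segregating sites, L = ", x$L, " bp\n", sep = "")
  invisible(x)
}

#' Simulate one locus
#'
#' @param timeline Epoch matrix from [build_timeline()].
#' @param lc A [locus_config()].
#' @param seed Integer seed.
#' @param output `"stats"` for the per-locus summary-statistic vector
#'   (computed inside the engine from branch descendant sets), or
#'   `"haplotypes"` for the full binary matrix (with the identical statistics
#'   attached as attribute `stats`).
#' @return Named statistic vector, or a `haplotype_data`.
#' @export
simulate_locus <- function(timeline, lc, seed, output = c("stats", "haplotypes")) {
  output <- match.arg(output)
  theta <- locus_theta(lc$mu, lc$L)
  if (output == "stats") {
    .sim_locus_stats_cpp(unclass(timeline), lc$n_K, lc$n_W, theta, lc$L,
                         as.double(seed))
  } else {
    res <- .sim_locus_haplotypes_cpp(unclass(timeline), lc$n_K, lc$n_W, theta,
                                     lc$L, as.double(seed))
    hd <- haplotype_data(res$haplotypes, res$positions,
                         rep(c("K", "W"), c(lc$n_K, lc$n_W)), lc$L)
    attr(hd, "stats") <- res$stats
    attr(hd, "tmrca") <- res$tmrca
    hd
  }
}

#' Simulate a multi-locus dataset
#'
#' Loci are independent (free recombination between loci, none within); the
#' per-locus RNG streams are derived from `seed` by counter, so increasing
#' `n_loci` never perturbs earlier loci.
#'
#' @param model Model label.
#' @param params A `parameter_set`.
#' @param n_loci Number of loci.
#' @param lc A [locus_config()].
#' @param seed Integer seed.
#' @param output `"stats"` (matrix, 10 statistics x loci; the fast path used
#'   for reference tables) or `"haplotypes"` (list of `haplotype_data`).
#' @return See `output`.
#' @export
simulate_dataset <- function(model, params, n_loci, lc, seed,
                             output = c("stats", "haplotypes")) {
  output <- match.arg(output)
  stopifnot(n_loci >= 1)
  tl <- build_timeline(params, model, g = lc$g)
  theta <- locus_theta(lc$mu, lc$L)
  if (output == "stats") {
    .sim_dataset_stats_cpp(unclass(tl), lc$n_K, lc$n_W, theta, lc$L, n_loci,
                           as.double(seed))
  } else {
    lapply(seq_len(n_loci) - 1L, function(i) {
      res <- .sim_locus_haplotypes_cpp(unclass(tl), lc$n_K, lc$n_W, theta,
                                       lc$L, as.double(derive_seed_r(seed, i)))
      hd <- haplotype_data(res$haplotypes, res$positions,
                           rep(c("K", "W"), c(lc$n_K, lc$n_W)), lc$L)
      attr(hd, "stats") <- res$stats
      hd
    })
  }
}

# Mirror of the C++ per-locus seed derivation so the haplotype path visits
# the identical streams as the dataset stats path.
derive_seed_r <- function(root, idx) {
  as.double(root) * 1048573 + (as.double(idx) + 1) * 7919
}
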