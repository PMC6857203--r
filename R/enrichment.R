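# Permutation-based GO category over-representation test.

#' Permutation GO enrichment
#'
#' For each GO category (within one annotation domain), compares the number
#' of member genes observed in the gene set against the distribution over
#' `n_resamples` equally sized random sets drawn from the universe without
#' replacement. Significance uses the Z-score `(obs - mean)/sd` with a
#' normal p-value (two-sided by default) and a Benjamini-Hochberg correction
#' across the categories tested. Categories are filtered from the
#' significant results when the expected count is below 1 and at most one
#' member is observed.
#'
#' @param gene_set Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Character vector of all eligible genes.
#' @param go A `go_annotation` (see [go_annotation()]).
#' @param domain Which annotation domain to test (default: each in turn).
#' @param n_resamples Number of random sets (1,000).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param p_method `"normal"` (Z-based, the default) or `"empirical"`, the
#'   exact resampling tail `(1 + #{resampled at least as extreme}) /
#'   (n_resamples + 1)`, preferable for small categories where the normal
#'   approximation is poor.
#' @param alpha Significance level on the adjusted p (0.05).
#' @return Data frame with one row per category and domain: observed,
#'   expected, sd, Z, p, p_adjusted, filtered, significant.
#' @export
permutation_enrichment <- function(gene_set, universe, go,
                                   domain = NULL, n_resamples = 1000,
                                   seed = 1,
                                   alternative = c("two.sided", "greater"),
                                   p_method = c("normal", "empirical"),
                                   alpha = 0.05) {
  alternative <- match.arg(alternative)
  p_method <- match.arg(p_method)
  if (length(gene_set) < 1) stop("empty gene set")
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  set.seed(seed)
  domains <- if (is.null(domain)) names(go$domains) else domain
  out <- list()
  for (dm in domains) {
    memb <- go$domains[[dm]]
    if (length(memb) == 0) next
    # membership indicator matrix restricted to the universe
    M <- vapply(memb, function(g) as.integer(universe %in% g),
                integer(length(universe)))
    rownames(M) <- universe
    obs <- as.integer(colSums(M[gene_set, , drop = FALSE]))
    k <- length(gene_set)
    draws <- replicate(n_resamples, sample.int(length(universe), k))
    # counts per category per resample via an indicator cross product
    Z <- matrix(0L, length(universe), n_resamples)
    Z[cbind(as.vector(draws), rep(seq_len(n_resamples), each = k))] <- 1L
    resampled <- crossprod(M, Z) # categories x resamples
    expd <- rowMeans(resampled)
    sds <- apply(resampled, 1, sd)
    # degenerate resampling distribution: Z is 0 when the observation equals
    # the (constant) expectation, undefined (flagged) otherwise
    z <- ifelse(sds > 0, (obs - expd) / sds,
                ifelse(obs == expd, 0, NA_real_))
    if (p_method == "normal") {
      p <- if (alternative == "two.sided") 2 * pnorm(-abs(z)) else pnorm(-z)
    } else {
      hi <- rowSums(resampled >= obs) # tail counts over the resamples
      lo <- rowSums(resampled <= obs)
      p <- if (alternative == "two.sided")
        2 * (1 + pmin(hi, lo)) / (n_resamples + 1) else
        (1 + hi) / (n_resamples + 1)
    }
    p <- pmin(p, 1)
    tested <- !is.na(z)
    padj <- rep(NA_real_, length(p))
    padj[tested] <- bh_adjust(p[tested])
    filtered <- expd < 1 & obs <= 1
    out[[dm]] <- data.frame(
      domain = dm, category = colnames(M), observed = obs, expected = expd,
      sd = sds, z = z, p = p, p_adjusted = padj, filtered = filtered,
      significant = !filtered & !is.na(padj) & padj < alpha)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (monotone, order-preserving);
#' a thin wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
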