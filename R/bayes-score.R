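#' Normal-gamma prior on a block's mean and precision
#'
#' Conjugate prior for the Gaussian blocks of the two-way clustering model:
#' within one (gene cluster x condition cluster) block all values share a
#' mean mu and precision tau, with mu | tau ~ N(mu0, 1/(lambda0 tau)) and
#' tau ~ Gamma(alpha0, rate = beta0). The marginal likelihood of a block is
#' then available in closed form ([block_logml()]), which is what both the
#' Gibbs sampler and the condition-tree construction maximize.
#'
#' @param mu0 prior mean.
#' @param lambda0 prior pseudo-observations (> 0).
#' @param alpha0,beta0 gamma shape and rate on the precision (> 0).
#' @return An `ng_prior` object.
#' @export
ng_prior <- function(mu0 = 0, lambda0 = 0.1, alpha0 = 0.1, beta0 = 0.1) {
  stopifnot(lambda0 > 0, alpha0 > 0, beta0 > 0)
  structure(list(mu0 = mu0, lambda0 = lambda0, alpha0 = alpha0, beta0 = beta0),
            class = "ng_prior")
}

#' @describeIn ng_prior Weakly informative prior adapted to a matrix: prior
#'   mean at the grand mean, `beta0` at one tenth of the grand variance.
#' @param m an [expr_matrix()] or numeric matrix.
#' @export
default_prior <- function(m) {
  v <- as.numeric(m)
  ng_prior(mu0 = mean(v), lambda0 = 0.1, alpha0 = 0.1,
           beta0 = max(0.1 * mean((v - mean(v))^2), 1e-8))
}

#' Sufficient statistics of a block of expression values
#'
#' @param x numeric vector (possibly empty).
#' @return List with `n`, `s1` (sum), `s2` (sum of squares).
#' @export
block_stats <- function(x) {
  list(n = length(x), s1 = sum(x), s2 = sum(x^2))
}

#' Log marginal likelihood of one expression block
#'
#' Closed-form normal-gamma evidence of a block with sufficient statistics
#' (n, s1, s2): with m = s1/n, lambda_n = lambda0 + n, alpha_n = alpha0 + n/2
#' and beta_n = beta0 + (s2 - n m^2)/2 + lambda0 n (m - mu0)^2 / (2 lambda_n),
#'
#' logml = -(n/2) log(2 pi) + log(lambda0/lambda_n)/2
#'         + lgamma(alpha_n) - lgamma(alpha0)
#'         + alpha0 log(beta0) - alpha_n log(beta_n).
#'
#' The empty block (n = 0) has log marginal 0.
#'
#' @param stats a list as returned by [block_stats()].
#' @param prior an [ng_prior()].
#' @return Scalar log marginal likelihood.
#' @examples
#' block_logml(block_stats(0), ng_prior(0, 1, 1, 1)) # log(1/4)
#' @export
block_logml <- function(stats, prior) {
  stopifnot(inherits(prior, "ng_prior"))
  if (stats$n == 0) {
    if (stats$s1 != 0 || stats$s2 != 0) stop("empty block with non-zero sums")
    return(0)
  }
  if (stats$s2 * stats$n < stats$s1^2 - 1e-9 * max(1, stats$s2 * stats$n))
    stop("invalid block statistics: s2 * n < s1^2")
  .block_logml_cpp(stats$n, stats$s1, stats$s2, prior$mu0, prior$lambda0,
                   prior$alpha0, prior$beta0)
}

#' Log marginal likelihood of a full two-way partition
#'
#' Sums [block_logml()] over every (gene cluster, condition cluster) block of
#' a clustering solution; each block pools all values of the cluster's genes
#' in the cluster's conditions (genes of one cluster share block mean and
#' precision, the "tightly co-expressed" reading).
#'
#' @param m an [expr_matrix()] (or numeric matrix with dimnames).
#' @param sol a `cluster_solution` (see [sample_solution()]) or a list with
#'   `gene_assignment` (named integer over all rows) and
#'   `condition_assignment` (per gene cluster, named integer over all
#'   columns).
#' @param prior an [ng_prior()].
#' @return Scalar log marginal likelihood.
#' @export
partition_logml <- function(m, sol, prior) {
  ga <- sol$gene_assignment
  ca <- sol$condition_assignment
  if (!setequal(names(ga), rownames(m)))
    stop("gene assignment does not cover the matrix rows")
  total <- 0
  for (c_idx in sort(unique(ga))) {
    genes <- names(ga)[ga == c_idx]
    cond <- ca[[c_idx]]
    if (!setequal(names(cond), colnames(m)))
      stop("condition assignment of cluster ", c_idx,
           " does not cover the matrix columns")
    for (k in unique(cond)) {
      samp <- names(cond)[cond == k]
      total <- total + block_logml(
        block_stats(as.numeric(unclass(m)[genes, samp])), prior)
    }
  }
  total
}

#' Cached block statistics for incremental Gibbs moves
#'
#' Precomputes per-block sufficient statistics of a solution, plus a
#' checksum (total observation count and value sum) used to detect stale
#' caches.
#'
#' @inheritParams partition_logml
#' @return A `stats_cache` list.
#' @export
make_stats_cache <- function(m, sol, prior) {
  ga <- sol$gene_assignment
  ca <- sol$condition_assignment
  blocks <- lapply(sort(unique(ga)), function(c_idx) {
    genes <- names(ga)[ga == c_idx]
    cond <- ca[[c_idx]]
    lapply(sort(unique(cond)), function(k) {
      samp <- names(cond)[cond == k]
      block_stats(as.numeric(unclass(m)[genes, samp]))
    })
  })
  structure(list(blocks = blocks, sol = sol, prior = prior,
                 checksum = c(n = length(m), s1 = sum(m))),
            class = "stats_cache")
}

#' Score delta of moving one gene between clusters
#'
#' Returns `partition_logml(after) - partition_logml(before)` for moving
#' `gene` from cluster `from` to cluster `to` (or `"new"` for a fresh
#' singleton cluster with a single condition cluster), computed incrementally
#' from cached block statistics — the work-horse move evaluation of the
#' Gibbs sampler, exposed for verification against full recomputation.
#'
#' @param cache a [make_stats_cache()] result.
#' @param m the matrix the cache was built from.
#' @param gene row identifier to move.
#' @param from,to cluster indices (`to` may be `"new"`).
#' @return Scalar log marginal delta (0 for `from == to`).
#' @export
delta_move_gene <- function(cache, m, gene, from, to) {
  stopifnot(inherits(cache, "stats_cache"))
  if (length(m) != cache$checksum["n"] ||
      abs(sum(m) - cache$checksum["s1"]) > 1e-8 * max(1, abs(cache$checksum["s1"])))
    stop("stale statistics cache: matrix does not match checksum")
  if (identical(from, to)) return(0)
  prior <- cache$prior
  ca <- cache$sol$condition_assignment
  x <- unclass(m)[gene, ]

  gene_block <- function(cond, k) {
    samp <- names(cond)[cond == k]
    block_stats(as.numeric(x[samp]))
  }
  delta <- 0
  cond_f <- ca[[from]]
  ks_f <- sort(unique(cond_f))
  for (i in seq_along(ks_f)) {
    b <- cache$blocks[[from]][[i]]
    g <- gene_block(cond_f, ks_f[i])
    nb <- list(n = b$n - g$n, s1 = b$s1 - g$s1, s2 = b$s2 - g$s2)
    if (nb$n == 0) nb <- list(n = 0L, s1 = 0, s2 = 0)
    delta <- delta + block_logml(nb, prior) - block_logml(b, prior)
  }
  if (identical(to, "new")) {
    delta <- delta + block_logml(block_stats(as.numeric(x)), prior)
  } else {
    cond_t <- ca[[to]]
    ks_t <- sort(unique(cond_t))
    for (i in seq_along(ks_t)) {
      b <- cache$blocks[[to]][[i]]
      g <- gene_block(cond_t, ks_t[i])
      delta <- delta +
        block_logml(list(n = b$n + g$n, s1 = b$s1 + g$s1, s2 = b$s2 + g$s2), prior) -
        block_logml(b, prior)
    }
  }
  delta
}
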