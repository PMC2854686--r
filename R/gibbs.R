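#' Draw one two-way clustering solution by Gibbs sampling
#'
#' Alternates full sweeps of (i) gene reassignment — each gene, in random
#' order, is reassigned among the existing clusters plus one empty cluster
#' with probability proportional to cluster size (or the concentration
#' `gamma` for the empty one) times `exp(delta logml)` — and (ii) per-cluster
#' condition reassignment under the same scheme on columns. The number of
#' clusters is open-ended (Chinese-restaurant style); a fresh cluster starts
#' with a single condition cluster. The returned solution is the best-scoring
#' (maximum [partition_logml()]) state visited, with empty clusters pruned —
#' the chain is used as a stochastic optimizer, and repeated seeded runs form
#' the ensemble that consensus clustering averages.
#'
#' @param m an [expr_matrix()] (>= 2 rows, >= 2 columns).
#' @param prior an [ng_prior()]; default [default_prior()] of `m`.
#' @param n_sweeps number of full sweeps (default 100).
#' @param seed integer seed for this run.
#' @param gamma concentration parameter for opening a new (gene or
#'   condition) cluster; default 1.
#' @param sample_conditions set `FALSE` to hold every cluster at a single
#'   condition cluster (gene-only clustering; used for diagnostics).
#' @param record_trace if `TRUE`, attach a sweeps-by-genes matrix of
#'   canonical cluster labels visited (for chain diagnostics).
#' @return A `cluster_solution`: list with `gene_assignment` (named integer
#'   over rows), `condition_assignment` (per gene cluster, named integer over
#'   columns), `logml`, `seed`, `n_sweeps`.
#' @export
sample_solution <- function(m, prior = default_prior(m), n_sweeps = 100,
                            seed = 1, gamma = 1,
                            sample_conditions = TRUE, record_trace = FALSE) {
  if (nrow(m) < 2 || ncol(m) < 2) stop("matrix must be at least 2 x 2")
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  res <- .gibbs_two_way_cpp(unclass(m), prior$mu0, prior$lambda0,
                            prior$alpha0, prior$beta0, as.integer(n_sweeps),
                            gamma, gamma, TRUE, sample_conditions,
                            record_trace)
  ga <- stats::setNames(res$gene_assignment, rownames(m))
  ca <- lapply(res$condition_assignment, stats::setNames, colnames(m))
  out <- structure(list(gene_assignment = ga, condition_assignment = ca,
                        logml = res$logml, seed = as.integer(seed),
                        n_sweeps = as.integer(n_sweeps),
                        logml_trace = res$logml_trace),
                   class = "cluster_solution")
  if (record_trace) attr(out, "trace") <- res$trace
  out
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d genes in %d clusters, logml %.3f (seed %d, %d sweeps)\n",
              length(x$gene_assignment), length(x$condition_assignment),
              x$logml, x$seed, x$n_sweeps))
  invisible(x)
}

#' Run an ensemble of independent clustering solutions
#'
#' Produces `n_runs` solutions from seeds `base_seed + 0 .. n_runs - 1`, in
#' deterministic order. The published analysis uses 30 runs.
#'
#' @inheritParams sample_solution
#' @param n_runs number of independent runs (default 30).
#' @param base_seed seed of the first run.
#' @return List of `cluster_solution` objects.
#' @export
run_ensemble <- function(m, prior = default_prior(m), n_runs = 30,
                         n_sweeps = 100, base_seed = 1, gamma = 1) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs) - 1L, function(i)
    sample_solution(m, prior, n_sweeps = n_sweeps, seed = base_seed + i,
                    gamma = gamma))
}

#' Draw a condition clustering of a gene set
#'
#' Columns-only Gibbs: the given genes are pooled into a single cluster and
#' only the condition partition is resampled. Returns the final state of the
#' chain (a draw, not the optimum), which is what the per-module condition
#' trees are built from so that the tree ensemble is diverse.
#'
#' @param m an [expr_matrix()] restricted to the module's genes.
#' @inheritParams sample_solution
#' @return Named integer vector over columns: condition-cluster index.
#' @export
sample_condition_partition <- function(m, prior = default_prior(m),
                                       n_sweeps = 20, seed = 1, gamma = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  res <- .gibbs_two_way_cpp(unclass(m), prior$mu0, prior$lambda0,
                            prior$alpha0, prior$beta0, as.integer(n_sweeps),
                            1, gamma, FALSE, TRUE, FALSE)
  k <- res$final_cond
  # renumber by first occurrence for determinism
  stats::setNames(match(k, unique(k)), colnames(m))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
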