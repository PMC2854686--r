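#' Co-clustering frequency matrix of an ensemble
#'
#' For every gene pair, the fraction of ensemble runs in which the two genes
#' share a cluster. This averages the partially overlapping solutions into a
#' single weighted graph from which tight clusters are extracted.
#'
#' @param solutions list of `cluster_solution` objects over the same gene
#'   universe.
#' @return A `cocluster_matrix`: symmetric numeric matrix in `[0, 1]` with
#'   unit diagonal, attribute `n_solutions`.
#' @export
coclustering_matrix <- function(solutions) {
  stopifnot(length(solutions) >= 1)
  ids <- names(solutions[[1]]$gene_assignment)
  F_ <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (sol in solutions) {
    ga <- sol$gene_assignment
    if (!setequal(names(ga), ids))
      stop("solutions have mismatched gene universes")
    ga <- ga[ids]
    same <- outer(ga, ga, `==`)
    F_ <- F_ + same
  }
  F_ <- F_ / length(solutions)
  structure(F_, n_solutions = length(solutions),
            class = c("cocluster_matrix", "matrix", "array"))
}

#' Extract tight clusters by spectral peeling
#'
#' Iteratively peels tight clusters off a co-clustering frequency matrix:
#' compute the dominant eigenvector `v` of the current matrix (negative
#' entries zeroed; by Perron-Frobenius the dominant eigenvector of the
#' nonnegative matrix can be taken nonnegative), take as candidate the genes
#' with `v_i >= membership_threshold * max(v)`, accept the candidate if its
#' mean pairwise co-clustering frequency is at least 0.5 and its size at
#' least `min_size`, zero the accepted genes' rows and columns, and repeat
#' until no acceptable cluster remains. Clusters are disjoint by
#' construction.
#'
#' Candidates are refined before acceptance by spectral bipartitioning:
#' when two equally cohesive clusters are weakly coupled, the dominant
#' eigenvector is (near-)constant across their union and the threshold alone
#' cannot separate them, so the candidate is split by the sign of the second
#' eigenvector of its submatrix whenever that reveals two groups of size >=
#' `min_size` that are each internally cohesive (mean within-frequency >=
#' 0.5) but weakly connected (mean between-frequency < 0.5); the more
#' cohesive half is kept and the other is left for a later peel.
#'
#' @param C a [coclustering_matrix()] (symmetric, entries in `[0, 1]`).
#' @param membership_threshold fraction of the eigenvector maximum required
#'   for membership (default 0.7).
#' @param min_size smallest reportable cluster (default 3, the size of the
#'   smallest published module).
#' @return A `tight_cluster_set`: list of disjoint gene-ID character
#'   vectors, ordered by extraction; attribute `min_size`.
#' @export
extract_tight_clusters <- function(C, membership_threshold = 0.7,
                                   min_size = 3) {
  Fm <- unclass(C)
  if (!isSymmetric(unname(Fm), tol = 1e-8)) stop("co-clustering matrix must be symmetric")
  ids <- rownames(Fm)
  active <- rep(TRUE, nrow(Fm))
  clusters <- list()
  repeat {
    if (sum(active) < min_size) break
    sub <- Fm
    sub[!active, ] <- 0
    sub[, !active] <- 0
    if (all(sub == 0)) break
    eig <- eigen(sub, symmetric = TRUE)
    v <- eig$vectors[, 1]
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    cand <- which(v >= membership_threshold * max(v) & active)
    if (length(cand) < min_size) break
    cand <- refine_candidate(Fm, cand, min_size)
    within <- Fm[cand, cand]
    mean_f <- mean(within[upper.tri(within)])
    if (!is.finite(mean_f) || mean_f < 0.5) break
    clusters[[length(clusters) + 1]] <- ids[cand]
    active[cand] <- FALSE
  }
  structure(clusters, min_size = min_size, class = "tight_cluster_set")
}

# mean off-diagonal frequency (NaN for a single gene)
mean_offdiag <- function(M) mean(M[upper.tri(M)])

# Spectral bipartition refinement of a candidate cluster: recursively split
# off weakly coupled cohesive subgroups along the sign of the second
# eigenvector; deterministic tie-breaks (size, then lexicographic id).
refine_candidate <- function(Fm, cand, min_size) {
  repeat {
    if (length(cand) < 2 * min_size) return(cand)
    sub <- Fm[cand, cand]
    u <- eigen(sub, symmetric = TRUE)$vectors[, 2]
    A <- cand[u >= 0]
    B <- cand[u < 0]
    if (length(A) < min_size || length(B) < min_size) return(cand)
    between <- mean(Fm[A, B])
    wA <- mean_offdiag(Fm[A, A])
    wB <- mean_offdiag(Fm[B, B])
    if (!(between < 0.5 && wA >= 0.5 && wB >= 0.5)) return(cand)
    keep_A <- wA > wB ||
      (wA == wB && (length(A) > length(B) ||
                    (length(A) == length(B) &&
                     min(rownames(Fm)[A]) <= min(rownames(Fm)[B]))))
    cand <- if (keep_A) A else B
  }
}

#' @export
print.tight_cluster_set <- function(x, ...) {
  cat(sprintf("<tight_cluster_set> %d clusters (sizes %s)\n", length(x),
              paste(lengths(x), collapse = ", ")))
  invisible(x)
}

#' @describeIn extract_tight_clusters Tidy view: one row per (cluster, gene).
#' @param clusters a `tight_cluster_set`.
#' @export
tight_clusters_tidy <- function(clusters) {
  if (!length(clusters))
    return(tibble::tibble(module = integer(), gene = character()))
  tibble::tibble(module = rep(seq_along(clusters), lengths(clusters)),
                 gene = unlist(clusters, use.names = FALSE))
}
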