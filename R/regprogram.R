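#' Build hierarchical condition trees for a module
#'
#' For each tree, a condition clustering of the module's samples is drawn by
#' columns-only Gibbs sampling ([sample_condition_partition()], genes
#' pooled), and the resulting condition clusters are then linked
#' agglomeratively: at each step the pair of clusters whose merge yields the
#' largest change in [block_logml()] is joined, and the merge is recorded as
#' an internal node splitting a low-expression (left) from a
#' high-expression (right) sample set. A draw with a single condition
#' cluster yields a tree with no nodes. The published analysis uses 100
#' trees per module.
#'
#' @param m an [expr_matrix()] over all samples.
#' @param genes character vector of the module's member rows.
#' @param prior an [ng_prior()].
#' @param n_trees number of trees (default 100).
#' @param base_seed seed of the first tree; tree `t` uses `base_seed + t - 1`.
#' @param n_sweeps Gibbs sweeps per condition draw (default 20).
#' @return List of `condition_tree` objects: each has `leaves` (list of
#'   sample-ID vectors) and `nodes` (list of `left`, `right` sample-ID
#'   vectors plus `weight = |left| + |right|`), with `left` the side with
#'   the lower pooled module mean.
#' @export
build_condition_trees <- function(m, genes, prior = default_prior(m),
                                  n_trees = 100, base_seed = 1,
                                  n_sweeps = 20) {
  stopifnot(length(genes) >= 1, ncol(m) >= 4)
  sub <- unclass(m)[genes, , drop = FALSE]
  lapply(seq_len(n_trees), function(t) {
    cond <- sample_condition_partition(
      m[match(genes, rownames(m)), , drop = FALSE], prior,
      n_sweeps = n_sweeps, seed = base_seed + t - 1)
    leaves <- split(names(cond), cond)
    names(leaves) <- NULL
    agglomerate_conditions(sub, leaves, prior)
  })
}

# Agglomerative linkage of condition clusters by marginal-likelihood gain.
agglomerate_conditions <- function(sub, leaves, prior) {
  groups <- leaves
  nodes <- list()
  pooled_stats <- function(samp) block_stats(as.numeric(sub[, samp]))
  pooled_mean <- function(samp) mean(sub[, samp])
  while (length(groups) > 1) {
    best <- NULL
    best_gain <- -Inf
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        a <- pooled_stats(groups[[i]])
        b <- pooled_stats(groups[[j]])
        ab <- list(n = a$n + b$n, s1 = a$s1 + b$s1, s2 = a$s2 + b$s2)
        gain <- block_logml(ab, prior) - block_logml(a, prior) -
          block_logml(b, prior)
        if (gain > best_gain) {
          best_gain <- gain
          best <- c(i, j)
        }
      }
    }
    A <- groups[[best[1]]]
    B <- groups[[best[2]]]
    if (pooled_mean(A) <= pooled_mean(B)) {
      node <- list(left = A, right = B, weight = length(A) + length(B))
    } else {
      node <- list(left = B, right = A, weight = length(A) + length(B))
    }
    nodes[[length(nodes) + 1]] <- node
    groups[[best[2]]] <- NULL
    groups[[best[1]]] <- c(A, B)
  }
  structure(list(leaves = leaves, nodes = nodes), class = "condition_tree")
}

#' Fuzzy split score of a regulator at a tree node
#'
#' Scores how well a standardized regulator profile separates the two sample
#' sets of a node: for the positive orientation,
#' `score = max_z sum_{c in L} log sigma(beta (z - x_c)) +
#'                sum_{c in R} log sigma(beta (x_c - z))`
#' with `sigma` the logistic function; the negative orientation swaps the
#' sides. `z` is searched over a deterministic finite grid (the observed
#' values, midpoints of consecutive sorted unique values, and one point
#' beyond each extreme). The better orientation is returned with its optimal
#' split value `z` and sign. Scores are always <= 0; an uninformative
#' (constant, all-zero) regulator scores `(|L| + |R|) log(1/2)`.
#'
#' Because `x_r` is standardized (and quantized, see [standardize_row()]),
#' the score is exactly invariant under positive affine transforms of the
#' raw regulator row — miRNA and mRNA regulators measured on different
#' scales are therefore directly comparable.
#'
#' @param x_r standardized regulator profile, named by sample.
#' @param L,R disjoint non-empty sample-ID vectors (the node's sides; `L` is
#'   the low-expression side).
#' @param beta sharpness of the logistic split (default 2).
#' @return List with `score`, `z`, `sign`.
#' @export
node_split_score <- function(x_r, L, R, beta = 2) {
  stopifnot(length(L) > 0, length(R) > 0, beta > 0)
  if (length(intersect(L, R))) stop("L and R must be disjoint")
  Z <- matrix(x_r, nrow = 1, dimnames = list("r", names(x_r)))
  res <- .node_score_batch_cpp(Z, match(L, names(x_r)), match(R, names(x_r)),
                               beta)
  list(score = res$score[1], z = res$z[1], sign = res$sign[1])
}

#' Rank candidate regulators at one node
#'
#' Scores every candidate with [node_split_score()] and keeps the top
#' `min(K, n_candidates)`; ties in score are broken by lexicographic
#' regulator ID. The published analysis assigns up to 100 regulators per
#' node.
#'
#' @param node a node of a [build_condition_trees()] tree.
#' @param Z standardized candidate matrix (regulators x samples), e.g. from
#'   [standardize_candidates()].
#' @param K maximum number of regulators retained (default 100).
#' @param beta logistic sharpness (default 2).
#' @return Tibble with `regulator`, `score`, `z`, `sign`, `rank`.
#' @export
assign_regulators_to_node <- function(node, Z, K = 100, beta = 2) {
  stopifnot(K >= 1)
  res <- .node_score_batch_cpp(Z, match(node$left, colnames(Z)),
                               match(node$right, colnames(Z)), beta)
  out <- tibble::tibble(regulator = rownames(Z), score = res$score,
                        z = res$z, sign = res$sign)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$regulator)
  out <- dplyr::slice_head(out, n = min(K, nrow(out)))
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Standardize candidate regulator profiles
#'
#' @param m an [expr_matrix()].
#' @param candidates character vector of candidate row IDs (must exist in
#'   `m`).
#' @return Numeric matrix (candidates x samples) of standardized profiles.
#' @export
standardize_candidates <- function(m, candidates) {
  missing_ids <- setdiff(candidates, rownames(m))
  if (length(missing_ids))
    stop("candidates absent from matrix: ", paste(missing_ids, collapse = ", "))
  candidates <- sort(candidates)
  Z <- t(vapply(candidates,
                function(r) as.numeric(standardize_row(unclass(m)[r, ])),
                numeric(ncol(m))))
  dimnames(Z) <- list(candidates, colnames(m))
  Z
}

#' Aggregate per-node assignments into ensemble global scores
#'
#' The strength with which a regulator participates in a module's regulatory
#' program is summed over all nodes of all trees where it was assigned:
#' `global_score(r) = sum w_node * (s_r - sbar_node)`, with `w_node` the
#' fraction of samples under the node and `sbar_node` the mean score of that
#' node's retained top-K list (so the score measures strength above peers,
#' which is what makes the random-regulator null comparable). Negative sums
#' are floored at 0. The sign is the sign of the node-weighted majority of
#' the regulator's per-node signs (ties count as +1).
#'
#' @param assignments tibble of per-node assignments with columns
#'   `regulator`, `score`, `sign`, `w` (node weight fraction), `sbar` (node
#'   top-K mean score), as produced inside [score_regulators()].
#' @param all_regulators character vector of every scored candidate (rows
#'   with no assignment score 0).
#' @return Tibble with `regulator`, `global_score`, `sign`,
#'   `n_nodes_assigned`.
#' @export
global_scores <- function(assignments, all_regulators) {
  agg <- assignments |>
    dplyr::mutate(contrib = .data$w * (.data$score - .data$sbar)) |>
    dplyr::group_by(.data$regulator) |>
    dplyr::summarise(global_score = max(0, sum(.data$contrib)),
                     sign_sum = sum(.data$w * .data$sign),
                     n_nodes_assigned = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(sign = ifelse(.data$sign_sum >= 0, 1L, -1L)) |>
    dplyr::select("regulator", "global_score", "sign", "n_nodes_assigned")
  missing_ids <- setdiff(all_regulators, agg$regulator)
  dplyr::bind_rows(agg,
                   tibble::tibble(regulator = missing_ids, global_score = 0,
                                  sign = 1L, n_nodes_assigned = 0L)) |>
    dplyr::arrange(dplyr::desc(.data$global_score), .data$regulator)
}

#' Learn regulatory programs and score regulators for a set of modules
#'
#' For each module: build `n_trees` condition trees, assign the top-K
#' candidates at every internal node, and aggregate into global scores
#' ([global_scores()]). Node records (sides, weight, top-K mean) are kept so
#' the random-regulator null ([null_scores()]) can score arbitrary
#' regulators through the identical path.
#'
#' @param m an [expr_matrix()].
#' @param modules a `tight_cluster_set` or list of gene-ID vectors.
#' @param candidates character vector of candidate regulator row IDs.
#' @param prior an [ng_prior()].
#' @param n_trees trees per module (default 100).
#' @param top_k regulators retained per node (default 100).
#' @param beta logistic sharpness (default 2).
#' @param seed master seed for the tree draws.
#' @param n_sweeps Gibbs sweeps per condition draw.
#' @return A `regulator_program_fit`: list with `scores` (tibble:
#'   `module`, `regulator`, `global_score`, `sign`, `n_nodes_assigned`),
#'   `node_records` (per-node tibble incl. `w`, `sbar`), `Z` (standardized
#'   candidates), `params`.
#' @export
score_regulators <- function(m, modules, candidates,
                             prior = default_prior(m), n_trees = 100,
                             top_k = 100, beta = 2, seed = 1, n_sweeps = 20) {
  Z <- standardize_candidates(m, candidates)
  S <- ncol(m)
  all_scores <- list()
  node_records <- list()
  for (mod_i in seq_along(modules)) {
    genes <- modules[[mod_i]]
    trees <- build_condition_trees(
      m, genes, prior, n_trees = n_trees,
      base_seed = derive_seed(seed, mod_i), n_sweeps = n_sweeps)
    assigns <- list()
    records <- list()
    for (t in seq_along(trees)) {
      for (nd_i in seq_along(trees[[t]]$nodes)) {
        nd <- trees[[t]]$nodes[[nd_i]]
        top <- assign_regulators_to_node(nd, Z, K = top_k, beta = beta)
        w <- nd$weight / S
        sbar <- mean(top$score)
        assigns[[length(assigns) + 1]] <-
          dplyr::mutate(top, tree = t, node = nd_i, w = w, sbar = sbar)
        records[[length(records) + 1]] <- tibble::tibble(
          module = mod_i, tree = t, node = nd_i, w = w, sbar = sbar,
          left = list(nd$left), right = list(nd$right))
      }
    }
    scores_m <- if (length(assigns)) {
      global_scores(dplyr::bind_rows(assigns), rownames(Z))
    } else {
      tibble::tibble(regulator = rownames(Z), global_score = 0, sign = 1L,
                     n_nodes_assigned = 0L)
    }
    all_scores[[mod_i]] <- dplyr::mutate(scores_m, module = mod_i,
                                         .before = 1)
    if (length(records)) node_records[[mod_i]] <- dplyr::bind_rows(records)
  }
  structure(list(
    scores = dplyr::bind_rows(all_scores),
    node_records = if (length(node_records)) dplyr::bind_rows(node_records)
                   else tibble::tibble(),
    Z = Z, beta = beta,
    params = list(n_trees = n_trees, top_k = top_k, beta = beta,
                  seed = seed, n_sweeps = n_sweeps)),
    class = "regulator_program_fit")
}

#' @export
print.regulator_program_fit <- function(x, ...) {
  cat(sprintf("<regulator_program_fit> %d modules, %d candidates, %d tree nodes\n",
              length(unique(x$scores$module)), nrow(x$Z),
              nrow(x$node_records)))
  invisible(x)
}

# One assignment's contribution, shared verbatim between the true global
# score and the random-regulator null: w * (score - sbar), floored at 0
# when aggregated alone.
node_contribution <- function(record, Z, regulator, beta) {
  res <- .node_score_batch_cpp(
    Z[regulator, , drop = FALSE],
    match(record$left[[1]], colnames(Z)),
    match(record$right[[1]], colnames(Z)), beta)
  max(0, record$w * (res$score[1] - record$sbar))
}
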