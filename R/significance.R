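#' Random-regulator null score distribution
#'
#' Draws `n_draws` (candidate, node) pairs uniformly — the candidate from the
#' full candidate set, the node from all recorded tree nodes across modules
#' — and scores each through the identical path used for true regulators:
#' the node contribution `w * (score - sbar)` aggregated exactly as
#' [global_scores()] would for a single assignment (floored at 0). The
#' resulting distribution is the reference against which true global scores
#' are judged (the true-versus-random comparison of the published figure).
#'
#' @param fit a `regulator_program_fit` from [score_regulators()].
#' @param n_draws number of random assignments (default 1000).
#' @param seed integer seed.
#' @return A `null_score_set`: tibble with `draw`, `module`, `tree`, `node`,
#'   `regulator`, `score`; attributes `n_draws`, `seed`.
#' @export
null_scores <- function(fit, n_draws = 1000, seed = 1) {
  stopifnot(inherits(fit, "regulator_program_fit"), n_draws >= 1)
  if (!nrow(fit$node_records)) stop("fit has no tree nodes to sample")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  regs <- rownames(fit$Z)
  node_idx <- sample.int(nrow(fit$node_records), n_draws, replace = TRUE)
  reg_idx <- sample.int(length(regs), n_draws, replace = TRUE)
  scores <- vapply(seq_len(n_draws), function(i) {
    node_contribution(fit$node_records[node_idx[i], ], fit$Z,
                      regs[reg_idx[i]], fit$beta)
  }, numeric(1))
  out <- tibble::tibble(
    draw = seq_len(n_draws),
    module = fit$node_records$module[node_idx],
    tree = fit$node_records$tree[node_idx],
    node = fit$node_records$node[node_idx],
    regulator = regs[reg_idx],
    score = scores)
  structure(out, n_draws = n_draws, seed = as.integer(seed),
            class = c("null_score_set", class(out)))
}

#' Apply the top-quantile score cutoff
#'
#' Flags the top `quantile` fraction of all true (module, regulator)
#' interaction scores; `quantile = 0.02` reproduces the published
#' stringent top-2% rule. The cutoff score is the `ceiling(quantile * N)`-th
#' largest score; ties at the cutoff are all retained (inclusive `>=`). The
#' maximum null score is reported alongside as the separation sanity check,
#' not as the threshold.
#'
#' @param scores regulator score table (tibble with `module`, `regulator`,
#'   `global_score`, `sign`), e.g. `fit$scores`.
#' @param null a [null_scores()] result (optional; `max_null_score` is `NA`
#'   without it).
#' @param quantile fraction of interactions to keep, in (0, 1].
#' @return A `regulator_calls` tibble: the score rows plus `passes_cutoff`;
#'   attributes `cutoff_score`, `max_null_score`, `quantile_used`.
#' @export
apply_cutoff <- function(scores, null = NULL, quantile = 0.02) {
  stopifnot(nrow(scores) > 0, quantile > 0, quantile <= 1)
  n_keep <- ceiling(quantile * nrow(scores))
  cutoff <- sort(scores$global_score, decreasing = TRUE)[n_keep]
  out <- dplyr::mutate(scores, passes_cutoff = .data$global_score >= cutoff)
  out <- dplyr::arrange(out, dplyr::desc(.data$global_score), .data$module,
                        .data$regulator)
  structure(out,
            cutoff_score = cutoff,
            max_null_score = if (is.null(null)) NA_real_ else max(null$score),
            quantile_used = quantile,
            class = c("regulator_calls", class(out)))
}

#' Binned true-versus-null score histogram data
#'
#' Tabulates true interaction scores and random-regulator null scores on a
#' common set of bins — the data behind the two-color score-distribution
#' figure. Written as TSV by the pipeline; plot with [autoplot.module_network_fit()].
#'
#' @param scores regulator score table.
#' @param null a [null_scores()] result.
#' @param n_bins number of bins (default 40).
#' @return Tibble with `bin_lo`, `bin_hi`, `set` (`"true"`/`"random"`),
#'   `count`.
#' @export
score_histogram <- function(scores, null, n_bins = 40) {
  all_v <- c(scores$global_score, null$score)
  rng <- range(all_v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- function(v) {
    idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
                n_bins)
    tabulate(idx, n_bins)
  }
  tibble::tibble(
    bin_lo = rep(breaks[-length(breaks)], 2),
    bin_hi = rep(breaks[-1], 2),
    set = rep(c("true", "random"), each = n_bins),
    count = c(bin(scores$global_score), bin(null$score)))
}
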