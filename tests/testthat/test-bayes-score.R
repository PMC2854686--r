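test_that("block evidence matches closed-form and numerical-integration oracles", {
  pr <- ng_prior(0, 1, 1, 1)
  expect_identical(block_logml(block_stats(numeric(0)), pr), 0)
  # prior predictive at a single 0 is exactly 1/4 for the unit prior
  expect_equal(block_logml(block_stats(0), pr), log(0.25), tolerance = 1e-9)
  expect_equal(block_logml(block_stats(c(1, -1)), pr), -3.7734779,
               tolerance = 1e-6)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(1:6, 1), sd = 1.5)
    prr <- ng_prior(runif(1, -1, 1), runif(1, 0.3, 2), runif(1, 0.3, 2),
                    runif(1, 0.3, 2))
    expect_equal(block_logml(block_stats(x), prr),
                 logml_integration_oracle(x, prr), tolerance = 1e-6)
  }
})

test_that("evidence satisfies the chain rule through the Student-t predictive", {
  pr <- ng_prior(0.3, 0.8, 1.2, 0.9)
  set.seed(5)
  x <- rnorm(6)
  for (i in seq_along(x)) {
    prev <- x[seq_len(i - 1)]
    delta <- block_logml(block_stats(x[seq_len(i)]), pr) -
      block_logml(block_stats(prev), pr)
    n <- length(prev)
    lam_n <- pr$lambda0 + n
    alpha_n <- pr$alpha0 + n / 2
    mu_n <- (pr$lambda0 * pr$mu0 + sum(prev)) / lam_n
    beta_n <- if (n > 0)
      pr$beta0 + 0.5 * sum((prev - mean(prev))^2) +
        pr$lambda0 * n * (mean(prev) - pr$mu0)^2 / (2 * lam_n)
    else pr$beta0
    scale <- sqrt(beta_n * (lam_n + 1) / (alpha_n * lam_n))
    log_pred <- dt((x[i] - mu_n) / scale, df = 2 * alpha_n, log = TRUE) -
      log(scale)
    expect_equal(delta, log_pred, tolerance = 1e-9)
  }
})

test_that("partition evidence is additive over blocks and invariant to labeling and order", {
  m <- toy_matrix(4, 4, seed = 2)
  pr <- default_prior(m)
  ga <- stats::setNames(c(1L, 1L, 2L, 2L), rownames(m))
  ca <- list(stats::setNames(c(1L, 1L, 2L, 2L), colnames(m)),
             stats::setNames(c(1L, 2L, 2L, 1L), colnames(m)))
  sol <- list(gene_assignment = ga, condition_assignment = ca)
  expect_equal(partition_logml(m, sol, pr),
               partition_logml_bruteforce(m, ga, ca, pr), tolerance = 1e-12)
  # single block = whole matrix flattened
  expect_equal(partition_logml(m, flat_solution(m), pr),
               block_logml(block_stats(as.numeric(m)), pr), tolerance = 1e-12)
  # relabel clusters (swap 1 and 2) and permute rows/columns
  ga2 <- stats::setNames(3L - ga, rownames(m))
  sol2 <- list(gene_assignment = ga2, condition_assignment = ca[2:1])
  expect_equal(partition_logml(m, sol2, pr), partition_logml(m, sol, pr),
               tolerance = 1e-9)
  perm <- m[c(3, 1, 4, 2), c(4, 2, 1, 3)]
  expect_equal(partition_logml(perm, sol, pr), partition_logml(m, sol, pr),
               tolerance = 1e-9)
  bad <- sol
  bad$gene_assignment <- ga[1:3]
  expect_error(partition_logml(m, bad, pr), "cover")
})

test_that("incremental move deltas equal brute-force recomputation", {
  m <- toy_matrix(10, 8, seed = 7)
  pr <- default_prior(m)
  set.seed(3)
  ga <- stats::setNames(sample(1:3, 10, replace = TRUE), rownames(m))
  ga[1:3] <- 1:3  # ensure all clusters populated
  ca <- lapply(1:3, function(i)
    stats::setNames(sample(1:2, 8, replace = TRUE), colnames(m)))
  sol <- list(gene_assignment = ga, condition_assignment = ca)
  cache <- make_stats_cache(m, sol, pr)
  base <- partition_logml(m, sol, pr)
  for (g in rownames(m)) {
    expect_identical(delta_move_gene(cache, m, g, ga[[g]], ga[[g]]), 0)
    for (to in setdiff(1:3, ga[[g]])) {
      moved <- ga
      moved[[g]] <- to
      full <- partition_logml(m, list(gene_assignment = moved,
                                      condition_assignment = ca), pr) - base
      expect_equal(delta_move_gene(cache, m, g, ga[[g]], to), full,
                   tolerance = 1e-9)
      # antisymmetry: the reverse move from the moved state negates the delta
      cache_m <- make_stats_cache(m, list(gene_assignment = moved,
                                          condition_assignment = ca), pr)
      expect_equal(delta_move_gene(cache_m, m, g, to, ga[[g]]), -full,
                   tolerance = 1e-9)
    }
  }
})

test_that("stale caches are detected and merged-block deltas match recomputation", {
  m <- toy_matrix(6, 5, seed = 9)
  pr <- default_prior(m)
  sol <- flat_solution(m)
  cache <- make_stats_cache(m, sol, pr)
  m2 <- m
  m2[1, 1] <- m2[1, 1] + 10
  expect_error(delta_move_gene(cache, m2, "g1", 1, 1), "stale")
  # merging two blocks with identical statistics: closed-form difference
  a <- block_stats(unclass(m)[1, ])
  merged <- list(n = 2 * a$n, s1 = 2 * a$s1, s2 = 2 * a$s2)
  direct <- block_logml(merged, pr) - 2 * block_logml(a, pr)
  brute <- block_logml(block_stats(rep(unclass(m)[1, ], 2)), pr) -
    2 * block_logml(block_stats(unclass(m)[1, ]), pr)
  expect_equal(direct, brute, tolerance = 1e-12)
})
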