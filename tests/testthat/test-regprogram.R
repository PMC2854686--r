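two_group_matrix <- function(n_genes = 6, seed = 3, sep = 3, noise = 0.1,
                             n_samples = 16) {
  set.seed(seed)
  grp <- rep(c(-sep, sep), each = n_samples / 2)
  vals <- t(vapply(seq_len(n_genes), function(i) grp + rnorm(n_samples, 0, noise),
                   numeric(n_samples)))
  dimnames(vals) <- list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples)))
  expr_matrix(vals)
}

test_that("well-separated condition groups yield single-node trees split on the groups", {
  m <- two_group_matrix()
  lo <- colnames(m)[1:8]
  hi <- colnames(m)[9:16]
  n_good <- 0
  n_total <- 0
  for (s in 1:20) {
    trees <- build_condition_trees(m, rownames(m), n_trees = 5,
                                   base_seed = 100 * s)
    for (tr in trees) {
      n_total <- n_total + 1
      if (length(tr$nodes) == 1 &&
          setequal(tr$nodes[[1]]$left, lo) &&
          setequal(tr$nodes[[1]]$right, hi))
        n_good <- n_good + 1
    }
  }
  expect_gte(n_good / n_total, 0.95)
})

test_that("tree nodes orient left = low expression and weight = samples under the node", {
  m <- two_group_matrix(seed = 9)
  trees <- build_condition_trees(m, rownames(m), n_trees = 3, base_seed = 7)
  for (tr in trees) {
    for (nd in tr$nodes) {
      expect_lte(mean(unclass(m)[, nd$left]), mean(unclass(m)[, nd$right]))
      expect_identical(nd$weight, length(nd$left) + length(nd$right))
      expect_length(intersect(nd$left, nd$right), 0)
    }
    # the root merge covers all samples
    expect_setequal(unlist(tr$nodes[[length(tr$nodes)]][c("left", "right")]),
                    colnames(m))
  }
})

test_that("node split score matches hand-computed values", {
  x <- stats::setNames(c(-1, -1, 1, 1), c("a", "b", "c", "d"))
  res <- node_split_score(x, L = c("a", "b"), R = c("c", "d"), beta = 3)
  expect_equal(res$score, 4 * plogis(3, log.p = TRUE), tolerance = 1e-9)
  expect_equal(res$score, -0.1943494, tolerance = 1e-6)
  expect_identical(res$z, 0)
  expect_identical(res$sign, 1L)
  # constant (flagged) regulator: sigma(0) = 1/2 at every sample
  zc <- stats::setNames(rep(0, 4), c("a", "b", "c", "d"))
  resc <- node_split_score(zc, L = c("a", "b"), R = c("c", "d"), beta = 3)
  expect_equal(resc$score, 4 * log(0.5), tolerance = 1e-9)
  expect_error(node_split_score(x, character(0), c("a")), "length")
  expect_error(node_split_score(x, c("a"), c("a")), "disjoint")
})

test_that("negating the regulator flips the sign and preserves score and |z|", {
  set.seed(8)
  for (i in 1:10) {
    x <- stats::setNames(as.numeric(standardize_row(rnorm(12))),
                         sprintf("s%d", 1:12))
    L <- names(x)[1:5]
    R <- names(x)[6:12]
    a <- node_split_score(x, L, R, beta = 2)
    b <- node_split_score(-x, L, R, beta = 2)
    expect_equal(b$score, a$score, tolerance = 1e-12)
    expect_identical(b$sign, -a$sign)
    expect_equal(abs(b$z), abs(a$z), tolerance = 1e-12)
    # swapping the node sides does the same
    d <- node_split_score(x, R, L, beta = 2)
    expect_equal(d$score, a$score, tolerance = 1e-12)
    expect_identical(d$sign, -a$sign)
  }
})

test_that("scores are bit-identical under positive affine transforms of the raw row", {
  set.seed(12)
  raw <- rnorm(20, mean = 7, sd = 3)
  names(raw) <- sprintf("s%d", 1:20)
  L <- names(raw)[1:9]
  R <- names(raw)[10:20]
  base <- node_split_score(standardize_row(raw), L, R)
  for (ab in list(c(2, 0), c(0.5, 0), c(1.7, 0.3), c(25, -4))) {
    tr <- node_split_score(standardize_row(ab[1] * raw + ab[2]), L, R)
    expect_identical(tr, base)
  }
})

test_that("node assignment ranks by score with lexicographic tie-breaks and caps at K", {
  m <- two_group_matrix(seed = 5)
  set.seed(2)
  reg <- rbind(r_good = c(rep(-1, 8), rep(1, 8)) + rnorm(16, 0, 0.05),
               b_twin = 0, a_twin = 0, r_noise = rnorm(16))
  reg["b_twin", ] <- reg["r_good", ] + 100  # same standardized profile
  reg["a_twin", ] <- 2 * reg["r_good", ]
  colnames(reg) <- colnames(m)
  big <- expr_matrix(rbind(unclass(m), reg))
  Z <- standardize_candidates(big, rownames(reg))
  node <- list(left = colnames(m)[1:8], right = colnames(m)[9:16],
               weight = 16L)
  top <- assign_regulators_to_node(node, Z, K = 100)
  expect_identical(nrow(top), 4L)  # K larger than candidate count
  # identical profiles tie and order lexicographically, ahead of noise
  expect_identical(top$regulator[1:3], c("a_twin", "b_twin", "r_good"))
  expect_identical(top$score[1], top$score[2])
  top2 <- assign_regulators_to_node(node, Z, K = 2)
  expect_identical(top2$regulator, c("a_twin", "b_twin"))
})

test_that("global scores center against peers and floor at zero", {
  asg <- tibble::tibble(
    regulator = c("r1", "r2", "r1"),
    score = c(-0.1, -0.9, -0.2), sign = c(1L, 1L, -1L),
    w = c(0.5, 0.5, 0.25), sbar = c(-0.5, -0.5, -0.2))
  gs <- global_scores(asg, all_regulators = c("r1", "r2", "r3"))
  # r1: 0.5*0.4 + 0.25*0 = 0.2 ; r2 floored at 0 ; r3 never assigned
  expect_equal(gs$global_score[gs$regulator == "r1"], 0.2)
  expect_equal(gs$global_score[gs$regulator == "r2"], 0)
  expect_equal(gs$global_score[gs$regulator == "r3"], 0)
  expect_identical(gs$n_nodes_assigned[gs$regulator == "r3"], 0L)
  # sign: r1 weighted majority positive
  expect_identical(gs$sign[gs$regulator == "r1"], 1L)
  # single candidate at a single node scores 0 by centering
  one <- tibble::tibble(regulator = "r1", score = -0.3, sign = 1L,
                        w = 1, sbar = -0.3)
  expect_equal(global_scores(one, "r1")$global_score, 0)
})

test_that("a planted direct regulator outranks iid decoys at tree nodes", {
  hits <- vapply(1:10, function(s) {
    d <- generate_dataset(synthetic_config(
      seed = 700 + s, n_modules = 1, n_background = 0,
      n_indirect_regulators_per_module = 0,
      n_direct_regulators_per_module = 1))
    genes <- d$truth$module_members$gene
    fit <- score_regulators(d$matrix, list(genes), d$candidates,
                            n_trees = 5, seed = s)
    planted <- d$truth$regulators$regulator[d$truth$regulators$mode == "direct"]
    fit$scores$regulator[1] %in% planted
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
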