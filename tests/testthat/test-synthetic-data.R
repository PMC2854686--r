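test_that("generation is bit-reproducible from the seed and validates configs", {
  cfg <- synthetic_config(seed = 21)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(unclass(d1$matrix), unclass(d2$matrix))
  expect_identical(d1$candidates, d2$candidates)
  expect_identical(d1$truth$regulators, d2$truth$regulators)
  expect_error(synthetic_config(n_samples = 0), "samples")
  expect_error(synthetic_config(n_modules = -1), "counts")
  expect_error(synthetic_config(cond_clusters_per_module = c(3, 99)),
               "infeasible")
  expect_error(synthetic_config(cluster_mean_sd = 0.1, gene_noise_sd = 0.3),
               "strong preset")
})

test_that("zero gene noise makes module rows identical to the condition-mean profile", {
  d <- generate_dataset(synthetic_config(gene_noise_sd = 0, seed = 4))
  mm <- d$truth$module_members
  for (k in unique(mm$module)) {
    rows <- unclass(d$matrix)[mm$gene[mm$module == k], ]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
})

test_that("planted structure matches the emitted matrix and candidate set", {
  d <- generate_dataset(synthetic_config(seed = 13))
  tr <- d$truth
  # all candidates are matrix rows; hidden intermediates are rows but never candidates
  expect_true(all(d$candidates %in% rownames(d$matrix)))
  expect_true(all(tr$hidden_intermediates$hidden_id %in% rownames(d$matrix)))
  expect_false(any(tr$hidden_intermediates$hidden_id %in% d$candidates))
  # module gene sets disjoint; one hidden intermediate per indirect regulator
  expect_false(any(duplicated(tr$module_members$gene)))
  ind <- tr$regulators$regulator[tr$regulators$mode == "indirect"]
  expect_setequal(tr$hidden_intermediates$regulator, ind)
  expect_false(any(duplicated(tr$hidden_intermediates$regulator)))
  # miRNA rows carry the mirna kind label
  kinds <- row_kind(d$matrix)
  expect_true(all(kinds[grep("^mir_", names(kinds))] == "mirna"))
})

test_that("direct regulators track their module mean tightly in the strong regime", {
  ok <- vapply(1:50, function(s) {
    d <- generate_dataset(synthetic_config(seed = 400 + s,
                                           n_background = 0,
                                           n_decoy_regulators = 0))
    tr <- d$truth
    prof <- lapply(split(tr$condition_assignment, tr$condition_assignment$module),
                   function(a) tr$cluster_means$mean[tr$cluster_means$module ==
                       a$module[1]][a$cluster])
    dirs <- tr$regulators[tr$regulators$mode == "direct", ]
    r <- vapply(seq_len(nrow(dirs)), function(i) {
      x <- as.numeric(standardize_row(unclass(d$matrix)[dirs$regulator[i], ]))
      abs(cor(x, prof[[dirs$module[i]]]))
    }, numeric(1))
    mean(r >= 0.9)
  }, numeric(1))
  expect_gte(mean(ok), 0.95)
})

test_that("standardized regulator rows are invariant to the miRNA scale", {
  cfg1 <- synthetic_config(seed = 31, mirna_scale = 1)
  cfg2 <- synthetic_config(seed = 31, mirna_scale = 20)
  d1 <- generate_dataset(cfg1)
  d2 <- generate_dataset(cfg2)
  for (r in d1$candidates)
    expect_identical(standardize_row(unclass(d1$matrix)[r, ]),
                     standardize_row(unclass(d2$matrix)[r, ]))
})

test_that("divergence noise decorrelates the hidden intermediate but not the indirect regulator", {
  cors <- sapply(1:10, function(s) {
    lo <- generate_dataset(synthetic_config(seed = 600 + s,
                                            indirect_divergence_sd = 0.1))
    hi <- generate_dataset(synthetic_config(seed = 600 + s,
                                            indirect_divergence_sd = 4))
    get_cors <- function(d) {
      tr <- d$truth
      h <- tr$hidden_intermediates[1, ]
      mod <- tr$regulators$module[tr$regulators$regulator == h$regulator]
      a <- tr$condition_assignment[tr$condition_assignment$module == mod, ]
      prof <- tr$cluster_means$mean[tr$cluster_means$module == mod][a$cluster]
      c(hidden = abs(cor(unclass(d$matrix)[h$hidden_id, ], prof)),
        reg = abs(cor(unclass(d$matrix)[h$regulator, ], prof)))
    }
    c(lo = get_cors(lo), hi = get_cors(hi))
  })
  expect_gt(mean(cors["lo.hidden", ]), mean(cors["hi.hidden", ]) + 0.2)
  expect_gt(mean(cors["hi.reg", ]), 0.85)
})

test_that("recovery metrics behave at the extremes", {
  d <- generate_dataset(synthetic_config(seed = 2))
  tr <- d$truth
  planted <- split(tr$module_members$gene, tr$module_members$module)
  perfect <- structure(unname(planted), class = "tight_cluster_set")
  rec <- recovery_metrics(tr, perfect)
  expect_equal(rec$ari, 1)
  expect_true(all(rec$module_recovery$jaccard == 1))
  # random partitions of the same sizes have ARI near 0
  aris <- vapply(1:20, function(s) {
    set.seed(900 + s)
    genes <- sample(tr$module_members$gene)
    rand <- structure(split(genes, rep(seq_along(planted), lengths(planted))),
                      class = "tight_cluster_set")
    recovery_metrics(tr, rand)$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
  # scores putting a planted regulator first everywhere give top-1 recovery 1
  regs <- tr$regulators[tr$regulators$mode != "decoy", ]
  scores <- dplyr::bind_rows(lapply(seq_along(planted), function(i)
    tibble::tibble(module = i,
                   regulator = c(regs$regulator[regs$module == i][1], "tf_decoy_001"),
                   global_score = c(10, 1))))
  rec2 <- recovery_metrics(tr, perfect, scores)
  expect_equal(rec2$top1_recovery, 1)
})
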