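#' Configuration for the synthetic module-network generator
#'
#' Defines the statistical structure the generator plants: modules of
#' tightly co-expressed genes whose per-sample mean jumps between condition
#' clusters; direct regulators whose standardized profile tracks the module
#' mean (with either sign); indirect regulators whose influence is routed
#' through a hidden intermediate whose *measured* profile is decorrelated by
#' extra noise (the situation where a transcription factor mediates a
#' miRNA's effect but its own measured profile correlates poorly with the
#' module); background genes; decoy regulators; and miRNA-kind rows measured
#' on a different absolute scale than mRNAs.
#'
#' The `"strong"` preset (the default) is the well-separated regime used for
#' recovery benchmarking: condition-cluster means with SD 2 against gene
#' noise SD 0.3, 3 modules of 20 genes across 40 samples, 2 direct and 1
#' indirect regulator per module, 50 decoys. The `"moderate"` preset halves
#' the separation (mean SD 1, noise SD 0.5).
#'
#' @param preset `"strong"` or `"moderate"`.
#' @param n_modules number of planted modules.
#' @param genes_per_module length-2 integer range (inclusive).
#' @param n_background background genes with iid N(0, 1) noise.
#' @param n_samples number of samples (columns).
#' @param cond_clusters_per_module length-2 integer range.
#' @param cluster_mean_sd SD of condition-cluster means.
#' @param gene_noise_sd SD of per-entry gene noise.
#' @param n_direct_regulators_per_module,n_indirect_regulators_per_module
#'   planted regulators per module.
#' @param indirect_divergence_sd noise SD decorrelating the hidden
#'   intermediate's measured row from its true profile.
#' @param mirna_fraction fraction of regulator/decoy rows labeled miRNA.
#' @param mirna_scale absolute-scale multiplier applied to miRNA rows.
#' @param n_decoy_regulators iid-noise decoy candidates.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(preset = c("strong", "moderate"),
                             n_modules = 3, genes_per_module = c(20, 20),
                             n_background = 20, n_samples = 40,
                             cond_clusters_per_module = c(3, 5),
                             cluster_mean_sd = NULL, gene_noise_sd = NULL,
                             n_direct_regulators_per_module = 2,
                             n_indirect_regulators_per_module = 1,
                             indirect_divergence_sd = 2,
                             mirna_fraction = 0.5, mirna_scale = 5,
                             n_decoy_regulators = 50, seed = 1) {
  preset <- match.arg(preset)
  if (is.null(cluster_mean_sd))
    cluster_mean_sd <- if (preset == "strong") 2 else 1
  if (is.null(gene_noise_sd))
    gene_noise_sd <- if (preset == "strong") 0.3 else 0.5
  cfg <- list(preset = preset, n_modules = n_modules,
              genes_per_module = genes_per_module,
              n_background = n_background, n_samples = n_samples,
              cond_clusters_per_module = cond_clusters_per_module,
              cluster_mean_sd = cluster_mean_sd,
              gene_noise_sd = gene_noise_sd,
              n_direct_regulators_per_module = n_direct_regulators_per_module,
              n_indirect_regulators_per_module = n_indirect_regulators_per_module,
              indirect_divergence_sd = indirect_divergence_sd,
              mirna_fraction = mirna_fraction, mirna_scale = mirna_scale,
              n_decoy_regulators = n_decoy_regulators, seed = seed)
  counts <- cfg[c("n_modules", "n_background", "n_samples",
                  "n_direct_regulators_per_module",
                  "n_indirect_regulators_per_module", "n_decoy_regulators")]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  if (n_samples < 2) stop("need at least 2 samples")
  if (any(genes_per_module < 1) || genes_per_module[2] < genes_per_module[1])
    stop("invalid genes_per_module range")
  if (cond_clusters_per_module[1] < 1 ||
      cond_clusters_per_module[2] > n_samples)
    stop("condition-cluster range infeasible for n_samples")
  if (mirna_scale <= 0) stop("mirna_scale must be > 0")
  if (mirna_fraction < 0 || mirna_fraction > 1)
    stop("mirna_fraction must be in [0, 1]")
  if (preset == "strong" && cluster_mean_sd <= gene_noise_sd)
    stop("strong preset requires cluster_mean_sd > gene_noise_sd")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Emits an expression matrix containing, in order: module genes (value =
#' the module's condition-cluster mean plus N(0, `gene_noise_sd`) noise),
#' background genes (iid noise), planted direct regulators (`sign` times the
#' standardized module mean profile plus noise, whole row rescaled by
#' `mirna_scale` for miRNA-kind rows), planted indirect regulators (same
#' construction but routed through a hidden intermediate whose emitted row
#' is the true profile plus N(0, `indirect_divergence_sd`) divergence
#' noise), the hidden intermediates themselves, and decoy regulators (iid
#' noise). The candidate set is all planted regulators plus decoys — never
#' the hidden intermediates. Everything is reproducible from `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `matrix` ([expr_matrix()]), `candidates` (character),
#'   and `truth` (a `ground_truth` list of tibbles: `module_members`,
#'   `condition_assignment`, `cluster_means`, `regulators`,
#'   `hidden_intermediates`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(cfg$seed))
  S <- cfg$n_samples
  samples <- sprintf("s%03d", seq_len(S))

  rows <- list(); kinds <- character(); ids <- character()
  push_row <- function(id, kind, values) {
    rows[[length(rows) + 1]] <<- values
    ids[length(ids) + 1] <<- id
    kinds[length(kinds) + 1] <<- kind
  }

  module_members <- list(); cond_assign <- list(); clu_means <- list()
  regulators <- list(); hidden <- list()
  module_profiles <- list()

  for (mi in seq_len(cfg$n_modules)) {
    K <- if (cfg$cond_clusters_per_module[1] == cfg$cond_clusters_per_module[2])
      cfg$cond_clusters_per_module[1]
    else sample(seq(cfg$cond_clusters_per_module[1],
                    cfg$cond_clusters_per_module[2]), 1)
    K <- min(K, S)
    repeat {
      assign_k <- sample.int(K, S, replace = TRUE)
      if (length(unique(assign_k)) == K) break
    }
    means <- rnorm(K, 0, cfg$cluster_mean_sd)
    profile <- means[assign_k]
    module_profiles[[mi]] <- profile
    n_genes <- if (cfg$genes_per_module[1] == cfg$genes_per_module[2])
      cfg$genes_per_module[1]
    else sample(seq(cfg$genes_per_module[1], cfg$genes_per_module[2]), 1)
    gene_ids <- sprintf("g_m%02d_%03d", mi, seq_len(n_genes))
    for (g in gene_ids)
      push_row(g, "mrna", profile + rnorm(S, 0, cfg$gene_noise_sd))
    module_members[[mi]] <- tibble::tibble(module = mi, gene = gene_ids)
    cond_assign[[mi]] <- tibble::tibble(module = mi, sample = samples,
                                        cluster = assign_k)
    clu_means[[mi]] <- tibble::tibble(module = mi, cluster = seq_len(K),
                                      mean = means)
  }

  for (b in seq_len(cfg$n_background))
    push_row(sprintf("bg_%03d", b), "mrna", rnorm(S))

  plant_regulator <- function(id_stub, mi, mode, j) {
    profile <- module_profiles[[mi]]
    z <- as.numeric(standardize_row(profile))
    sgn <- sample(c(1L, -1L), 1)
    is_mir <- runif(1) < cfg$mirna_fraction
    kind <- if (is_mir) "mirna" else "mrna"
    id <- sprintf("%s_%s_m%02d_%d", if (is_mir) "mir" else "tf", id_stub,
                  mi, j)
    core <- sgn * z + rnorm(S, 0, cfg$gene_noise_sd)
    push_row(id, kind, if (is_mir) cfg$mirna_scale * core else core)
    list(id = id, sign = sgn, kind = kind, z = z)
  }

  for (mi in seq_len(cfg$n_modules)) {
    for (j in seq_len(cfg$n_direct_regulators_per_module)) {
      r <- plant_regulator("d", mi, "direct", j)
      regulators[[length(regulators) + 1]] <- tibble::tibble(
        regulator = r$id, module = mi, mode = "direct", sign = r$sign,
        kind = r$kind)
    }
    for (j in seq_len(cfg$n_indirect_regulators_per_module)) {
      r <- plant_regulator("i", mi, "indirect", j)
      hid <- sprintf("hidden_tf_m%02d_%d", mi, j)
      push_row(hid, "mrna", r$z + rnorm(S, 0, cfg$indirect_divergence_sd))
      regulators[[length(regulators) + 1]] <- tibble::tibble(
        regulator = r$id, module = mi, mode = "indirect", sign = r$sign,
        kind = r$kind)
      hidden[[length(hidden) + 1]] <- tibble::tibble(
        regulator = r$id, hidden_id = hid)
    }
  }

  for (d in seq_len(cfg$n_decoy_regulators)) {
    is_mir <- runif(1) < cfg$mirna_fraction
    kind <- if (is_mir) "mirna" else "mrna"
    id <- sprintf("%s_decoy_%03d", if (is_mir) "mir" else "tf", d)
    core <- rnorm(S)
    push_row(id, kind, if (is_mir) cfg$mirna_scale * core else core)
    regulators[[length(regulators) + 1]] <- tibble::tibble(
      regulator = id, module = NA_integer_, mode = "decoy", sign = NA_integer_,
      kind = kind)
  }

  vals <- do.call(rbind, rows)
  dimnames(vals) <- list(ids, samples)
  m <- expr_matrix(vals, row_kind = kinds)
  reg_tbl <- dplyr::bind_rows(
    tibble::tibble(regulator = character(), module = integer(),
                   mode = character(), sign = integer(), kind = character()),
    regulators)
  truth <- structure(list(
    module_members = dplyr::bind_rows(
      tibble::tibble(module = integer(), gene = character()), module_members),
    condition_assignment = dplyr::bind_rows(cond_assign),
    cluster_means = dplyr::bind_rows(clu_means),
    regulators = reg_tbl,
    hidden_intermediates = dplyr::bind_rows(
      tibble::tibble(regulator = character(), hidden_id = character()),
      hidden),
    config = cfg), class = "ground_truth")
  list(matrix = m, candidates = sort(reg_tbl$regulator), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d modules, %d planted regulators (%d decoys)\n",
              max(c(0, x$module_members$module)),
              sum(x$regulators$mode != "decoy"),
              sum(x$regulators$mode == "decoy")))
  invisible(x)
}

#' Recovery metrics against planted ground truth
#'
#' Compares inferred tight clusters and regulator rankings to the planted
#' structure: (i) best-match Jaccard index per planted module and the
#' adjusted Rand index of the gene partition over planted module genes
#' (genes left unclustered count as singletons); (ii) the fraction of
#' planted modules whose matched cluster's top-ranked regulator is one of
#' that module's planted regulators; (iii) the rank of every planted
#' regulator within its matched cluster's score table.
#'
#' @param truth a `ground_truth` from [generate_dataset()].
#' @param modules a `tight_cluster_set` (or list of gene-ID vectors).
#' @param scores optional regulator score table (tibble with `module`
#'   indexing `modules`, `regulator`, `global_score`).
#' @return A `recovery_report`: list with `ari`, `module_recovery` (tibble:
#'   `module`, `jaccard`, `matched_cluster`, `top_regulator`, `top1_hit`),
#'   `top1_recovery`, `regulator_ranks` (tibble).
#' @export
recovery_metrics <- function(truth, modules, scores = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  planted <- split(truth$module_members$gene, truth$module_members$module)

  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  module_rows <- purrr::imap(planted, function(genes, mod_name) {
    js <- if (length(modules))
      vapply(modules, jaccard, numeric(1), a = genes) else numeric(0)
    best <- if (length(js) && max(js) > 0) which.max(js) else NA_integer_
    tibble::tibble(module = as.integer(mod_name),
                   jaccard = if (length(js)) max(js, 0) else 0,
                   matched_cluster = best)
  })
  module_recovery <- dplyr::bind_rows(module_rows)

  # ARI over planted genes; unclustered genes become singletons
  genes_all <- truth$module_members$gene
  true_lab <- truth$module_members$module
  pred_lab <- rep(NA_integer_, length(genes_all))
  for (ci in seq_along(modules))
    pred_lab[genes_all %in% modules[[ci]]] <- ci
  n_miss <- sum(is.na(pred_lab))
  if (n_miss)
    pred_lab[is.na(pred_lab)] <- length(modules) + seq_len(n_miss)
  ari <- mclust::adjustedRandIndex(true_lab, pred_lab)

  top1 <- NA_real_
  reg_ranks <- tibble::tibble()
  if (!is.null(scores)) {
    planted_regs <- dplyr::filter(truth$regulators, .data$mode != "decoy")
    hits <- logical(0)
    rank_rows <- list()
    for (i in seq_len(nrow(module_recovery))) {
      mc <- module_recovery$matched_cluster[i]
      mod_id <- module_recovery$module[i]
      regs_m <- planted_regs$regulator[planted_regs$module == mod_id]
      if (is.na(mc)) {
        hits <- c(hits, FALSE)
        next
      }
      tab <- scores |>
        dplyr::filter(.data$module == mc) |>
        dplyr::arrange(dplyr::desc(.data$global_score), .data$regulator) |>
        dplyr::mutate(rank = dplyr::row_number())
      hits <- c(hits, nrow(tab) > 0 && tab$regulator[1] %in% regs_m)
      rank_rows[[length(rank_rows) + 1]] <- tab |>
        dplyr::filter(.data$regulator %in% regs_m) |>
        dplyr::transmute(module = mod_id, regulator = .data$regulator,
                         rank = .data$rank,
                         global_score = .data$global_score)
    }
    module_recovery$top1_hit <- hits
    module_recovery$top_regulator <- vapply(seq_len(nrow(module_recovery)),
      function(i) {
        mc <- module_recovery$matched_cluster[i]
        if (is.na(mc)) return(NA_character_)
        tab <- scores[scores$module == mc, ]
        tab$regulator[which.max(tab$global_score)]
      }, character(1))
    top1 <- mean(hits)
    reg_ranks <- dplyr::bind_rows(rank_rows)
  }
  structure(list(ari = ari, module_recovery = module_recovery,
                 top1_recovery = top1, regulator_ranks = reg_ranks),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> ARI %.3f; median Jaccard %.3f%s\n", x$ari,
              stats::median(x$module_recovery$jaccard),
              if (!is.na(x$top1_recovery))
                sprintf("; top-1 regulator recovery %.2f", x$top1_recovery)
              else ""))
  invisible(x)
}
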