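#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted module network
#'
#' One row per (module, regulator) interaction, ordered by decreasing
#' global score within module, with the cutoff flag when calls were made.
#'
#' @param x a `module_network_fit`.
#' @param ... unused.
#' @return A tibble with `module`, `regulator`, `global_score`, `sign`,
#'   `n_nodes_assigned` and (if available) `passes_cutoff`.
#' @method tidy module_network_fit
#' @export
tidy.module_network_fit <- function(x, ...) {
  if (is.null(x$programs))
    return(tibble::tibble(module = integer(), regulator = character(),
                          global_score = numeric(), sign = integer(),
                          n_nodes_assigned = integer()))
  out <- if (!is.null(x$calls)) tibble::as_tibble(x$calls)
         else x$programs$scores
  dplyr::arrange(out, .data$module, dplyr::desc(.data$global_score),
                 .data$regulator)
}

#' Glance at a fitted module network
#'
#' @param x a `module_network_fit`.
#' @param ... unused.
#' @return One-row tibble: ensemble size, number of tight modules and
#'   clustered genes, interactions scored/called, cutoff and max-null
#'   scores.
#' @method glance module_network_fit
#' @export
glance.module_network_fit <- function(x, ...) {
  tibble::tibble(
    n_runs = length(x$solutions),
    n_modules = length(x$modules),
    n_module_genes = sum(lengths(x$modules)),
    n_interactions = if (is.null(x$programs)) 0L else nrow(x$programs$scores),
    n_called = if (is.null(x$calls)) 0L else sum(x$calls$passes_cutoff),
    cutoff_score = if (is.null(x$calls)) NA_real_
                   else attr(x$calls, "cutoff_score"),
    max_null_score = if (is.null(x$calls)) NA_real_
                     else attr(x$calls, "max_null_score"),
    quantile = x$params$quantile)
}

#' Plot true versus random regulator score distributions
#'
#' The two-color histogram comparing the global scores of true (module,
#' regulator) interactions against the random-regulator null, with the
#' cutoff score and the maximum null score marked — well-separated
#' distributions indicate that high-scoring regulators are not explainable
#' by chance assignment.
#'
#' @param object a `module_network_fit` with null scores.
#' @param bins histogram bins (default 40).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot module_network_fit
#' @export
autoplot.module_network_fit <- function(object, bins = 40, ...) {
  if (is.null(object$null)) stop("fit has no null scores to plot")
  df <- dplyr::bind_rows(
    tibble::tibble(score = object$programs$scores$global_score,
                   set = "true"),
    tibble::tibble(score = object$null$score, set = "random"))
  cutoff <- attr(object$calls, "cutoff_score")
  max_null <- attr(object$calls, "max_null_score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$set)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = 2) +
    ggplot2::geom_vline(xintercept = max_null, linetype = 3) +
    ggplot2::scale_fill_manual(values = c(true = "#E6C229",
                                          random = "#3E8E41")) +
    ggplot2::labs(x = "global regulator score", y = "count", fill = NULL,
                  title = "True vs. randomly assigned regulator scores",
                  subtitle = "dashed: cutoff score; dotted: max null score") +
    ggplot2::theme_minimal()
}

#' Plot the co-clustering frequency matrix
#'
#' Heatmap of the gene-by-gene co-clustering frequency, with genes ordered
#' by tight-cluster membership when a cluster set is supplied.
#'
#' @param C a [coclustering_matrix()].
#' @param clusters optional `tight_cluster_set` used to order genes.
#' @return A ggplot object.
#' @export
plot_cocluster <- function(C, clusters = NULL) {
  ids <- rownames(C)
  if (!is.null(clusters) && length(clusters)) {
    ord <- c(unlist(clusters), setdiff(ids, unlist(clusters)))
    C <- unclass(C)[ord, ord]
  }
  df <- tibble::as_tibble(unclass(C), rownames = "gene_i") |>
    tidyr::pivot_longer(-"gene_i", names_to = "gene_j",
                        values_to = "frequency") |>
    dplyr::mutate(gene_i = factor(.data$gene_i, levels = rownames(C)),
                  gene_j = factor(.data$gene_j, levels = rownames(C)))
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_i, .data$gene_j,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#13315C",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-clustering\nfrequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
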