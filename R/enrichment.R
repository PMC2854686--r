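#' Hypergeometric over-representation tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` members of a size-`K` gene set when sampling `n` genes (a
#' module) without replacement from a universe of `N`. Computed in log space
#' via [stats::phyper()].
#'
#' @param k observed overlap.
#' @param n module size.
#' @param K gene-set size.
#' @param N universe size.
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeom_pval(4, 5, 5, 20) # 76/15504
#' @export
hypergeom_pval <- function(k, n, K, N) {
  stopifnot(k >= 0, k <= n, n <= N, k <= K, K <= N)
  if (k == 0) return(1)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Gene-set over-representation per module
#'
#' One-sided hypergeometric test of every (module, gene set) pair with at
#' least one overlapping gene, with Benjamini-Hochberg correction applied
#' within each module (each module's enrichment list is its own family of
#' tests). Module genes absent from the universe are dropped with a
#' warning.
#'
#' @param modules a `tight_cluster_set` or named list of gene-ID vectors.
#' @param sets a [gene_set_collection()].
#' @param alpha adjusted-p threshold for the `enriched` flag (default 0.05).
#' @return Tibble with `module`, `set_name`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `p_adj`, `enriched`.
#' @export
enrich_modules <- function(modules, sets, alpha = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- sets$universe
  if (!length(universe)) stop("empty gene universe")
  N <- length(universe)
  if (is.null(names(modules)) || !any(nzchar(names(modules))))
    names(modules) <- seq_along(modules)
  rows <- purrr::imap(modules, function(genes, mod_name) {
    outside <- setdiff(genes, universe)
    if (length(outside))
      warning("module ", mod_name, ": ", length(outside),
              " gene(s) outside the universe dropped", call. = FALSE)
    genes <- intersect(genes, universe)
    if (!length(genes)) return(NULL)
    res <- purrr::imap(sets$sets, function(members, set_name) {
      k <- length(intersect(genes, members))
      if (k < 1) return(NULL)
      tibble::tibble(module = mod_name, set_name = set_name, k = k,
                     n = length(genes), K = length(members), N = N,
                     p_raw = hypergeom_pval(k, length(genes),
                                            length(members), N))
    })
    out <- dplyr::bind_rows(res)
    if (!nrow(out)) return(NULL)
    dplyr::mutate(out, p_adj = p.adjust(.data$p_raw, method = "BH"))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    return(tibble::tibble(module = character(), set_name = character(),
                          k = integer(), n = integer(), K = integer(),
                          N = integer(), p_raw = numeric(), p_adj = numeric(),
                          enriched = logical()))
  out |>
    dplyr::mutate(enriched = .data$p_adj < alpha) |>
    dplyr::arrange(.data$module, .data$p_adj, .data$set_name)
}
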