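# Independent oracles and small fixture builders shared across test files.

# 2-D numerical integration of the normal-gamma evidence:
# log integral over (mu, tau) of prod N(x_i | mu, 1/tau) * NG(mu, tau | prior)
logml_integration_oracle <- function(x, pr) {
  inner <- function(tau) {
    vapply(tau, function(tt) {
      g <- integrate(function(mu) vapply(mu, function(m)
        prod(dnorm(x, m, 1 / sqrt(tt))) *
          dnorm(m, pr$mu0, 1 / sqrt(pr$lambda0 * tt)), numeric(1)),
        -Inf, Inf, rel.tol = 1e-11)$value
      g * dgamma(tt, pr$alpha0, rate = pr$beta0)
    }, numeric(1))
  }
  log(integrate(inner, 0, Inf, rel.tol = 1e-10)$value)
}

# brute-force partition score: pool every block from scratch
partition_logml_bruteforce <- function(m, ga, ca, pr) {
  total <- 0
  for (ci in sort(unique(ga))) {
    genes <- names(ga)[ga == ci]
    cond <- ca[[ci]]
    for (k in unique(cond)) {
      v <- as.numeric(unclass(m)[genes, names(cond)[cond == k]])
      total <- total + block_logml(block_stats(v), pr)
    }
  }
  total
}

# hand-rolled BH step-up, independent of stats::p.adjust
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# small named expression matrix fixture
toy_matrix <- function(n_genes = 4, n_samples = 4, seed = 1, kind = NULL) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                 sprintf("s%d", seq_len(n_samples))))
  expr_matrix(vals, row_kind = kind)
}

# a trivial one-cluster / one-condition-cluster solution over a matrix
flat_solution <- function(m) {
  list(gene_assignment = stats::setNames(rep(1L, nrow(m)), rownames(m)),
       condition_assignment = list(
         stats::setNames(rep(1L, ncol(m)), colnames(m))))
}

cocluster_from <- function(F_) {
  structure(F_, class = c("cocluster_matrix", "matrix", "array"))
}
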