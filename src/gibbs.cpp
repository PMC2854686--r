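#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Normal-gamma machinery shared by the sampler and the R-level scores.

struct Prior {
  double mu0, lambda0, alpha0, beta0;
};

static inline double block_lgml(double n, double s1, double s2, const Prior &pr) {
  if (n <= 0.0) return 0.0;
  double m = s1 / n;
  double q = s2 - n * m * m; // within-block sum of squared deviations
  if (q < 0.0) {
    if (q < -1e-6 * std::max(1.0, std::fabs(s2)))
      stop("negative sum of squared deviations: inconsistent block statistics");
    q = 0.0;
  }
  double lam_n = pr.lambda0 + n;
  double alpha_n = pr.alpha0 + 0.5 * n;
  double beta_n = pr.beta0 + 0.5 * q +
    pr.lambda0 * n * (m - pr.mu0) * (m - pr.mu0) / (2.0 * lam_n);
  if (beta_n <= 0.0) stop("non-positive posterior rate beta_n");
  return -0.5 * n * std::log(2.0 * M_PI) + 0.5 * std::log(pr.lambda0 / lam_n) +
    std::lgamma(alpha_n) - std::lgamma(pr.alpha0) +
    pr.alpha0 * std::log(pr.beta0) - alpha_n * std::log(beta_n);
}

// [[Rcpp::export(.block_logml_cpp)]]
double block_logml_cpp(double n, double s1, double s2, double mu0,
                       double lambda0, double alpha0, double beta0) {
  Prior pr = {mu0, lambda0, alpha0, beta0};
  return block_lgml(n, s1, s2, pr);
}

// One gene cluster: member rows, a partition of all samples into condition
// clusters, and pooled sufficient statistics per condition cluster.
struct Cluster {
  std::vector<int> genes;
  std::vector<int> cond;           // per sample: condition-cluster id
  std::vector<int> csize;          // samples per condition cluster
  std::vector<double> bn, bs1, bs2;

  int ncond() const { return (int)csize.size(); }

  double logml(const Prior &pr) const {
    double t = 0.0;
    for (int k = 0; k < ncond(); ++k) t += block_lgml(bn[k], bs1[k], bs2[k], pr);
    return t;
  }
};

static void add_gene(Cluster &cl, const NumericMatrix &X, int g) {
  int S = X.ncol();
  for (int s = 0; s < S; ++s) {
    int k = cl.cond[s];
    double x = X(g, s);
    cl.bn[k] += 1.0; cl.bs1[k] += x; cl.bs2[k] += x * x;
  }
  cl.genes.push_back(g);
}

static void remove_gene(Cluster &cl, const NumericMatrix &X, int g) {
  int S = X.ncol();
  for (int s = 0; s < S; ++s) {
    int k = cl.cond[s];
    double x = X(g, s);
    cl.bn[k] -= 1.0; cl.bs1[k] -= x; cl.bs2[k] -= x * x;
  }
  cl.genes.erase(std::find(cl.genes.begin(), cl.genes.end(), g));
}

// log-marginal gain of adding gene g to cluster cl
static double gene_add_delta(const Cluster &cl, const NumericMatrix &X, int g,
                             const Prior &pr) {
  int S = X.ncol(), K = cl.ncond();
  std::vector<double> gn(K, 0.0), gs1(K, 0.0), gs2(K, 0.0);
  for (int s = 0; s < S; ++s) {
    int k = cl.cond[s];
    double x = X(g, s);
    gn[k] += 1.0; gs1[k] += x; gs2[k] += x * x;
  }
  double d = 0.0;
  for (int k = 0; k < K; ++k) {
    if (gn[k] == 0.0) continue;
    d += block_lgml(cl.bn[k] + gn[k], cl.bs1[k] + gs1[k], cl.bs2[k] + gs2[k], pr) -
         block_lgml(cl.bn[k], cl.bs1[k], cl.bs2[k], pr);
  }
  return d;
}

static Cluster singleton_cluster(const NumericMatrix &X, int g) {
  int S = X.ncol();
  Cluster cl;
  cl.cond.assign(S, 0);
  cl.csize.assign(1, S);
  cl.bn.assign(1, 0.0); cl.bs1.assign(1, 0.0); cl.bs2.assign(1, 0.0);
  add_gene(cl, X, g);
  return cl;
}

// Fisher-Yates with R's RNG so set.seed() governs everything
static void shuffle_r(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

static int sample_logweights(const std::vector<double> &lw) {
  double mx = *std::max_element(lw.begin(), lw.end());
  double tot = 0.0;
  std::vector<double> w(lw.size());
  for (size_t i = 0; i < lw.size(); ++i) { w[i] = std::exp(lw[i] - mx); tot += w[i]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t i = 0; i < lw.size(); ++i) {
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return (int)lw.size() - 1;
}

// remove empty condition cluster k from cl, renumbering
static void drop_cond_cluster(Cluster &cl, int k) {
  int K = cl.ncond();
  for (size_t s = 0; s < cl.cond.size(); ++s)
    if (cl.cond[s] > k) cl.cond[s] -= 1;
  cl.csize.erase(cl.csize.begin() + k);
  cl.bn.erase(cl.bn.begin() + k);
  cl.bs1.erase(cl.bs1.begin() + k);
  cl.bs2.erase(cl.bs2.begin() + k);
  (void)K;
}

// Two-way Gibbs sampler. Alternates full sweeps of gene reassignment
// (existing clusters + one empty, CRP-weighted) and per-cluster condition
// reassignment, tracking the best partition log-marginal seen.
// [[Rcpp::export(.gibbs_two_way_cpp)]]
List gibbs_two_way_cpp(NumericMatrix X, double mu0, double lambda0,
                       double alpha0, double beta0, int n_sweeps,
                       double gamma_gene, double gamma_cond,
                       bool sample_genes, bool sample_conds,
                       bool record_trace) {
  Prior pr = {mu0, lambda0, alpha0, beta0};
  int G = X.nrow(), S = X.ncol();
  if (n_sweeps < 1) stop("n_sweeps must be >= 1");

  std::vector<Cluster> clusters;
  std::vector<int> assign(G); // gene -> index into clusters
  if (sample_genes) {
    for (int g = 0; g < G; ++g) {
      clusters.push_back(singleton_cluster(X, g));
      assign[g] = g;
    }
  } else {
    Cluster cl;
    cl.cond.assign(S, 0);
    cl.csize.assign(1, S);
    cl.bn.assign(1, 0.0); cl.bs1.assign(1, 0.0); cl.bs2.assign(1, 0.0);
    clusters.push_back(cl);
    for (int g = 0; g < G; ++g) { add_gene(clusters[0], X, g); assign[g] = 0; }
  }

  double best_logml = R_NegInf;
  std::vector<int> best_assign;
  std::vector<std::vector<int> > best_cond;
  IntegerMatrix trace;
  if (record_trace) trace = IntegerMatrix(n_sweeps, G);
  NumericVector logml_trace(n_sweeps);

  std::vector<int> gene_order(G), samp_order(S);
  for (int g = 0; g < G; ++g) gene_order[g] = g;
  for (int s = 0; s < S; ++s) samp_order[s] = s;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    if (sample_genes) {
      shuffle_r(gene_order);
      for (int gi = 0; gi < G; ++gi) {
        int g = gene_order[gi];
        int c0 = assign[g];
        remove_gene(clusters[c0], X, g);
        if (clusters[c0].genes.empty()) {
          clusters.erase(clusters.begin() + c0);
          for (int h = 0; h < G; ++h)
            if (assign[h] > c0) assign[h] -= 1;
          assign[g] = -1;
        }
        int K = (int)clusters.size();
        std::vector<double> lw(K + 1);
        for (int c = 0; c < K; ++c)
          lw[c] = std::log((double)clusters[c].genes.size()) +
                  gene_add_delta(clusters[c], X, g, pr);
        // new cluster: trivial (single) condition partition
        double s1 = 0.0, s2 = 0.0;
        for (int s = 0; s < S; ++s) { double x = X(g, s); s1 += x; s2 += x * x; }
        lw[K] = std::log(gamma_gene) + block_lgml((double)S, s1, s2, pr);
        int pick = sample_logweights(lw);
        if (pick == K) {
          clusters.push_back(singleton_cluster(X, g));
          assign[g] = K;
        } else {
          add_gene(clusters[pick], X, g);
          assign[g] = pick;
        }
      }
    }

    if (sample_conds) {
      for (size_t c = 0; c < clusters.size(); ++c) {
        Cluster &cl = clusters[c];
        int ng = (int)cl.genes.size();
        // per-sample pooled contribution of this cluster's genes
        std::vector<double> colsum(S, 0.0), colsq(S, 0.0);
        for (int j = 0; j < ng; ++j) {
          int g = cl.genes[j];
          for (int s = 0; s < S; ++s) {
            double x = X(g, s);
            colsum[s] += x; colsq[s] += x * x;
          }
        }
        shuffle_r(samp_order);
        for (int si = 0; si < S; ++si) {
          int s = samp_order[si];
          int k0 = cl.cond[s];
          cl.bn[k0] -= ng; cl.bs1[k0] -= colsum[s]; cl.bs2[k0] -= colsq[s];
          cl.csize[k0] -= 1;
          cl.cond[s] = -1;
          if (cl.csize[k0] == 0) drop_cond_cluster(cl, k0);
          int K = cl.ncond();
          std::vector<double> lw(K + 1);
          for (int k = 0; k < K; ++k)
            lw[k] = std::log((double)cl.csize[k]) +
              block_lgml(cl.bn[k] + ng, cl.bs1[k] + colsum[s], cl.bs2[k] + colsq[s], pr) -
              block_lgml(cl.bn[k], cl.bs1[k], cl.bs2[k], pr);
          lw[K] = std::log(gamma_cond) + block_lgml((double)ng, colsum[s], colsq[s], pr);
          int pick = sample_logweights(lw);
          if (pick == K) {
            cl.csize.push_back(0);
            cl.bn.push_back(0.0); cl.bs1.push_back(0.0); cl.bs2.push_back(0.0);
          }
          cl.cond[s] = pick;
          cl.csize[pick] += 1;
          cl.bn[pick] += ng; cl.bs1[pick] += colsum[s]; cl.bs2[pick] += colsq[s];
        }
      }
    }

    double lm = 0.0;
    for (size_t c = 0; c < clusters.size(); ++c) lm += clusters[c].logml(pr);
    logml_trace[sweep] = lm;
    if (lm > best_logml) {
      best_logml = lm;
      best_assign = assign;
      best_cond.clear();
      for (size_t c = 0; c < clusters.size(); ++c) best_cond.push_back(clusters[c].cond);
    }
    if (record_trace) {
      // canonical labels by first occurrence so traces are comparable
      std::vector<int> relab((int)clusters.size(), -1);
      int nxt = 0;
      for (int g = 0; g < G; ++g) {
        if (relab[assign[g]] < 0) relab[assign[g]] = nxt++;
        trace(sweep, g) = relab[assign[g]] + 1;
      }
    }
  }

  // 1-based, first-occurrence-ordered labels for the best state
  int Kb = (int)best_cond.size();
  std::vector<int> relab(Kb, -1);
  int nxt = 0;
  IntegerVector gene_assign(G);
  for (int g = 0; g < G; ++g) {
    if (relab[best_assign[g]] < 0) relab[best_assign[g]] = nxt++;
    gene_assign[g] = relab[best_assign[g]] + 1;
  }
  List cond_out(Kb);
  for (int c = 0; c < Kb; ++c) {
    for (int cc = 0; cc < Kb; ++cc) {
      if (relab[cc] == c) {
        IntegerVector v(S);
        for (int s = 0; s < S; ++s) v[s] = best_cond[cc][s] + 1;
        cond_out[c] = v;
        break;
      }
    }
  }

  // final-state condition partition of the (single) cluster, for tree draws
  IntegerVector final_cond(S);
  for (int s = 0; s < S; ++s) final_cond[s] = clusters[assign[0]].cond[s] + 1;

  List out = List::create(
    _["gene_assignment"] = gene_assign,
    _["condition_assignment"] = cond_out,
    _["logml"] = best_logml,
    _["logml_trace"] = logml_trace,
    _["final_cond"] = final_cond);
  if (record_trace) out["trace"] = trace;
  return out;
}

static inline double log_sigmoid(double t) {
  if (t >= 0.0) return -std::log1p(std::exp(-t));
  return t - std::log1p(std::exp(t));
}

// Fuzzy split score for one standardized regulator profile at one tree node.
// score(+) = max_z sum_L log sig(beta (z - x)) + sum_R log sig(beta (x - z));
// z searched over {min-1} U data values U midpoints U {max+1}.
static void score_one(const double *x, const std::vector<int> &L,
                      const std::vector<int> &R, double beta,
                      double &score, double &zbest, int &sign) {
  std::vector<double> vals;
  vals.reserve(L.size() + R.size());
  for (size_t i = 0; i < L.size(); ++i) vals.push_back(x[L[i]]);
  for (size_t i = 0; i < R.size(); ++i) vals.push_back(x[R[i]]);
  std::sort(vals.begin(), vals.end());
  vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
  std::vector<double> grid;
  grid.push_back(vals.front() - 1.0);
  for (size_t i = 0; i < vals.size(); ++i) {
    grid.push_back(vals[i]);
    if (i + 1 < vals.size()) grid.push_back(0.5 * (vals[i] + vals[i + 1]));
  }
  grid.push_back(vals.back() + 1.0);

  score = R_NegInf; zbest = 0.0; sign = 1;
  for (size_t zi = 0; zi < grid.size(); ++zi) {
    double z = grid[zi], sp = 0.0, sm = 0.0;
    for (size_t i = 0; i < L.size(); ++i) {
      double xi = x[L[i]];
      sp += log_sigmoid(beta * (z - xi));
      sm += log_sigmoid(beta * (xi - z));
    }
    for (size_t i = 0; i < R.size(); ++i) {
      double xi = x[R[i]];
      sp += log_sigmoid(beta * (xi - z));
      sm += log_sigmoid(beta * (z - xi));
    }
    if (sp > score) { score = sp; zbest = z; sign = 1; }
    if (sm > score) { score = sm; zbest = z; sign = -1; }
  }
}

// [[Rcpp::export(.node_score_batch_cpp)]]
List node_score_batch_cpp(NumericMatrix Z, IntegerVector Lidx,
                          IntegerVector Ridx, double beta) {
  int n = Z.nrow(), S = Z.ncol();
  std::vector<int> L(Lidx.begin(), Lidx.end()), R(Ridx.begin(), Ridx.end());
  for (size_t i = 0; i < L.size(); ++i) L[i] -= 1;
  for (size_t i = 0; i < R.size(); ++i) R[i] -= 1;
  NumericVector score(n), zv(n);
  IntegerVector sg(n);
  std::vector<double> row(S);
  for (int r = 0; r < n; ++r) {
    for (int s = 0; s < S; ++s) row[s] = Z(r, s);
    double sc, zb; int sn;
    score_one(row.data(), L, R, beta, sc, zb, sn);
    score[r] = sc; zv[r] = zb; sg[r] = sn;
  }
  return List::create(_["score"] = score, _["z"] = zv, _["sign"] = sg);
}
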