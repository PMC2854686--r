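---
title: "Inferring miRNA–mRNA module networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring miRNA-mRNA module networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mirmodnet infers *module networks* from expression matrices in which
messenger RNAs and microRNAs are measured side by side: modules of tightly
co-expressed genes, each governed by a regulatory program — a ranked list of
candidate regulators (transcription factors, signal transducers, miRNAs)
whose expression predicts the module's condition-dependent behaviour. This
vignette explains the statistical model, the algorithmic choices, and what
the synthetic benchmark does and does not demonstrate.

## The block model and its evidence

The core modelling assumption is that expression decomposes into
approximately homogeneous blocks: a cluster of co-expressed genes, observed
over a cluster of conditions, shares one mean and one precision. Each block
is scored by its normal–gamma marginal likelihood. With block sufficient
statistics $(n, s_1, s_2)$, $m = s_1/n$, and prior
$(\mu_0, \lambda_0, \alpha_0, \beta_0)$:

$$\lambda_n = \lambda_0 + n,\qquad \alpha_n = \alpha_0 + n/2,\qquad
\beta_n = \beta_0 + \tfrac12\!\left(s_2 - n m^2\right) +
\frac{\lambda_0\, n\, (m-\mu_0)^2}{2\lambda_n}$$

$$\log p(x) = -\tfrac{n}{2}\log 2\pi + \tfrac12\log\frac{\lambda_0}{\lambda_n}
+ \log\Gamma(\alpha_n) - \log\Gamma(\alpha_0)
+ \alpha_0\log\beta_0 - \alpha_n\log\beta_n$$

A two-way partition (genes into clusters; per gene cluster, samples into
condition clusters) is scored by the sum of block evidences
(`partition_logml()`). The default prior is weakly informative and
scale-adapted: $\mu_0$ at the grand mean, $\lambda_0 = \alpha_0 = 0.1$, and
$\beta_0$ at one tenth of the grand variance. The data are assumed
log-scale and roughly continuous; heavy-tailed alternatives are out of
scope. The closed form is verified in the test suite against 2-D numerical
integration of the evidence integral.

## Two-way Gibbs sampling and the ensemble

`sample_solution()` alternates full sweeps of gene reassignment and
per-cluster condition reassignment. The number of clusters is open-ended:
each gene (or sample) chooses among existing clusters plus one empty
cluster, with weight proportional to cluster size (concentration
$\gamma = 1$ for the empty one) times the exponentiated evidence change —
collapsed Chinese-restaurant-process Gibbs. Design choices worth stating:

* **Point estimates, not posteriors.** Solutions are used as stochastic
  point estimates: the best-evidence state visited over `n_sweeps = 100`
  sweeps is returned (MAP-over-chain), with no burn-in or thinning. The
  ensemble of independently seeded runs (30 by default) supplies the
  robustness that a single chain lacks.
* **New clusters start with a trivial condition partition.** This makes the
  joint kernel an approximation on the two-way state space (the reverse of
  deleting a cluster with a refined condition partition is not proposed).
  Because the sampler is an optimizer here, that is acceptable; the test
  suite verifies exact detailed balance in the regime where it should hold
  exactly — gene moves with condition partitions held fixed, where the
  stationary law on the two-gene state space is enumerable.
* Gene and sample orders are reshuffled every sweep from the run's RNG;
  every run is fully determined by its seed.

## Consensus and tight clusters

The ensemble is averaged into a co-clustering frequency matrix $F$
($F_{ij}$ = fraction of runs clustering $i$ with $j$). Tight clusters are
peeled off spectrally: take the dominant eigenvector $v$ of the active
submatrix (negatives zeroed; Perron–Frobenius makes the dominant
eigenvector of a nonnegative matrix nonnegative up to sign), form the
candidate $\{i : v_i \ge 0.7\,\max v\}$, accept it if its mean pairwise
frequency is at least 0.5 and it has at least `min_size = 3` genes (the
smallest module worth reporting), zero its rows and columns, and repeat.

One refinement proved necessary: when two similarly sized, internally
cohesive clusters are *weakly* coupled (a between-cluster frequency of,
say, 0.15 from runs that occasionally merge them), the dominant eigenvector
is nearly constant across their union, the threshold cannot separate them,
and the union still passes the 0.5 cohesion bar. The candidate is therefore
refined by classic spectral bipartitioning: split along the sign of the
second eigenvector of the candidate's submatrix whenever that exposes two
groups of size ≥ `min_size` that are each cohesive (mean within-frequency
≥ 0.5) but weakly connected (mean between-frequency < 0.5); the more
cohesive half is kept, the remainder is recovered by a later peel. All
tie-breaks are deterministic (size, then lexicographic identifier).

## Regulatory programs and regulator scoring

For each module, `n_trees = 100` hierarchical condition trees are built:
a condition clustering of the module's samples is *drawn* by columns-only
Gibbs (final chain state, so the tree ensemble is diverse), and the
resulting condition clusters are merged agglomeratively, each step joining
the pair whose merge most increases the pooled block evidence. Every merge
is an internal node splitting low-expression (left) from high-expression
(right) samples.

At each node every candidate regulator is scored on its **standardized**
profile $x$ through a fuzzy split score with logistic sharpness
$\beta = 2$:

$$s(x) = \max_z \sum_{c \in L} \log\sigma\!\big(\beta(z - x_c)\big)
 + \sum_{c \in R} \log\sigma\!\big(\beta(x_c - z)\big)$$

maximized over both orientations (the better one defines the regulator's
sign) and over a deterministic grid of candidate split points $z$ (observed
values, midpoints of consecutive sorted unique values, and one point beyond
each extreme — no continuous optimizer, so results are exactly
reproducible). Scores are always ≤ 0; a constant regulator scores
$(|L|+|R|)\log\tfrac12$, the uninformative floor. $\beta$ is fixed, not
fitted: a shared sharpness keeps scores comparable across regulators.

The top `top_k = 100` regulators are retained per node (ties broken
lexicographically), and the ensemble **global score** of regulator $r$ sums
its strength above peers over all nodes of all trees where it was retained:

$$G(r) = \Big\lfloor \sum_{\text{nodes}} w_{\text{node}}
  \big(s_{r} - \bar s_{\text{node}}\big) \Big\rfloor_{0}$$

with $w_{\text{node}}$ the fraction of samples under the node and
$\bar s_{\text{node}}$ the mean score of the node's retained list. Weighting
by sample fraction makes deep, data-poor splits count less; centering by
the peer mean converts raw log-likelihoods into relative strength, which is
what makes a randomly assigned regulator's expected contribution zero. The
sign of $G(r)$ is the node-weight-weighted majority of per-node signs.

Because scoring sees only the standardized profile, miRNA regulators —
typically measured on a different absolute scale than mRNAs — compete on
exactly equal footing. Standardized profiles are quantized to 9 decimal
places, which is far below any biological signal but makes the invariance
*exact*: transforming a raw regulator row by $a x + b$ ($a > 0$) leaves
every score bit-identical, a property the test suite asserts literally.

## The random-regulator null and the cutoff

Significance is judged against a null built through the *identical* scoring
path: `null_scores()` draws (candidate, node) pairs uniformly — the
candidate from the full candidate set, the node from all recorded tree
nodes — and aggregates each exactly as a single true assignment would be.
The package applies a top-quantile rule on true interaction scores
(`quantile = 0.02`, i.e. the top 2%, ties at the cutoff retained) and
reports the maximum null score alongside as the separation sanity check
rather than using it as the threshold. Whether random regulators should be
matched per node or pooled globally is not dictated by the method; uniform
sampling over all (module, node) pairs was chosen as the simplest scheme
that exercises every part of the scoring path.

## Gene-set enrichment

`enrich_modules()` is a flat, one-sided hypergeometric over-representation
test with Benjamini–Hochberg correction applied within each module (each
module's enrichment list is treated as its own family). Ontology-graph
handling (term propagation, DAG-aware corrections) is deliberately out of
scope; any GMT file can be supplied.

## What the synthetic generator emulates

`generate_dataset()` plants the structure the method is designed to find:

* modules of co-expressed genes whose per-sample mean jumps between
  condition clusters (means i.i.d. $N(0, \sigma_c^2)$, samples assigned
  uniformly);
* direct regulators: sign × the standardized module mean profile plus
  gene-level noise — positively or negatively correlated regulators are
  equally likely;
* indirect regulators routed through a *hidden intermediate*: the regulator
  tracks the module via the intermediate's true profile, but the
  intermediate's **emitted** row carries large divergence noise
  (`indirect_divergence_sd = 2`), emulating a mediating transcription
  factor whose measured profile correlates poorly with the module it
  drives — e.g. when the mediation happens post-transcriptionally. The
  intermediates are emitted as ordinary matrix rows but never offered as
  candidates;
* background genes and decoy regulators (i.i.d. noise), and miRNA-kind rows
  whose whole raw row is multiplied by `mirna_scale = 5`.

The `"strong"` preset — 3 modules × 20 genes, 40 samples, condition-mean SD
2 against gene noise SD 0.3, 2 direct + 1 indirect regulator per module, 50
decoys — is the regime where recovery should be essentially perfect, and
the recovery criteria in the test suite are stated against it. The
`"moderate"` preset (mean SD 1, noise SD 0.5) exists for exploring graceful
degradation. Where the analysis of real tumour data offers no effect sizes
to copy, these presets are calibration choices made once: the strong preset
separates condition means from gene noise by roughly 7:1, which is what
"tightly co-expressed with clearly distinct condition groups" means in a
well-powered microarray study.

The generator draws everything from one RNG stream seeded once, with a
fixed generation order (modules, background, regulators, decoys), so a
single integer reproduces the dataset bit-for-bit.

**What passing the synthetic benchmark does not show.** The generator's
noise is i.i.d. Gaussian: there are no probe effects, batch structure,
heavy tails, correlated noise across samples, or tumour-class label
structure, and planted modules are disjoint with stable membership. Perfect
recovery here demonstrates the machinery is correct and well-calibrated,
not that real-data modules at these sizes would be recovered with the same
fidelity.

## Numerical choices and degenerate inputs

* Within-block sums of squared deviations are clamped at 0 when they go
  (slightly) negative through cancellation; a violation beyond $10^{-6}$
  relative is an error, since it indicates corrupted statistics.
* Constant rows standardize to the zero vector with a `constant` flag
  instead of erroring, so degenerate regulators score as uninformative
  rather than aborting a run.
* Empty blocks have evidence 0 (the empty product); a cluster left empty by
  a move is pruned immediately.
* Single-condition-cluster draws yield trees with no nodes; such trees
  simply contribute nothing to regulator scores.
* Ties — in split scores, regulator ranks, candidate bipartitions — are all
  resolved deterministically (score, then lexicographic identifier), so
  reruns are byte-identical.
* Every stage seed is derived from one master seed through a fixed affine
  map modulo $2^{31}-1$.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at the
strong preset (142 rows × 40 samples: 60 module genes, 20 background, 9
planted regulators, 3 hidden intermediates, 50 decoys) with the published
ensemble sizes — 30 clustering runs × 100 sweeps, 100 trees per module, up
to 100 regulators per node, 1,000 null draws — replicated over 20 (tests)
or 10 (acceptance script) seeds. These sizes were chosen so the whole
benchmark is a desk-scale computation while every ensemble dimension keeps
its published value; the original tumour compendium (89 samples, ~12,000
rows) is neither packaged nor required.

## Known limitations

* The Gibbs kernel is exact for gene moves at fixed condition partitions
  but approximate jointly; it is used as a stochastic optimizer.
* Modules are hard partitions; no soft or overlapping membership.
* The regulator score is correlational: directionality and causality claims
  require external evidence, and indirect regulators are indistinguishable
  from direct ones by construction (that is precisely why the hidden
  intermediate's divergent profile matters for interpretation).
* No analytic p-values for regulator scores and no FDR across modules; the
  null comparison is empirical.
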