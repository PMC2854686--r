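# mirmodnet

Module network inference from joint mRNA and microRNA expression data.

## The problem

Microarray compendia increasingly measure messenger RNAs and microRNAs on
the same samples. A *module network* decomposes such data into **modules**
— clusters of tightly co-expressed genes — each governed by a **regulatory
program**: a ranked list of candidate regulators (transcription factors,
signal transducers, miRNAs) whose expression predicts the module's
condition-dependent mean. Because regulators are judged purely on their
*standardized* differential expression across condition clusters, miRNAs
and mRNAs — typically measured on very different absolute scales — compete
on exactly equal footing, and miRNAs can surface as top regulators of
coherent modules. The package is for computational biologists who want this
analysis as tested, scriptable R, together with a synthetic benchmark that
knows its own ground truth.

## The method

1. **Two-way Gibbs clustering.** Genes and, within each gene cluster,
   samples are co-clustered by collapsed Gibbs sampling under a
   normal–gamma block model: each (gene cluster × condition cluster) block
   shares a mean and precision, and a partition is scored by its closed-form
   marginal likelihood
   `logml = −(n/2)·ln 2π + ½·ln(λ0/λn) + lnΓ(αn) − lnΓ(α0) + α0·ln β0 − αn·ln βn`
   summed over blocks. 30 independently seeded runs (each keeping its
   best-scoring visited state) form an ensemble.
2. **Consensus tight clusters.** The ensemble is averaged into a gene×gene
   co-clustering frequency matrix; tight modules are peeled off by a
   graph-spectral method (dominant-eigenvector thresholding with
   second-eigenvector bipartition refinement).
3. **Regulatory programs.** Per module, 100 hierarchical condition trees
   are built (Gibbs condition draws + evidence-maximizing agglomeration).
   At every tree node, each candidate regulator's standardized profile x is
   scored by a fuzzy split score
   `max_z Σ_L ln σ(β(z − x_c)) + Σ_R ln σ(β(x_c − z))`,
   up to 100 regulators are kept per node, and node contributions
   (sample-weighted, centered on the node's peer mean) are summed into a
   global score per (module, regulator).
4. **Significance.** A random-regulator null is drawn through the identical
   scoring path; the top 2% of true interaction scores are called, with the
   maximum null score reported as the separation check. Modules can also be
   tested for gene-set over-representation (hypergeometric +
   Benjamini–Hochberg within module).

All results are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Generate a strong-signal synthetic dataset (3 planted modules × 20 genes,
40 samples, direct and indirect planted regulators, 50 decoys, miRNAs on a
5× absolute scale) and run the full inference:

```r
library(mirmodnet)
library(dplyr)

dat <- generate_dataset(synthetic_config(seed = 7))
fit <- fit_module_network(dat$matrix, dat$candidates, seed = 11)
fit
#> <module_network_fit> 30 runs -> 6 tight modules; 8/354 interactions pass the top-2% cutoff

tidy(fit) |> filter(passes_cutoff)
#> # A tibble: 8 × 6
#>   module regulator   global_score  sign n_nodes_assigned passes_cutoff
#>    <int> <chr>              <dbl> <int>            <int> <lgl>
#> 1      3 mir_i_m02_1        3277.     1              200 TRUE
#> 2      3 mir_d_m02_1        3258.    -1              200 TRUE
#> 3      3 tf_d_m02_2         3251.     1              200 TRUE
#> 4      4 mir_d_m03_1        3258.     1              200 TRUE
#> 5      4 mir_i_m03_1        3097.    -1              200 TRUE
#> 6      5 tf_d_m01_1         3268.    -1              200 TRUE
#> 7      5 mir_d_m01_2        3246.    -1              200 TRUE
#> 8      5 mir_i_m01_1        3229.     1              200 TRUE

recovery_metrics(dat$truth, fit$modules, fit$programs$scores)
#> <recovery_report> ARI 1.000; median Jaccard 1.000; top-1 regulator recovery 1.00
```

Reading the output: the 6 tight clusters include the 3 planted modules
(clusters 3, 4, 5; the others collect background/decoy rows that genuinely
co-cluster) and every interaction passing the top-2% cutoff is a planted
regulator of its matched module — planted direct (`*_d_*`) and indirect
(`*_i_*`) regulators, miRNA and TF alike, were assigned at all 200 tree
nodes of their module. The adjusted Rand index of 1.0 against the planted
gene partition and top-1 regulator recovery of 1.0 confirm exact recovery
in this regime. `autoplot(fit)` draws the true-versus-random score
histogram; the separation between the maximum null score (~28) and the
planted regulators' scores (~3,100+) is what makes the calls trustworthy.

`run_pipeline(config, out_dir)` runs the same analysis from a YAML/list
config and writes human-readable artifacts (matrix, modules, ranked
scores, calls, null scores, histogram data, enrichment, recovery report,
run log), byte-identically reproducible from the seed.

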