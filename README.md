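# prognet

Tumor expression cohorts yield thousands of genes whose expression is
statistically associated with patient survival, but most of those
associations are indirect — inherited from a few upstream regulators. This
package implements a network-based pipeline that separates the two: it
screens genes for prognostic relevance, estimates a causal regulatory
network among the relevant genes, scores network hubs to nominate
**master prognosis-impacting genes**, derives expression **subtypes** from
the masters, and validates those subtypes against resampling nulls and on
external cohorts. It is aimed at computational biologists working with
matched expression + survival (+ mutation) data, e.g. TCGA-style cohorts.

## The method

1. **Cox screening.** For each gene \(g\) a univariate proportional-hazards
   model \(h(t \mid x_g) = h_0(t)\,e^{\beta_g x_g}\) is fitted (partial
   likelihood, Efron ties, Wald test). Genes with \(p < 0.05\) are
   prognosis-relevant; \(\beta_g > 0\) (HR > 1) is *unfavourable*,
   \(\beta_g < 0\) *favourable*. Genes with \(p < 0.01\) and
   \(|\beta_g| > 0.2\) enter the network stage.
2. **Causal network.** Biweight midcorrelations (median-centred,
   bisquare-weighted — robust to outlying samples) are computed among the
   selected genes, and the PC algorithm (stable skeleton phase, Fisher-z
   partial-correlation tests at \(\alpha = 0.01\), v-structure orientation,
   Meek rules) estimates a CPDAG.
3. **Master genes.** Each node is scored by its *summarized degree* =
   out-degree − in-degree over directed edges. Nodes with
   \(|\text{out} - \text{in}| > 5\) are the master prognosis genes: they
   broadcast (or collect) influence across many prognosis-relevant genes.
4. **Subtypes.** Samples are consensus-clustered (PAM over 100 subsampled
   repeats, k = 2) on the z-scored master-gene matrix; cluster C1 is the
   worse-prognosis group. The subtype log-rank statistic is calibrated
   against clusterings of randomly drawn gene sets of the same size.
5. **Characterization.** Random-forest permutation importance ranks genes
   for the subtype labels; the top-50 are tested for pathway enrichment
   (hypergeometric, BH-FDR); mutations are related to subtypes (Fisher
   exact) and to expression (two-sample tests, fold changes).
6. **Predictor.** An elastic-net logistic model on the top-10 genes
   (alpha/lambda by internal CV, leave-one-out accuracy reported) transfers
   subtype labels to external cohorts, where the survival split is
   re-tested.

A synthetic-data module generates cohorts from a linear-Gaussian structural
model with planted hubs, latent subtypes, proportional-hazards survival and
subtype-enriched mutations, so every stage has a recoverable ground truth.

## Worked example

```r
library(prognet)
manifest <- run_demo("demo_out", seed = 1)
```

This simulates a 500-sample cohort (60 network genes with 8 planted hubs,
1000 background genes, 6 mutated genes), runs the full pipeline, and
self-checks against the planted truth. With seed 1 it prints stage logs and
ends with:

```
masters: 6   logrank_p: 4.31e-79   loocv: 0.992
self_check: hub_recall 0.75, subtype_ari 0.952, observed_above_null_p95 TRUE
```

Reading: the network stage recovered 6 of the 8 planted hubs as master
genes (recall 0.75); clustering patients on those masters reproduced the
planted subtypes almost exactly (adjusted Rand index 0.95); the subtype
survival split (log-rank p ≈ 4×10⁻⁷⁹ on this strongly planted effect) lies
far above the 95th percentile of the random-gene-set null; and the top-10
predictor reaches 99% leave-one-out accuracy. All artifacts (per-gene
screen table, CPDAG edge list, degree summaries, consensus matrix, null
distribution, importance ranking, predictor JSON, run manifest) are written
under `demo_out/results/`.

The same stages are available individually (`cox_screen`, `bicor_matrix`,
`pc_estimate`, `summarize_degrees`, `consensus_cluster`,
`random_gene_null`, `rank_importance`, `hypergeom_enrich`,
`fit_predictor`, `transfer_labels`) and through the CLI:

```sh
Rscript inst/cli/prognet.R demo --out-dir demo_out --seed 1
Rscript inst/cli/prognet.R screen --expr E.tsv --clin C.tsv --out screen.tsv
```

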