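---
title: "prognet: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prognet: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each stage
assumes, which tunable parameters matter, what the synthetic-data generator
does and does not emulate, and where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The pipeline and its statistical assumptions

### Cox screening

Each gene is fitted in a univariate proportional-hazards model by partial
likelihood with Efron handling of tied event times and a Wald p-value —
the standard single-covariate summary of R's `survival` machinery, which
this package uses as its backend. The screen assumes proportional hazards
per gene and treats genes independently; no multiplicity correction is
applied at this stage because the downstream network stage is itself the
filter that matters. Two thresholds are exposed:

* `screen_p` (default 0.05) — prognosis-relevance call, direction
  favourable/unfavourable by coefficient sign;
* `network_p` (0.01) and `min_abs_coef` (0.2) — the stricter cut for
  network membership. Both are strict inequalities.

The absolute-coefficient cutoff is scale-dependent; expression is used as
provided (a `standardize` flag exists), and the scale of the input matrix
(log2 by convention) is declared in the pipeline configuration.

### Biweight midcorrelation

Pairwise gene association uses the biweight midcorrelation: deviations
from the per-gene median are weighted by \((1-u^2)^2\) for
\(|u| < 1\), \(u = (x-\mathrm{med})/(9\,\mathrm{MAD})\) with the raw
(unscaled) MAD. Compared with Pearson correlation it is insensitive to a
handful of outlying samples while agreeing closely on clean Gaussian data
(the suite checks agreement within 0.06 at n = 2000). Genes with zero MAD
fall back to mean-centred unit weights (the Pearson fallback) with a
warning.

### PC algorithm

The causal network is the CPDAG estimated by the PC algorithm:

* *stable* skeleton phase (neighbourhoods frozen per level), so the
  skeleton does not depend on gene input order;
* Fisher-z tests of partial correlations computed from the supplied
  correlation matrix by inversion over the conditioning set, significance
  `pc_alpha` = 0.01 (the convention of constraint-based packages; exposed);
* v-structures oriented from recorded separation sets, with conflicting
  orientation demands resolved by leaving the edge undirected
  (conservative; an arbitrary overwrite would manufacture directionality);
* Meek rules R1–R4 applied to closure.

The bicor matrix is handed to the Gaussian test as if it were a Pearson
matrix — the robust correlation replaces the Pearson estimate wholesale
rather than changing the test. Non-positive-definite inputs are repaired
by eigenvalue clipping
at 1e-10 (warning); a non-invertible conditioning submatrix makes that
single test non-significant rather than failing the run.

The skeleton phase is implemented twice: a compiled (Rcpp/Armadillo) loop
used by default — hub nodes make subset enumeration exponential in the
neighbourhood size — and a pure-R reference path sharing all orientation
code. The suite asserts both engines produce identical CPDAGs; the d-sep
oracle suite (exhaustive DAGs up to 5 nodes plus random 8-node graphs) is
checked against an independent brute-force Markov-equivalence
construction that enumerates every orientation of the skeleton.

`max_cond_size` caps the conditioning-set order. The API default is
unbounded (classic PC); the demo configuration caps it at 3. Two reasons,
both known properties of finite-sample PC rather than tuning: (i) at
cohort sizes of a few hundred, an order-\(\ell\) partial correlation rests
on \(n-\ell-3\) effective observations and its estimate is noisy; (ii) the
skeleton phase removes an edge if *any* tested subset fails to reject, so
letting it try thousands of high-order subsets gives a true edge thousands
of chances to be deleted by noise. On the synthetic family all planted
independencies separate at order ≤ 2, and the capped and unbounded runs
return identical CPDAGs at n = 2000.

### Summarized degree and masters

Out-degree minus in-degree over *directed* edges only; undirected edges
contribute zero because any resolution adds one to both counts, leaving
the difference unchanged (the source pipeline is silent on this point —
documented design decision). Nodes with strict
`|summarized degree| > hub_threshold` (default 5) are the master genes,
returned ordered by |degree| with lexicographic tie-break.

### Consensus subtypes

Monti-style consensus clustering: `n_reps` = 100 rounds subsample 80% of
samples and cluster them by PAM (deterministic build+swap given the
dissimilarity matrix) into k = 2; consensus = co-clustering frequency
among co-sampled pairs; final labels from average-linkage hierarchical
clustering of 1 − consensus. All parameters follow the consensus-clustering
convention and are configurable; k is fixed at 2 by design (choosing k is
a non-goal). C1 is pinned to the worse-prognosis cluster via the log-rank
observed-minus-expected deaths, ties broken by smaller mean survival.

Two sample distances are available: 1 − Pearson correlation between
z-scored profiles (default: scale-free pattern matching) and Euclidean.
The correlation distance subtracts each sample's profile mean and is
therefore *mathematically blind to a subtype program that shifts all
marker genes in the same direction*; the demo world plants exactly such a
proliferation-like program and its configuration selects the Euclidean
distance for that reason. With sign-mixed marker panels the default
distance is appropriate.

### Random-gene null

The prognostic value of the subtypes is judged against repetitions of the
whole clustering on randomly drawn gene sets (without replacement, from
the zero-filtered genome-wide pool). Whether the draw size should match
the master count or the larger prognosis-relevant count is a genuinely
open choice; the pipeline draws the master count (the observed clustering
used master genes, so the null should too) and the draw size is a
parameter. The empirical p of the observed statistic is
\((1 + \#\{null \ge obs\})/(n+1)\). Inside the null each consensus run may
use fewer subsampling rounds (`null_consensus_reps`, default 30) — only
the final labels enter the log-rank statistic, and the label call
stabilizes long before the consensus matrix does; this is a documented
runtime choice.

### Importance, enrichment, mutations

Gene importance for the subtype labels comes from an in-package random
forest (CART trees, Gini splits, per-split `mtry` = √p feature sampling,
bootstrap bagging) scored by out-of-bag permutation importance — chosen
over impurity importance because it is comparable across correlated genes
(impurity available by flag). No tree package in the target environment
provides this, so the forest is implemented here and validated by
recovery, calibration and stability tests.

Enrichment of the top-50 genes is an upper-tail hypergeometric test per
pathway over the universe of zero-filtered, pathway-annotated genes, with
BH FDR. Mutation–subtype association is Fisher's exact test (sample odds
ratio with Haldane 0.5 correction when a cell is empty). Mutation–
expression association uses the unpaired two-sided t-test by default with
Wilcoxon by flag — the source material names both in different places;
t-test was chosen for the genome-wide scan as the stated method, Wilcoxon
retained because the fold-change table cites it. Fold changes are computed
on anti-logged values; the input scale (log2/ln/linear) is declared in the
configuration.

### Subtype predictor

Elastic-net logistic regression (glmnet backend) on the z-scored top-10
genes, with C1 encoded as the positive class. `alpha` ∈ {0.25, 0.5, 0.75,
1} and 50 log-spaced lambdas in [1e-4, 1] are searched by internal
cross-validated misclassification with seed-derived folds; ties prefer the
sparser model. LOOCV re-runs the entire procedure (scaling included) on
every fold. For external cohorts the default re-z-scores within the new
cohort — transferring an RNA-seq model to a microarray cohort is only
sensible after per-cohort standardization — with training-scaling mode
available. Probabilities above 0.5 are C1; exact ties go to C2.

A natural optimizer invariant (the objective decreasing monotonically over
iterations) cannot be asserted against glmnet, which exposes no iteration
trace; the suite instead verifies that the returned coefficients
are a local optimum of the penalized objective under random perturbations,
plus coefficient-path continuity in lambda.

## 2. The synthetic world

`simulate_expression` draws each gene in topological order as the weighted
sum of its parents plus \(N(0, \sigma^2)\) noise (linear-Gaussian SEM —
the model under which PC with Fisher-z tests is consistent). Master genes
receive an additive shift in C1 samples *at generation time*, so the shift
propagates to descendants, making the subtype a latent upstream cause as
in real cohorts. Survival times follow a Weibull-baseline proportional-
hazards model (shape 1 = exponential by default; no survival-generating
model is prescribed by the source, so the simplest correctly-specified one
is used) with linear predictor \(\sum_g \beta_g x_g\); censoring is
independent Uniform(0, τ) with τ calibrated so the expected censored
fraction matches `censor_rate`. Mutations are Bernoulli per SMG with a
cluster-dependent rate realizing the requested odds ratio.

The default demo world (`make_demo_truth`): 500 samples (the scale of a
typical TCGA tumor cohort), 8 hub genes each with 13
outgoing edges of weight 0.6 into 52 collider genes that draw two distinct
hub parents each, 1000 pure-noise background genes, hub Cox effects ±0.5
(five unfavourable, three favourable), children ±0.15 per parent sign,
subtype shift +2 SD on all masters, mutation odds ratio 4 at baseline rate
0.2, 30% censoring. Two structural choices deserve emphasis:

* **every non-hub is an unshielded collider** (two nonadjacent hub
  parents). A pure star has no v-structures, its CPDAG is fully
  undirected, and every summarized degree is zero — hub recovery would be
  impossible *in principle*. Colliders are what give PC orientation
  information.
* **the subtype program shifts all masters in the same direction.** The
  latent subtype correlates the hubs (ρ = e²/4 ÷ (σ² + e²/4) ≈ 0.5 at
  e = 2), which PC cannot attribute to a latent cause (that would need
  FCI, a non-goal). With a uniform program, however, every child carries a
  strong subtype loading and conditioning on two or three such proxies
  separates the spurious hub–hub edges at low order, after which the
  colliders orient correctly. Sign-mixed programs leave half the children
  as non-proxies and empirically destroy orientation at realistic n; this
  trade-off, not aesthetics, fixed the demo world. The acceptance
  experiment for hub recovery uses the unconfounded world
  (subtype effect 0), which is the regime whose assumptions the PC stage
  actually states.

What the generator does **not** emulate: read-count noise, library-size
and voom effects, batch structure, probe-level artifacts, non-Gaussian
marginals, feedback loops, and latent confounders other than the subtype
itself. A green suite therefore establishes correctness of the algorithms
under their stated assumptions — not robustness to everything real
RNA-seq does.

## 3. Numerical choices and degenerate inputs

* Fisher-z statistic \(\sqrt{n-|S|-3}\,|\mathrm{atanh}\,r|\); partial
  correlations clamped to ±(1 − 1e-12); conditioning order capped at
  n − 4.
* Cox screen: constant genes return coef 0, p 1, direction none, flagged;
  non-convergence is flagged and the screen continues.
* `filter_zero_heavy` uses "more than" semantics: a gene with exactly 70%
  zeros is retained.
* z-scoring uses the sample SD (n−1); constant genes are dropped with a
  warning.
* PAM uses the deterministic build+swap algorithm (`pamonce = 6`
  acceleration, result-identical), so every consensus round is
  reproducible from the seed.
* All generators derive sub-stream seeds from a single root seed; equal
  inputs give bit-identical outputs.
* Empirical null p uses the add-one form, never exactly zero.

## 4. Known limitations

* PC assumes causal sufficiency; the latent subtype violates it in the
  composite demo, which is handled by world design (see above) rather
  than by algorithmic extension (FCI is out of scope).
* Summarized degree is orientation-driven: in regimes where PC leaves
  most edges undirected, master recovery degrades gracefully toward an
  empty call rather than a wrong one.
* The |coef| > 0.2 network cut is expression-scale-dependent by
  construction and is not rescaled internally.
* The random forest uses per-split feature sampling on axis-aligned CART
  trees; interaction-only signals with zero marginal effect are found
  slowly, as with any such forest.
* LOOCV re-searches the grids per fold, which is honest but quadratic in
  n; for n in the thousands, k-fold CV would be the pragmatic substitute.
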