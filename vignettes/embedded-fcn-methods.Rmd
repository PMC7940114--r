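---
title: "Embedded functional connectivity networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedded functional connectivity networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedfcn)
```

# The problem

Resting-state fMRI yields one noisy time series per brain region
(ROI).  A functional connectivity network (FCN) summarises the
statistical dependence between regions as a weighted graph; local
graph measures of that network can then serve as features for
classifying subjects, and the features a sparse classifier keeps are
candidate biomarkers.  `embedfcn` implements this pipeline for
parcellated time series (the 84-region Desikan-Killiany regime:
`T ~ 150` volumes at a repetition time of 2 s), with two FCN
constructions — the direct cross-correlation pseudo-distance and an
ISOMAP re-embedding of it — and a leakage-proof double cross-validation
around the classifier.

# Connectivity model

For two ROI series the lagged cross-correlation at lag $l$ is the
Pearson-type statistic

$$\mathrm{CCF}(A_i, A_j, l) =
  \frac{\sum_t (A_{i,t+l}-\bar A_i)(A_{j,t}-\bar A_j)}
       {N\, s_i\, s_j},$$

with the sum over the $N-|l|$ aligned pairs (truncated overlap, not
circular) and means and standard deviations taken over the full
series.  This is the convention of classical time-series analysis
(`stats::ccf`); the Cauchy-Schwarz inequality keeps the value in
$[-1,1]$ and lag 0 reduces to the plain Pearson correlation.  The
normalisation convention is not fully determined by the statistic's
usual presentation; this one is fixed and documented here.

The pseudo-distance between two ROIs is
$d_c(i,j) = 1 - \max_{|l| \le 3} |\mathrm{CCF}(i,j,l)|$: strongly
correlated regions are close even when their coupling is shifted by a
few samples.  `l_max = 3` (seven correlation scores per pair) is the
default; it is exposed as a parameter.  With TR = 2 s this admits
haemodynamic offsets up to six seconds.

# ISOMAP embedding

The pseudo-distance matrix is full: every pair has some correlation.
ISOMAP re-expresses it through its manifold structure in three steps:

1. **k-NN graph.** Each ROI is linked to its `k` nearest neighbours
   (by $d_c$); the edge set is symmetrized by union, and ties in the
   neighbour ranking break toward the smaller node index.  Edges carry
   the distance $d$ and the affinity $w = 1/d$.  Below `k = 6` such
   graphs tend to fragment; above `k = 20` most nodes are neighbours of
   most others and geodesics lose meaning, so the recommended grid is
   `k in 6..20`.  A fragmented graph raises an error naming the
   components; an explicit `on_fragmented = "largest"` override embeds
   the largest component and warns loudly.
2. **Geodesics.** All-pairs shortest paths over the edge lengths
   (Dijkstra, via igraph).  The affinities ride along on the graph but
   play no role in path finding.
3. **Classical MDS.** Double-center $-\tfrac12 D_G^2$, eigendecompose,
   and scale eigenvector $j$ by $\sqrt{\lambda_j}$.  Geodesic matrices
   are generally non-Euclidean, so negative eigenvalues occur; they are
   excluded from the coordinates and their largest magnitude recorded.

Two diagnostics guide the choice of the embedding dimension `p`:
the averaged eigengap sequence $\lambda_j - \lambda_{j+1}$ over the
top 15 eigenvalues, and the residual variance
$1 - R^2(D_G, D_Y)$, where $R$ is the Pearson correlation between the
upper-triangle vectorizations of the geodesic and the embedded
Euclidean distances.  Upper triangles (diagonal excluded) are used;
for symmetric matrices the value is identical to a full-matrix
correlation without the zero diagonal.  On noiseless Euclidean input
with a complete neighbour graph the embedding is exact at the true
dimension (residual variance 0 to machine precision), which is how
the test-suite fixtures with known intrinsic dimension are built.

# FCN graphs and node measures

Proportional thresholding keeps the
$\mathrm{round}(PT/100 \cdot M(M-1)/2)$ smallest-distance pairs, so
graph density is identical across subjects — the standard guard
against density-driven group differences.  Rounding is half-up and
boundary ties break lexicographically; the graph remains weighted
($w = 1/d$).  Thresholds are nested: a higher PT keeps a superset of
the edges.

Five local measures per node: strength $s_i = \sum_j a_{ij} w_{ij}$;
local efficiency (global efficiency — mean reciprocal shortest-path
length, unreachable pairs contributing 0 — of the subgraph induced by
the node's neighbours); the weighted local clustering coefficient
$c_i = \frac{1}{s_i(k_i-1)}\sum_{j,h}\frac{w_{ij}+w_{ih}}{2}
a_{ij}a_{ih}a_{jh}$; weighted betweenness centrality (shortest paths
by edge length, endpoints excluded); and the participation coefficient
$PC_i = 1 - \sum_m (k_i(m)/k_i)^2$ over Louvain modules, with binary
degrees.  Degenerate conventions: degree 0 gives all measures 0;
degree 1 gives clustering and efficiency 0.  Shortest-path measures
use the lengths $d$; strength and clustering use the affinities $w$,
consistent with edges representing distances.  Louvain community
detection is stochastic, so it is run under a derived seed with ten
restarts, keeping the highest-modularity partition; the per-subject
seed derives from the pipeline master seed and the subject index.

The feature vector flattens the five measures in measure-major order
(strength, efficiency, clustering, betweenness, participation), giving
$5M = 420$ named features for 84 ROIs.

# Feature selection

**LASSO.** The squared-error objective
$\arg\min_a \tfrac{1}{2n}\lVert y - a_0 - Xa\rVert^2 +
\lambda \lVert a\rVert_1$ is solved by a compiled cyclical
coordinate-descent solver (soft-threshold updates, warm starts,
active-set sweeps with Karush-Kuhn-Tucker passes to admit violators,
at most 150 sweeps per $\lambda$) along 100 log-spaced $\lambda$
values from $\lambda_{\max}$ (the smallest value with an all-zero
solution) down to $10^{-3}\lambda_{\max}$.  The solver is
cross-checked against the soft-threshold closed form on orthonormal
designs, the least-squares limit, and an independent reference
implementation.  An
alternative would be a logistic (binomial) LASSO; the squared-error
form on 0/1 labels with a 0.5 decision threshold is used here, and the
choice is confined to `lasso_path()`.  Features are standardized from
the training subjects of each fold only — held-out statistics never
leak in — and the intercept is unpenalized.  Leave-one-out CV scores
each $\lambda$ by misclassification, and the one-standard-deviation
rule picks the largest $\lambda$ whose CV error is within one standard
deviation of the best.  The plain SD of the 0/1 fold errors is used
(not the standard error; `rule = "se"` switches).  Two behavioural
consequences are worth knowing.  First, with balanced labels the
intercept-only end of the path has LOOCV misclassification 1.0, not
0.5: removing a subject tips the training mean away from that
subject's class, so the fitted response always lands on the wrong side
of 0.5.  The empty model is therefore never chosen, and
label-permuted data yield one or two spurious features rather than
none.  Second, the rule is bimodal: when some $\lambda$ attains CV
error exactly 0 the SD is 0 and only zero-error models qualify
(selection is then sharp); otherwise the wide Bernoulli SD usually
admits a single-feature model.  A practical consequence is that the
five measures of one node are strongly collinear — a coupling change
at a node moves several of them at once — and the rule's parsimony
lets them stand in for each other: which member of such a bundle is
selected can rotate across folds or cohorts even when the bundle
itself is selected very stably.

**Random forest.** Thirty independent forests of 500 trees (Gini
splitting, $\lfloor\sqrt{p}\rfloor$ candidate features per split,
trees grown to purity) are averaged into a per-feature mean decrease
in Gini impurity, reported on the per-sample scale: each split
contributes the node's sample fraction times its impurity decrease.
The top 5% (ceiling) of features are retained in descending MDG, and
nested subsets of sizes 1, 3, 5, … are scored by LOOCV accuracy of the
linear SVM (`C = 1`) — the same model used downstream, so the inner
and outer objectives match.  Ties go to the smallest subset.

# Classification and validation

The classifier is a soft-margin linear SVM with `C = 1` on
fold-standardized features.  The double leave-one-out scheme holds out
one subject; the *entire* selection procedure (which internally runs
its own LOOCV) sees only the remaining subjects; the SVM trains on
those subjects restricted to the selected features; and the held-out
subject is predicted.  Patients are positives: sensitivity is
TP/(TP+FN), specificity TN/(TN+FP).  Selection counts over the outer
folds (each feature can be chosen at most $n$ times) summarise how
stable each biomarker candidate is.  An empty inner selection falls
back to the single feature most correlated with the training labels,
with a message.  A response of exactly 0 classifies as the negative
class.  Seeds fan out as master seed + outer-fold index, so any single
fold can be reproduced in isolation.

The companion `group_compare()` reports per-feature Welch t statistics
with Bonferroni control at $\alpha / n_{\text{features}}$ (0.05/420 in
the default regime).

# The synthetic cohort generator

No public generative model exists for this kind of data, so the
generator is the package's own convention, built to emulate the
features of parcellated resting-state data that matter to the
pipeline; its defaults are fixed and documented here.

* **Latents.** Each of 4 modules (resting-state-network-like blocks of
  contiguous ROIs) has a band-limited latent signal: white noise
  smoothed by a 5-sample moving average (10 s at TR 2 s), standardized.
* **ROIs.** An ROI is `0.8 x` its module latent `+ 0.25 x` one
  designated other-module latent `+ N(0, 0.6)` noise.  A quarter of
  ROIs receive their cross-module term at a lag of 1–3 samples,
  applied by truncation (not wrapping), matching the non-circular
  estimator.  15% of ROIs are *connector hubs* whose cross-module
  coupling equals the within-module value.  Connectors are what keeps
  the k-NN graph of real FCNs connected across the `k in 6..20`
  range; a purely block-modular toy fragments at every such `k`.  The
  moderate generic cross-coupling matters too: it places the
  proportional-threshold cutoff just below the noise floor of
  uncoupled pairs, so whether an uncoupled pair sneaks under the
  cutoff is rare rather than a coin flip, and the participation
  coefficient of unperturbed nodes stays comparatively stable across
  subjects.
* **Planted effects** (patients).  A `raise_participation` node starts
  from an integrative-hub baseline — even coupling to its own and one
  partner module — and in patients spreads into every remaining module
  at the effect-size coefficient, rescaled so the node's total
  coupling energy is unchanged: participation rises without a strength
  artefact.  `lower_strength` multiplies the node's couplings by
  `1 - effect_size`.  Patients express every planted effect in full.
* **Subclinical controls.** 20% of controls carry *one* planted
  effect (chosen at random) at a partial severity drawn from
  U(0.5, 0.75) — the single-marker overlap that makes individual
  biomarkers unspecific in real cohorts; no control is aberrant on
  every marker at once.  This gives each single planted feature a
  realistic false-positive rate while the marker pair remains far more
  discriminative jointly.  The documented "strong" setting
  (`strong_planted_nodes()`) uses effect size 0.8 for both nodes.
* **Seeding.** Subject `i` uses seed
  `(master_seed + 7919 i) mod (2^31 - 1)`; index 0 seeds the cohort
  wiring (module targets, lags, connector flags).  Cohorts are
  bit-reproducible and subjects independent.

What the generator does *not* emulate: haemodynamic response shapes,
physiological noise spectra, scanner drift, spatial autocorrelation
between neighbouring parcels, or realistic inter-regional anatomy.
Passing recovery tests therefore demonstrate that the pipeline's
machinery is correct and leak-free — not that comparable accuracy
would be reached on clinical data.

# Problem sizes and numerical choices

The recovery and permutation test suites run the full pipeline on
cohorts of 60 subjects (30/30) with 84 ROIs and 150 timepoints —
the regime the pipeline targets — and scaled-down cohorts (36 ROIs)
for the distribution-level unit tests.  Oracle checks use graphs of at
most 12 nodes, where exhaustive enumeration (all-pairs Floyd-Warshall,
branch-and-bound path counting) is exact.  Tolerances: graph measures
and MDS reproduce oracles to 1e-9; the LASSO path matches the
soft-threshold closed form to 1e-6 (coordinate-descent tolerance 1e-9,
relaxed to 1e-5 inside cross-validation where only 0/1 decisions
matter); the SVM matches a quadratic-programming solve of its dual to
1e-4.  Louvain ties and restarts are controlled by seed; distance ties
in thresholding and neighbour ranking break deterministically
(lexicographic / smaller index) so reruns are bit-identical.

# Behaviour under label permutation

A common sanity check runs the double cross-validation on
label-permuted data and expects chance-level accuracy.  Two effects
make the outcome wider than a Binomial(n, 1/2) band when the cohort
carries a real group difference.  First, a random permutation of
balanced labels agrees with the true labels anywhere between roughly
40% and 60% of the time; since the pipeline can still learn the true
structure from the permuted training folds, its permuted-label
accuracy tracks — and, through fold-level selection, amplifies — that
agreement.  Second, deviations *below* 50% (anti-learning) are the
signature of a leak-free pipeline meeting labels that contradict the
data; a leaky pipeline would instead score systematically above
chance on the permuted labels themselves.  The leakage contract is
therefore tested directly (a held-out subject's features cannot
influence its own fold's selection or model) rather than inferred
from the permutation distribution alone.

# Known limitations

* The squared-error LASSO with a 0.5 threshold is a linear-probability
  approximation to the classification task; a binomial-deviance path
  would weight borderline subjects differently.
* Proportional thresholding guarantees equal density, not equal
  topology; at low PT the graph can disconnect, which the local
  measures tolerate (unreachable pairs contribute zero) but global
  interpretations would not.
* The ISOMAP residual variance compares geodesics with embedded
  distances; with sparse neighbour graphs the geodesics themselves are
  polygonal overestimates of the manifold metric, so the residual
  variance does not converge to zero even for perfect recovery.
* Louvain community structure is re-estimated per subject; module
  identity is not matched across subjects, which is fine for the
  participation coefficient (a per-subject quantity) but would not
  support cross-subject module comparisons.
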