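---
title: "Methods: SSR-based origin inference with ssrOrigin"
author: "ssrOrigin maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR-based origin inference with ssrOrigin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# Scientific problem

Seized or sampled plant material of unknown provenance can often be tied
to a geographic origin through population-specific genetic markers.
Microsatellites (simple sequence repeats, SSRs) are short tandem repeats
of 1–6 bp motifs whose copy number varies between populations while
staying stable within them, which makes them natural candidates for such
markers. `ssrOrigin` implements the full inference chain:

1. detect SSRs in per-sample consensus genomes that share one reference
   coordinate frame;
2. encode each repeat as a binary presence/absence feature keyed by the
   triple (locus, motif, repeat count), so `LOC123|GA|5` means "this
   sample carries exactly five GA units at locus LOC123";
3. select small, discriminative marker panels with four strategies;
4. benchmark three classifiers over those panels with leave-one-out
   cross-validated (LOOCV) learning curves;
5. visualise sample relatedness by Jaccard-distance principal coordinate
   analysis (PCoA) and UPGMA clustering.

A synthetic-data generator plants known group structure into feature
tables or complete FASTA/GFF3 sample sets, so every stage can be
validated against a ground truth.

# SSR detection

`detectSSRs()` reports every maximal perfect run of a primitive 1–6 bp
motif whose number of *full* unit copies reaches the per-unit-length
minimum (`defaultThresholds()`: mono 10, di 5, tri 4, tetra 3, penta 3,
hexa 3 — the smallest counts seen in published marker panels of this
type). Conventions that matter for reproducibility:

* Coordinates are 0-based half-open, so
  `end - start == nchar(motif) * repeat_count` always holds. GFF3 input
  (1-based inclusive) is converted on read.
* Runs are anchored at the start of the maximal periodic region and the
  motif is reported as it first appears there; a run is never reported
  again under a non-primitive unit (`ATATATAT` is one `(AT)4`, never
  `(ATAT)2`).
* Partial trailing units are excluded from the span and count.
* `N` never extends a run.

`classifyCalls()` applies two post-processing rules: consecutive
same-motif runs separated by at most `interrupt_max_bp = 4` merge into
one *imperfect* call whose count is the sum of unit copies; after
merging, adjacent calls of different motifs separated by at most
`compound_gap_bp = 10` are both marked *compound* (compound status
overrides imperfect). `assignLoci()` maps calls to annotated genes by
maximal base-pair overlap (ties to the smaller gene start; no overlap
yields a synthetic intergenic bin id), and `buildFeatureMatrix()`
produces the binary `SSRFeatureSet`, a `SummarizedExperiment` subclass
holding the `presence` assay, the key components in `rowData` and the
origin groups in `colData`.

```{r detect-example, eval = FALSE}
library(ssrOrigin)
detectSSRs(c(chr1 = "TCATCATCATCATCA"))
#>   sample_id seq_id start end motif repeat_count ssr_class contains_n
#> 1      <NA>   chr1     0  15   TCA            5   perfect      FALSE
```

# Feature selection

Four strategies produce `SSRSelection` objects:

* **Group-wise conserved filter** (`gcSSRSelect()`): keep a feature iff
  it is present in *every* sample of at least one origin group, and
  record which groups. No cap is applied — the natural size of this
  panel defines the cap used by the other three strategies, mirroring
  how a conserved-marker panel defines the marker budget in practice.
* **Top-k by ANOVA F** (`selectKBest()`): one-way classification
  F-value per feature (infinite when within-group variance is zero but
  between-group variance is not), ties broken lexicographically by key.
* **Hybrid filter + wrapper** (`hybridSelect()`): `selectKBest` down to
  `k1` (default 5000), then a seeded random search (default 150 draws,
  stratified 4-fold CV, weighted-F1 criterion) over the random-forest
  space (`forestSearchSpace()`: 50–500 trees, depth 2–20, min node size
  1–5, feature fraction sqrt/log2/uniform 0.1–1), then recursive
  feature elimination (RFE) with step 1 on impurity importances down to
  `k2`.
* **Lasso** (`lassoSelect()` / `lassoFit()`): one-vs-rest L1-penalised
  logistic classifiers fitted with `glmnet`
  (`family = "binomial"`, `alpha = 1`, `standardize = FALSE`). The
  sampled inverse-regularisation value C maps to glmnet's penalty as
  $\lambda = 1/(n\,C)$; candidates are drawn log-uniformly from
  $[10^{-3}, 10^3]$ and scored by LOOCV weighted F1, with ties resolved
  towards stronger regularisation. Features with any non-zero
  coefficient are kept, ranked by the maximum absolute coefficient
  across classes.

The model's training objective is summarised by `lassoLoss()`:

$$
\mathcal{L} = -\frac{1}{n}\sum_{i=1}^{n}\sum_{k=1}^{K}
  \mathbb{1}(y_i = k)\,\log p_{i,k}
  \;+\; \lambda \sum_{k=1}^{K}\sum_{j=1}^{m} |\omega_{k,j}|,
$$

where $p_{i,k}$ are the per-class sigmoid scores normalised across the
$K$ one-vs-rest components (clamped below at $10^{-15}$). The test
suite checks this against an independent double-sum oracle, against the
analytic value $\ln K$ for uniform probabilities, and for monotonicity
in $\lambda$.

# Classifier benchmarking

`runBenchmark()` crosses every selection with three classifiers:

* **Linear SVC**: binary `e1071::svm` machines (linear kernel, no
  scaling, balanced class weights) composed one-vs-rest in package
  code. The primal weight vector is recovered as
  $w = \text{coefs}^\top \text{SV}$ and each component is oriented so
  larger decision values mean "this class"; per-feature importance is
  the sum of $|w|$ over components.
* **Random forest**: `ranger` with impurity importance, balanced class
  weights, a fixed seed and one thread.
* **Gradient boosting**: `xgboost` `multi:softprob` with gain
  importance, one thread and a fixed seed.

For each pair the harness (i) tunes hyperparameters (default 100
configurations, stratified 3-fold CV, weighted F1) — the default
configuration is always candidate 1, so tuning can never score below
the untuned model on the same folds; (ii) ranks the selected features
by step-1 RFE at fixed hyperparameters; (iii) builds a LOOCV learning
curve for panel sizes $k = 1..k_{\max}$ over replicates (replicate $r$
uses seed $\text{base} + r$), storing mean and SD of weighted F1,
accuracy, precision and recall plus per-k and overall mean confusion
matrices; (iv) picks the smallest $k$ attaining the maximum mean
weighted F1 (`chooseBest()`).

The default tuner is a light sequential model-based optimiser: after a
random initial design, each next candidate maximises a random-forest
surrogate of the CV score over a pool of random draws. A pure random
search is available via `method = "random"`. The surrogate proposes by
predicted mean (no expected-improvement acquisition), which is adequate
at the panel sizes involved here.

LOOCV fits exactly $n$ models per replicate; this contract is
instrumented (`fitCount()`) and asserted in the tests.

# Clustering

`jaccardDistance()` computes $d(A, B) = 1 - |A \cap B| / |A \cup B|$
over the selected panel (two samples carrying no panel feature are at
distance 0). `pcoaAnalysis()` performs classical metric scaling (Gower
double-centering; axes with positive eigenvalues; no Lingoes/Cailliez
correction), and `upgmaTree()` is unweighted average linkage whose
cophenetic distances reproduce ultrametric inputs exactly. Newick
serialisation uses the half-height edge convention: a pair merging at
distance 2 serialises as `(A:1,B:1);`.

# The synthetic study design

`simulationConfig()` defaults describe the reference study the package
targets: four origin groups sized 8 (PG), 4 (CO), 12 (MP) and 14 (FG);
8, 6 and 5 planted group-conserved markers for CO, MP and FG; PG
heterogeneous (no marker may be conserved across all its samples,
enforced by rejection redraws); 200 noise features; motif-length
weights skewed towards dinucleotides (0.20/0.48/0.17/0.06/0.05/0.04).

`noise_presence_prob = 0.15` is the probability that a planted marker
appears outside its own group, or a noise marker anywhere. The value
encodes the empirical observation that most group-conserved markers in
studies of this kind are *exclusive* to their group, with the remainder
carried by scattered individual samples elsewhere: at 0.15 a marker is
expected in roughly one sample per foreign group, keeping exclusivity
typical but not universal. Substantially higher rates would make
foreign samples carry near-complete marker sets of other groups, which
contradicts that observed exclusivity.

In `genome_mode`, the generator writes a repeat-free reference
chromosome (detected runs are broken iteratively), centres each planted
array inside its annotated locus, and sets the flanking bases so the
array can neither extend nor merge with its surroundings. Detection →
classification → matrix construction therefore recovers the simulated
truth table exactly, which the tests assert.

What the generator deliberately does **not** emulate: sequencing error
and coverage gaps (beyond the `injectN()` helper), repeat-length
mutation processes, linkage between loci, within-group population
substructure, and imperfect/compound repeats in the planted arrays (all
planted arrays are perfect).

# Pipeline and reproducibility

`runPipeline()` executes simulate → extract → select → bench → cluster
from a YAML configuration (`validateConfig()` fills documented defaults
and rejects unknown keys). Each stage derives its seed from the global
seed plus a fixed offset, writes its interface files (CSV/TSV/JSON/
Newick) under `output_dir`, and appends JSON-lines log records; a
manifest and a provenance record complete the run. Identical seeds
reproduce byte-identical selection, curve and tree outputs — this is an
acceptance-tested property.

Typical problem sizes: the default synthetic study is 38 samples × 219
features; the acceptance run (tuning 20 configurations, ranking 19
features, a 15-point learning curve with 5 replicates, PCoA/UPGMA and a
genome-mode round trip) completes in under a minute on one CPU.

# Limitations

* The linear SVC one-vs-rest composition uses the empirical-orientation
  heuristic described above; degenerate folds in which a class is
  absent yield $-\infty$ decisions for that class.
* UPGMA tie-breaking between equally close cluster pairs follows
  `stats::hclust`; ultrametric reconstructions are unaffected.
* The Lasso LOOCV tuner refits $K$ binary models per held-out sample
  per candidate; it is intended for the post-selection panel sizes
  (tens of features), not for genome-scale matrices.
* PCoA reports negative eigenvalues unchanged; proportions explained
  are computed over positive eigenvalues only.
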