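---
title: "Methods: evolutionary model selection for protein-protein interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary model selection for protein-protein interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`ppievolve` predicts and ranks protein-protein interactions (PPIs). The
stack has five stages:

1. **Dataset curation** — interaction records read from an iRefIndex-style
   PSI-MITAB table pass a filter cascade (UniProt-identified partners,
   RIGID redundancy-group deduplication, detection-method rule, host
   taxon), negatives are sampled at a fixed ratio (2:1 by default, matching
   the natural excess of non-interacting pairs), and test sets are
   decontaminated by removing pairs homologous to training pairs.
2. **Feature characterization** — each unordered pair gets a fixed-order
   61-slot feature vector with an explicit missingness mask.
3. **Evolutionary model selection** — a multi-objective Pareto-based
   evolutionary algorithm (EA) jointly selects a feature subset, an
   estimator kind (SVM or random forest) and its hyperparameters, scored by
   stratified cross-validation (CV).
4. **Affinity regression** — binding affinities (Kd/Ki) are converted to
   Gibbs free energy via $\Delta G = RT\,\ln K_d$, min-max normalized to a
   $[0,1]$ endpoint, and regressed by the same EA with regression
   estimators and objectives.
5. **Interactome screening** — candidate receptor-proteome pairs are
   classified (best-model rule), positive pairs receive an ensemble
   affinity prediction, and interactions are ranked by the mean of the
   classification probability and the min-max-scaled affinity.

# The feature panel

The 61 features, in registry order
(`feature_registry()`):

* **GO-term similarity x 3** — per-aspect (BP/MF/CC) Jaccard index over
  direct annotations, in $[0,1]$, missing when both sets are empty. The
  similarity measure is pluggable (`go_similarity(measure = ...)`) so
  information-content measures over the GO graph can be substituted;
  Jaccard is the default because it is the simplest measure satisfying the
  $[0,1]$ contract without requiring the ontology graph.
* **Orthologous-interaction flags x 4** — unordered-pair membership in
  interaction tables for *M. musculus*, *D. melanogaster*,
  *S. cerevisiae*, *E. coli* (pre-mapped to human accessions).
* **Database flags x 4** — membership in MINT, APID, BioGRID and a fourth,
  configurable source (placeholder label `DB4`; only three sources are
  fixed by the panel).
* **Sequence similarity x 1** — the externally computed alignment-search
  E-value of the pair's two sequences; missing when not supplied. The
  package never runs the search itself.
* **Domain-domain interaction x 1** — 1 iff any cross-product of the two
  proteins' Pfam domains is a known interacting domain pair.
* **Co-localization x 1** — 1 iff the subcellular compartment sets
  intersect; missing when either localization is unknown.
* **Co-expression x 17** — Spearman correlation of the pair's expression
  profiles in each of 17 expression datasets; missing when a protein is
  absent from a dataset, fewer than 3 samples overlap, or a profile is
  constant. The panel can be reconfigured to treat additional RNA-seq
  datasets as separate features, which changes the registry length; the
  17-dataset default is what reaches exactly 61 features.
* **Physicochemical differences x 30** — absolute differences of: the 20
  amino-acid composition fractions; molecular weight (average residue
  masses minus peptide-bond water); aromaticity (F/W/Y fraction); the
  Guruprasad dipeptide instability index; helix/turn/sheet residue-class
  fractions (helix {V,I,Y,F,W,L}, turn {N,P,G,S}, sheet {E,M,A,L} — the
  classes are a convention, fixed here and documented because different
  toolkits use different sets); molar extinction coefficients at 280 nm
  (Gill-von Hippel: $5500 n_W + 1490 n_Y$, plus $125\lfloor n_C/2\rfloor$
  per cystine); Kyte-Doolittle GRAVY; and net charge at pH 7 by
  Henderson-Hasselbalch over the EMBOSS pKa set (the pKa table is a
  declared choice; the panel only needs a consistent one).

Missing values are carried in an explicit mask and are **never** imputed at
feature time; mean imputation is fitted inside each training fold (and on
the full training set at refit time), so no test information leaks into
preprocessing.

# The evolutionary optimizer

Each genome is a real vector in $[0,1]^{F+4}$: $F$ feature genes
(selected iff $\ge 0.5$; an all-off genome is repaired by enabling the
argmax gene), an estimator-selector gene, and three hyperparameter genes
decoded onto $C \in [2^{-5}, 2^{15}]$ and $\gamma \in [2^{-15}, 2^{3}]$
(log-uniform) and trees $\in [10, 500]$ (linear).

Objectives are maximize-oriented and normalized to $[0,1]$; count
objectives are scaled by their configured maxima. Classification:
feature-count minimization (weight 1), accuracy (10), F1 (10), F2 (1),
precision (1), recall (1), ROC-AUC (1), model-size minimization — support
vectors or trees — (1), and the Manhattan objective (1), interpreted as one
minus the mean $L_1$ distance between predicted positive-class
probabilities and the binary labels. Regression: feature significance
(interpreted as feature-count minimization, 1), negative MSE (10), MAE (1),
explained variance (1), model-complexity minimization (1), RMSE (1), and
Spearman correlation mapped to $[0,1]$ (1). Undefined metrics (e.g.
precision with no positive predictions) enter the objective vector as 0 —
worst case — while the reported CV metrics keep `NA`.

The scalarization used alongside Pareto ranking is a weighted sum of these
normalized objectives. The generational scheme, which the underlying
method leaves open, is: tournament selection (size 2) on weighted fitness;
two-point crossover with probability 0.9, arithmetic crossover 0 and
per-gene uniform mutation 0.01 (the published EA parameter profile);
Pareto-front elitism (the current front, capped at half the population,
survives unchanged, which makes the best weighted fitness non-decreasing);
and an **archive front**: the returned Pareto front is computed over every
individual evaluated during the run, not only the final generation.
Identical genomes are evaluated once (cached), and the whole run is
reproducible bitwise under `ea_config(seed = )`.

Estimators: RBF-kernel SVM and random forest for classification; linear
SVR, RBF SVR and random-forest regression for regression. The RBF kernel
is assumed for the classification SVM, mirroring the regression variant. A
small feed-forward neural regressor can be enabled
(`ea_config(enable_nn = TRUE)`) but is off by default: its architecture is
not pinned down by the method description and determinism is preferred.
Random forests are fitted with `ranger` (single-threaded, seeded from the
R RNG stream). SVM positive-class probabilities are sigmoid-mapped
decision values rather than internally cross-validated Platt scaling —
roughly five times cheaper inside the EA loop, monotone in the margin, and
sufficient for voting, the Manhattan objective and ranking; the absolute
calibration of these probabilities is not guaranteed and they should not
be read as calibrated posteriors.

## Evaluation and ensembles

Cross-validation is stratified (per-class round-robin after shuffling, so
per-fold class proportions are within one sample of the global ones).
ROC-AUC is the Mann-Whitney rank statistic. The **best-model** rule picks
the front member with the highest weighted fitness (ties: fewer features,
then lexicographic genome). The **ensemble** rules: classification
members need CV accuracy strictly above 0.80, regression members CV
Spearman correlation strictly above 0.2; per sample, a member votes only
if strictly less than half of its selected features are missing; labels by
majority vote (even splits decided by mean probability $\ge 0.5$, which is
always available because probabilities are reported alongside votes);
probabilities and regression predictions by averaging over voters; samples
with no eligible voter are flagged unpredictable, never silently imputed.
The accuracy filter is applied against CV accuracy once at front load — CV
accuracy is the only accuracy available at prediction time.

# Affinity endpoint

$\Delta G = R T \ln K$ with $R = 8.314\,\mathrm{J\,mol^{-1}K^{-1}}$,
the experimental temperature when recorded and 300 K otherwise, reported
in kJ/mol ($K_d = 1\,\mathrm{M} \Rightarrow 0$;
$K_d = 10^{-6}\,\mathrm{M}, 300\,\mathrm{K} \Rightarrow -34.46$).
Curation keeps human, dimeric, exactly-valued records in supported units
(Kd/Ki in molar units, dG in kJ/mol) and collapses duplicates to first
occurrence, with machine-readable rejection reasons. The regression
endpoint is the min-max normalization of the training $\Delta G$ values;
the scaler is fitted on the training split only and reused for inversion
(which split defines the scale is otherwise arbitrary; fixing it to
training avoids test leakage). RMSE on the normalized scale times the
scaler span equals RMSE in kJ/mol exactly (affine invariance), which the
tests assert numerically. Screened libraries print $|\Delta G|$, the
conventional positive presentation of binding strength; the signed value
is stored.

# The synthetic world

`generate_world()` emulates every input the pipeline consumes: a random
proteome, GO/Pfam/localization annotations, 17 expression matrices, an
iRefIndex-style interaction table, a negative-pair list, E-value tables,
affinity tables with decoy rows, and a receptor catalog. Interaction
signal is planted into five feature channels — GO similarity in the three
aspects, the domain-interaction flag and co-localization. For each
true-interacting pair, each channel applies independently with its effect
probability; GO planting adds a fresh shared "functional module" of terms
to *both* proteins (union semantics over 500-term vocabularies), so a
protein participating in several interactions keeps all its planted
modules. Co-expression for interacting pairs can be drawn from a shared
latent factor (`expression_rho`), default 0. Observed labels are the true
labels flipped with probability `noise`.

Default conditions: 300 proteins, 200 positive and 400 negative pairs,
label noise 0.05, effect sizes `BP/MF = 0.85`, `CC = 0.7`, `pfam = 0.75`,
`coloc = 0.85`. These defaults were chosen once so that the planted
separation is nearly perfect on the true labels: with 5% label flips the
AUC attainable against *observed* labels is bounded near 0.94 regardless
of the model, so a generator meant to demonstrate recovery above 0.9 must
plant close-to-perfect true-label separation. What passing these tests
shows is that the optimizer finds a planted, mostly linear, low-dimensional
signal under label noise — not that real interactomes are this separable;
real data have correlated features, much weaker effects, heavy
missingness, and composition-biased sequence features, none of which the
generator reproduces beyond carrying non-uniform residue frequencies.

# Problem sizes and numerical choices

The demonstration runs in the tests and the acceptance script use a
scaled-down optimizer configuration — population 30, 20 generations,
5-fold CV — on the default 600-pair world; the full-scale profile
(population 50, 100 or 1000 generations, 10-fold CV) is the package
default for real use. Other numerical choices: tie-breaks in best-model
selection (fewer features, then lexicographic genome) and in ranking
(probability, then pair key) make every ordering deterministic; degenerate
cases error loudly (single-class folds, all-equal endpoints, empty
fronts); unknown E-value lookups count as not-similar during test-set
decontamination (conservative retention, logged) because an incomplete
all-vs-all search must not silently discard test pairs; round-to-nearest
is used for the negative-sampling count and floor for the train/test
split, the latter matching a 519-record table splitting 415/104 at 80%.

# Known limitations

* GO similarity ignores the ontology graph unless a graph-aware measure is
  plugged in.
* SVM probabilities are monotone scores, not calibrated posteriors.
* The fourth database flag is a configurable placeholder.
* The neural regressor is intentionally minimal and disabled by default.
* Screened affinity scaling is relative to the screened positive set
  unless a fixed scaler is supplied, so mean scores are comparable within
  one screen, not across screens.
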