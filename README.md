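# ppievolve

Prediction and ranking of protein–protein interactions (PPIs) with a
multi-objective Pareto-based evolutionary algorithm, aimed at screening a
receptor family (e.g. human taste receptors) against a proteome.

Experimental interactomes are incomplete and noisy: high-throughput
detection misses interactions and reports false ones, and binding-strength
measurements exist for only a few hundred human pairs. `ppievolve` is for
computational biologists who want to (a) build curated, leakage-free
PPI training/testing datasets from iRefIndex-style PSI-MITAB tables,
(b) characterize protein pairs with a fixed 61-feature panel (GO-term
similarity, orthology and database evidence, domain–domain interactions,
co-localization, co-expression across 17 expression datasets, and 30
physicochemical sequence differences), (c) train classification and
binding-strength regression ensembles, and (d) screen and rank an
interactome.

## The core method

A genome $g \in [0,1]^{F+4}$ encodes a feature mask (gene $\ge 0.5$), an
estimator choice (SVM or random forest; linear/RBF SVR and RF regression
for the regression variant) and its hyperparameters
($C \in [2^{-5},2^{15}]$, $\gamma \in [2^{-15},2^{3}]$,
trees $\in [10,500]$). Each genome is scored by stratified k-fold
cross-validation on a weighted multi-objective profile — classification:
feature-count minimization (1), accuracy (10), F1 (10), F2 (1), precision
(1), recall (1), ROC-AUC (1), model-size minimization (1), Manhattan
distance (1); regression: feature significance (1), negative MSE (10),
MAE (1), explained variance (1), model complexity (1), RMSE (1),
correlation (1). Evolution uses tournament selection on the weighted sum,
two-point crossover (p = 0.9), uniform mutation (p = 0.01) and
Pareto-front elitism; the result is the archive Pareto front of mutually
non-dominated fitted models. Prediction uses either the best-weighted
model or front ensembles (majority voting with a CV-accuracy > 0.80
filter, or prediction averaging with a CV-correlation > 0.2 filter, and a
per-sample abstention rule when more than half of a member's features are
missing).

Binding affinities enter as $\Delta G = RT \ln K_d$ (kJ/mol, 300 K
default), min-max normalized to a $[0,1]$ regression endpoint. Screened
interactions are ranked by the mean of classification probability and
scaled affinity.

## Worked example

Everything below runs offline on a synthetic world with planted
interaction signal (300 proteins, 200 interacting / 400 non-interacting
pairs, 5% label noise):

```r
library(ppievolve)

world <- generate_world(seed = 1)             # proteome + annotations
fm    <- world_feature_matrix(world)          # 600 x 61 features

cfg   <- ea_config(population_size = 30, max_generations = 20,
                   cv_folds = 5, seed = 1)
front <- run_optimization(fm$features, fm$labels, "classification", cfg)
print(front)
#> Pareto front (classification): 22 member(s)
#>   random_forest  27 features  fitness 23.976
#>   random_forest  30 features  fitness 23.908
#>   random_forest  26 features  fitness 24.026
#>   ...
best <- select_best_model(front)
round(unlist(best$cv_metrics[c("accuracy", "roc_auc", "f1")]), 3)
#> accuracy  roc_auc       f1
#>    0.930    0.917    0.897
```

The best model's cross-validated accuracy (0.930) and AUC (0.917) say the
optimizer recovered the planted signal; the selection frequency of the
five planted feature channels across the front
(`feature_selection_frequency(front)`) exceeds that of the 56 noise
features about 1.8-fold. A regression front on the world's synthetic
affinity table and a ranked screen of a receptor catalog follow the same
pattern; see the methods vignette (`vignettes/ppievolve-methods.Rmd`) and
the command-line wrapper (`inst/scripts/ppievolve-cli.R`, subcommands
`make-fixtures`, `build-dataset`, `compute-features`, `evolve`, `screen`).

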