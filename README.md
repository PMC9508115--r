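# nestage

Infer the age class of breeding seabirds from variables measurable at the
nest in a single visit: egg dimensions and clutch size, optionally joined
with annual environmental covariates.

In long-lived colonial gulls, breeding performance is age-dependent —
newly recruited 3–4 year olds ("young") and senescent birds lay smaller
eggs and clutches than prime middle-aged breeders. Where a marked,
known-age subset of the colony exists, that signal can be turned into a
classifier for the unmarked majority. `nestage` implements the full
workflow:

* **Egg-volume features** — `V (cm³) = 0.000476·L·W²` (mm), per-nest total
  volume `VT`, mean volume `VM`, clutch size, NAO climate indices, fish
  landings and z-scored per-capita food availability.
* **GLM model selection** — Gaussian GLMs of egg volume under competing
  age parameterizations (linear, quadratic, logarithmic, categorical
  schemes), always with clutch size, ranked by AIC. A concave quadratic
  winning the comparison is the signature of poorer performance at both
  ends of life.
* **Balanced-bootstrap forest ensemble** — the core tool. Age classes are
  heavily imbalanced, so each of `n_iterations` bootstrap iterations
  downsamples every class to the smallest class's size, trains a random
  forest, and records out-of-bag error, confusion, Gini importances and
  full-dataset predictions. Aggregates give accuracy `100·(1−OOB)`,
  sensitivity/specificity for the 'Young' class, importance rankings and
  per-nest misclassification-consistency counts.
* **Evaluation** — confusion-matrix metrics, per-year/per-age error
  profiles, learning curves versus training-set size, and chi-square
  comparison of young-breeder proportions across colonies.
* **Synthetic colony generator** — a seeded simulator of nest and
  environment tables (right-skewed age pyramid on ages 3–28, modal clutch
  3, concave quadratic age effect on volume plus year/food/NAO effects)
  so that the entire pipeline is testable without field data.

## Worked example

```r
library(nestage)

cfg <- sim_config(seed = 7)              # 24 years x 100 nests
ds  <- generate_dataset(cfg)
ft  <- build_feature_table(ds$nests, ds$environment,
                           version = "full", scheme = "AGE2")

head(as.data.frame(select_age_model(ft, "VM")), 3)
#>                     model  k    logLik      AIC     dAIC
#> 1 VM ~ QUADRATIC + Clutch  8 -5830.723 11677.45   0.0000
#> 2     VM ~ AGE14 + Clutch 19 -6159.531 12357.06 679.6148
#> 3      VM ~ AGE6 + Clutch 11 -6173.948 12369.90 692.4494

res <- run_ensemble(ft, ensemble_config("AGE2", n_iterations = 20,
                                        n_trees = 150, seed = 7))
res
#> Balanced-bootstrap forest ensemble (AGE2, 20 iterations x 150 trees)
#>   accuracy 63.5%  sensitivity 65.9%  specificity 61.2% (positive: Young)
#>   Gini importance: VM=151.27, VT=117.80, ANAO=18.88, Clutch=18.70, ...
```

The AIC table says the quadratic age form beats every competitor by
hundreds of AIC units on this simulated colony: mean egg volume rises
from recruitment, peaks in mid-life and declines with senescence. The
ensemble then tells you how well nest variables alone separate young
breeders from the rest — here ~64% aggregated OOB accuracy, with the two
egg-volume predictors carrying almost all the Gini importance, an order
of magnitude above any environmental covariate.

A single call runs the whole pipeline and writes its artifacts
(`nests.csv`, `features.csv`, `glm_ranking.csv`, `ensemble_summary.json`,
misclassification reports, a seeded metadata header):

```r
run_pipeline(pipeline_config(seed = 7, out_dir = "run"))
```

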