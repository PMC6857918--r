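# survtopics

Survival prediction from high-dimensional gene expression via
**cancer-topic features**. The package compresses a patients × genes
expression matrix into a handful of interpretable "topic" loadings — by
globally z-scoring, discretizing each gene's deviations into signed bins
(dGEVs), encoding them as non-negative gene-word counts, and fitting a
latent Dirichlet allocation by variational EM — and feeds those loadings,
optionally with clinical covariates and supervised principal components
(SuperPC+), into a survival learner under right-censoring:

* **MTLR** (multi-task logistic regression): one logistic weight vector per
  time-grid point (`m = floor(sqrt(n))` quantile-placed points), giving each
  patient a full survival distribution
  `P(D >= t | x) ∝` reverse-cumulative `exp` scores, with exact
  marginalization over censored outcomes and a convex L2-penalized objective;
* **Cox / ridge Cox**: Breslow partial likelihood maximized by Newton's
  method, with a Kalbfleisch–Prentice baseline so these models also emit
  individual survival curves.

Models are evaluated by the concordance index (strict pairwise ranking over
comparable pairs) and by **D-calibration**: predicted survival probabilities
at observed death times should be uniform, tested with a Hosmer–Lemeshow
chi-square on 20 probability bins (`df = G − 2`). A synthetic cohort
generator with planted topic structure and topic-driven hazards makes every
stage testable without external data.

## Worked example

```r
library(survtopics)

# a topic-structured synthetic cohort: 400 patients, 200 genes, 3 topics,
# exponential hazards driven by the topic mixture, ~30% censoring
ch <- generate_cohort(simulation_config(n = 400, seed = 1))
split <- train_test_split(ch$labels, test_fraction = 0.2, seed = 2)
lbl_tr <- survival_labels(ch$labels$time[split$train], ch$labels$event[split$train])
lbl_te <- survival_labels(ch$labels$time[split$test],  ch$labels$event[split$test])

fit <- survtopic(ch$expression[split$train, ], ch$clinical[split$train, ], lbl_tr,
                 features = c("clinical", "dlda"), learner = "mtlr",
                 k_grid = 3, encodings = "enc_b", c_grid = 1, seed = 3)
print(fit)
#> Survival model with expression-derived features
#>   learner: MTLR; feature groups: clinical + dlda (6 columns)
#>   dLDA basis: K = 3, encoding enc_b
#>   training: 320 patients, 229 events

pred <- predict(fit, ch$expression[split$test, ], ch$clinical[split$test, ])
concordance_index(pred$risk, lbl_te)
#> [1] 0.7088138
d_calibration(pred$curves, lbl_te, n_bins = 20)
#> D-calibration (Hosmer-Lemeshow): HL = 25.3186, df = 18, p = 0.1164
#>   57 uncensored patients in 20 bins; calibrated at the 0.05 level
```

The concordance says the topic-plus-clinical MTLR model ranks ~71% of
comparable held-out patient pairs correctly (the clinical-only Cox baseline
on the same split reaches 0.58, since the planted hazard is mostly
topic-driven); the calibration p-value above 0.05 says the predicted
survival probabilities at the observed death times are consistent with the
uniform distribution a well-calibrated model implies. Bundles round-trip
losslessly with `save_bundle()` / `load_bundle()`, and
`inst/cli/survtopic.R` exposes `train` / `predict` / `evaluate` /
`simulate` subcommands for shell use.

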