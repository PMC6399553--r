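# preopssi

Preoperative surgical site infection (SSI) risk modelling from temporal
blood-test data.

Surgical site infections are the most common nosocomial complication of
gastrointestinal surgery. Long before the operation, the EHR already
contains two kinds of predictive signal: the *values* of routine blood
tests (an elevated CRP points to ongoing inflammation) and the *testing
pattern* itself (a clinician who suspects trouble orders more tests).
This package turns irregular preoperative laboratory time series into
windowed temporal features that capture both, and fits sparse,
cost-aware penalized logistic regressions on them. It is written for
biostatisticians and clinical-informatics researchers who want a tested,
reproducible reference implementation of the whole pipeline — including a
seeded synthetic EHR cohort generator, since real hospital cohorts of
this kind cannot be shared.

## The model

Measurements are aggregated to a patient × test × day grid over the
observation interval (60, 30, or 15 days before surgery; day 0 = day of
surgery), imputed (LOCF, within-test KNN, or a hybrid), and abstracted
per test into short/medium/long windows (defaults S = [2, 0],
M = [15, 3], L = [60, 16] days before surgery). Each test × window yields
six features — mean, slope (toward surgery), number and proportion of
performed tests (pre-imputation), and proportions of high/low abnormal
values — 252 features from 14 tests, plus age and sex.

The classifier is the L1-penalized logistic regression

$$\min_{\beta_0,\beta}\ \frac1N\sum_{i=1}^N -\,l\big(y_i,\ \beta_0+\beta^Tx_i\big)\ +\ \lambda\sum_{j=1}^p v_j\,|\beta_j|,$$

with per-feature penalty factors $v_j = r_{\max}/r_j$ derived from
blood-test prices $r_j$ (NOK), and an early-stopping cap `p_max` that
truncates the $\lambda$ path before the first value selecting more than
`p_max` features — so the returned model never exceeds the cap. Models
are evaluated by stratified repeated 80/20 holdout (AUC, AUPRC,
threshold, sensitivity, specificity, PPV, NPV, with 95% t-intervals),
with per-feature selection frequencies and a provisional blood-test cost
account. An exhaustive window-partition search
(`best_partitioning()`) replaces manual window selection by maximizing a
product of per-window case/control contrast distances over all
$\binom{n}{k}$ cut-day selections.

## Worked example

```r
library(preopssi)

catalog <- default_catalog()   # 14 tests, prices, reference ranges, rates
cohort  <- generate_cohort(cohort_spec(300, prevalence = 0.2, seed = 42),
                           catalog)
table(cohort$patients$ssi)
#>   0   1
#> 240  60

grid <- aggregate_daily(cohort$labs, obs_days = 60,
                        cohort$patients$patient_id, catalog$test_name)
grid <- impute_hybrid(grid, k = 5, catalog)   # grid is ~93% missing
X <- build_feature_matrix(grid, window_spec(60), catalog,
                          cohort$patients, feature_set = "FLM")
dim(X)
#> [1] 300 254                                 # 252 features + age + sex

y   <- cohort$patients$ssi
res <- repeated_holdout(X, y,
                        experiment_spec(n_repeats = 10, p_max = 20,
                                        price_penalty = TRUE, seed = 1),
                        catalog = catalog, labs = cohort$labs)
round(res$summary[c("auc", "auprc", "sens", "spec", "n_selected"), ], 3)
#>              mean     lo     hi
#> auc         0.980  0.972  0.988
#> auprc       0.943  0.919  0.968
#> sens        0.875  0.833  0.917
#> spec        0.952  0.930  0.974
#> n_selected 14.100 11.544 16.656

head(res$selection, 5)
#>                     feature n_selected modal_sign
#> 1    Hemoglobin_nmbr_test_M         10          +
#> 2    Leukocytes_nmbr_test_M         10          +
#> 3 Leukocytes_low_abn_prop_M         10          +
#> 4        Sodium_nmbr_test_M         10          +
#> 5       CRP_high_abn_prop_M         10          +

res$cost_total
#> [1] 1088388                                 # NOK billed over all repeats
```

The price-penalized model (`price_penalty = TRUE`) with `p_max = 20`
keeps at most 20 features per repeat; the selection table shows the
generator's planted signals — medium-window testing intensity for the
designated tests and elevated medium-window CRP — selected in every
repeat with positive coefficients. Each repeat bills every recorded
measurement of every selected test for its validation patients at
catalog prices.

## The analysis workflow

The numbered drivers under `analysis/` run the full study on a synthetic
development cohort (909 patients, 183 cases) and write tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the 909- and 228-patient cohorts, checks rates and missingness |
| `02_preprocess_features.R` | daily grid, hybrid imputation, CRP/BLM/FLM matrices (5/128/254 columns) |
| `03_fit_models.R` | penalty factors, lasso path, single fits with and without price penalties and `p_max` |
| `04_evaluate_variants.R` | repeated-holdout battery (CRP, BLM, FLM, PPM ± caps), selection table, FLM-vs-PPM cost comparison |
| `05_window_search.R` | exhaustive window-partition search over the 34,220 candidate 3-partitionings |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`. The methods vignette
(`vignettes/preoperative-ssi-modelling.Rmd`) documents the model, the
generator's assumptions, and every numerical convention.

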