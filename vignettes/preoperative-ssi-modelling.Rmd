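---
title: "Preoperative SSI risk modelling from temporal blood-test data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preoperative SSI risk modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Surgical site infection (SSI) is among the most common nosocomial
complications of gastrointestinal surgery. Preoperative blood tests —
routinely ordered, cheap, and recorded in the EHR — carry two kinds of
signal about a patient's infection risk: the *values* themselves (an
elevated C-reactive protein points to an ongoing inflammatory process) and
the *testing pattern* (a clinician who suspects something orders more
tests). This package implements a pipeline that abstracts both kinds of
signal from irregular preoperative laboratory time series and feeds them
to a sparse, cost-aware penalized logistic regression.

The pipeline has five stages, each exposed as package functions:

1. **Cohort** (`generate_cohort()` or CSV input): long-format lab
   measurements, demographics, binary SSI labels.
2. **Daily grid** (`aggregate_daily()`): patient × test × day values over
   the observation interval (60, 30, or 15 days before surgery; day 0 is
   the day of surgery), same-day replicates averaged. An immutable
   observed mask records pre-imputation occupancy.
3. **Imputation** (`impute_locf()`, `impute_knn()`, `impute_hybrid()`).
4. **Windowed features** (`window_spec()`, `build_feature_matrix()`):
   short/medium/long windows per test, six feature families.
5. **Model and evaluation** (`fit_lasso_path()`, `select_lambda_cv()`,
   `repeated_holdout()`): L1-penalized logistic regression with
   price-derived penalty factors, a feature-count cap, stratified
   repeated-holdout metrics, and blood-test cost accounting.

A sixth component, `best_partitioning()`, replaces manual window selection
with an exhaustive search.

# The model

The classifier minimizes the penalized negative Bernoulli log-likelihood

$$
\min_{\beta_0, \beta}\; \frac{1}{N}\sum_{i=1}^{N}
  -\,l\!\left(y_i,\; \beta_0 + \beta^{T} x_i\right)
  \;+\; \lambda \sum_{j=1}^{p} v_j\,|\beta_j| ,
$$

fit by coordinate descent over a decreasing grid of 100 \(\lambda\)
values from \(\lambda_{\max}\) (the smallest \(\lambda\) with all
penalized coefficients zero) down to \(10^{-3}\lambda_{\max}\), with warm
starts (glmnet). Features are standardized inside the solver and
coefficients reported on the original scale. Elastic-net mixing and
nonlinear learners are deliberately out of scope: the point of the
pipeline is an interpretable sparse linear model.

## Penalty factors from prices

With price penalization on, every feature derived from blood test \(j\)
carries the factor \(v_j = r_{\max} / r_j\), where \(r_j\) is the test's
price in NOK and \(r_{\max}\) the price of the most expensive test
(leukocytes and thrombocytes, 58 NOK; glucose is cheapest at 23 NOK, so
its features carry the largest factor \(58/23 \approx 2.52\)).
Demographics (age, sex) always have \(v = 1\).

A note on direction: under this formula the *expensive* tests are the
least penalized, so selection concentrates on fewer distinct tests rather
than drifting to individually cheap ones. Because the provisional cost of
a model bills every recorded measurement of every *selected test*, cost
reduction comes from selecting fewer tests — which this convention,
combined with the `p_max` cap, achieves. The opposite convention
(\(v_j = r_j/r_{\max}\), cheap tests preferred) is a one-line change via a
custom `penalty_spec`; we implement the ratio as stated above and treat it
as the package's convention. Only the products \(\lambda v_j\) are
identified, so the solver normalizes the factors to mean one and reports
\(\lambda\) on that scale.

## The p_max early-stopping rule

`select_lambda_cv()` tunes \(\lambda\) by stratified 10-fold
cross-validation scored by AUC (deviance available). The cap acts on the
path, not on the CV winner post hoc: candidate \(\lambda\) values are the
prefix of the decreasing grid *before* the first \(\lambda\) whose
full-data fit selects more than `p_max` features. Counting on the
full-data path (rather than per-fold counts) is what makes the guarantee
hard: the returned model is the full-data fit at the winning \(\lambda\),
so it can never exceed `p_max` nonzero coefficients, for every seed.
Ties in CV AUC go to the largest (most regularized) \(\lambda\) — the
sparser model. `p_max = 0` degenerates to the intercept-only model whose
prediction is the training prevalence. AUC rather than deviance is the
default CV criterion because the models are tuned for maximal AUC
throughout the evaluation harness.

## Class rebalancing

`rose_oversample()` implements smoothed-bootstrap oversampling: rows are
resampled with replacement within class and perturbed by Gaussian noise
with per-feature bandwidth \(h\,\sigma_{jc}\), where
\(h = (4/((p+2)n_c))^{1/(p+4)}\) is a Silverman-type rule per class.
Rebalancing is implemented and exposed but **off by default** in the
pipeline: on imbalanced cohorts of this shape it tends to cost a little
AUC, and the lasso handles the ~20% prevalence without it.

# Temporal windows and features

Default windows partition the observation interval per test:
S = [2, 0] (the dense final days), M = [15, 3], L = [60, 16] (days before
surgery, inclusive; a 30-day interval uses L = [30, 16]; the 15-day
interval has the single window W = [15, 0]). Boundaries are constrained to
the ranges that make clinical sense here (S ends within days 0–2, M
within days 13–18) and are overridable per test. A single documented
default — rather than per-test hand-tuned boundaries — keeps runs
reproducible; `best_partitioning()` exists precisely to replace manual
choices.

Per test and window, the full feature set (FLM) holds six families:

| kind | meaning | source |
|---|---|---|
| `mean` | mean of daily (imputed) values | imputed grid |
| `slope` | OLS slope of value vs. time | imputed grid |
| `nmbr_test` | observed days in window | pre-imputation mask |
| `prop_nmbr_test` | share of the patient's observed days falling in the window | mask |
| `high_abn_prop` | share of observed window values above the reference range | raw values |
| `low_abn_prop` | share below the reference range | raw values |

The slope's time axis runs forward toward surgery (t = −day), so a value
rising toward surgery has a positive slope. Count features are computed
from the immutable pre-imputation mask — imputation can never inflate
them. Abnormal proportions use the *window's* observed count as
denominator and only ever see genuinely observed values; empty windows
yield zeros. This gives 14 × 3 × 6 = 252 test-derived features (84 on the
single-window 15-day interval), plus age and sex.

The basic set (BLM) keeps only value-derived information: `mean`,
`slope`, and the merged `abn_prop` (high + low share) — 126 features, 128
with demographics. Three kinds rather than four is a deliberate
reconciliation: a value-only model with one merged abnormality proportion
is the unique reading consistent with both the 126-feature count and the
naming scheme; the separate counting features are exactly what
distinguishes the FLM. The CRP baseline is `CRP_mean_S/M/L` plus age and
sex — the model a clinician would write down first.

# Imputation

Daily grids here are ~90–98% missing per test, so the imputation scheme
matters mostly through its downstream stability, not through any claim of
recovering truth:

* **LOCF** carries the last earlier value forward within each
  patient-test series; leading gaps (no earlier observation) are filled
  with the per-test cohort mean — a finite, neutral fill that the
  regression needs. A test with no observations cohort-wide falls back to
  the reference-range midpoint with a warning.
* **KNN** (k = 5 by default) fills each missing cell with the mean of the
  cell's value among the k nearest patients, where nearness is the mean
  absolute difference over the pair's jointly observed days *of the same
  test*, after per-test standardization. Restricting to within-test
  neighbours keeps the distance on one scale and avoids inventing
  cross-test structure the data cannot support at this missingness.
  Fewer than k candidates: use all; none: per-test cohort mean.
* **Hybrid** (pipeline default) carries each series' earliest available
  observation back to the farthest day (day 60) — patient history at the
  interval edge — and uses KNN elsewhere.

Imputation never alters observed cells or the mask; LOCF is idempotent.

# The synthetic cohort generator

The original hospital cohort is not available, so `generate_cohort()`
draws cohorts with the statistical structure the analysis assumes:

* **Labels**: exactly `round(n × prevalence)` cases (default prevalence
  20.13%, the development-cohort rate; 909 and 228 patients reproduce the
  published 183 and 50 case counts).
* **Sampling process**: per patient and test, an independent per-day
  Poisson process with piecewise-constant intensity, per-day weights
  3 : 1.5 : 1 over S/M/L, normalized so the expected count over the most
  recent 30 days equals the test's published mean (`rate30`, hemoglobin
  5.37 down to ALP 1.04). This reproduces the observed concentration of
  testing near surgery without inventing an unstated mechanism, and gives
  ~90–97% daily missingness. A measurement gains a same-day duplicate
  with probability 0.05 so the daily-mean aggregation path is exercised.
* **Values**: Gaussian around the reference-range midpoint with SD set so
  ~10% of control values fall outside the range.
* **Planted case effects** (defaults chosen once, as plausible clinical
  magnitudes): cases' CRP values in the M window are shifted up by 1
  within-test SD (an elevated but not extreme CRP); cases' sampling
  intensity for leukocytes, sodium, hemoglobin, and thrombocytes is
  doubled in the M window (the "physician suspicion" signal); cases'
  values in the M window fall outside the reference range with
  probability 0.25 instead of 0.10. Effects are concentrated in the
  medium window because that is where the published selection-frequency
  structure localizes the stable predictors (mid-term inflammation and
  testing intensity, rather than the final pre-surgery days).
* Age is uniform 40–85 years (the colorectal-surgery demographic) and sex
  0/1, both label-independent by default. `neutral_effects()` switches
  every effect off, giving a null cohort on which any classifier should
  score AUC ≈ 0.5.

What the generator does *not* emulate: between-test correlation,
physiological autocorrelation within a series, label-dependent
demographics, informative absence beyond the planted rate boost, and
heavy-tailed analyte distributions (a real CRP is strongly right-skewed).
Passing tests on these cohorts therefore demonstrate that the pipeline
recovers the signal structure it targets — not that it would achieve any
particular AUC on real hospital data.

# Evaluation harness

`repeated_holdout()` repeats stratified 80/20 splits (validation size
exactly `floor(0.2 n)`; 100 repeats on 909 patients yields the 18,100
validation-patient evaluations that the cost simulation bills), fits on
the training side, picks the classification threshold there (Youden's J,
ties to the lowest threshold, midpoints of score gaps as candidates), and
scores the validation side: ROC AUC (Mann–Whitney, ties ½), PR AUC (step
curve; prevalence under constant scores), sensitivity, specificity, PPV,
NPV, and the selected-feature count. Aggregates are means with 95%
t-intervals over repeats — the simplest interval consistent with
repeat-level resampling. Selection frequencies and modal coefficient
signs are tallied across repeats; stable features are those selected in
nearly every repeat with a consistent sign.

Costs are the most conservative reading of provisional billing: for each
validation patient of each repeat, every recorded measurement (in the
observation interval) of every test appearing in that repeat's
selected-feature set is billed at the catalog price. Unpublished prices
default to a linear ramp between the known extremes (23–58 NOK) in
catalog order, overridable via JSON.

# Automatic window search

`group_curves()` computes per-day group means (cases vs. controls) with
normal-approximation 95% half-widths, linearly interpolated across empty
days. The default day-wise distance is the absolute group gap divided by
the combined CI half-width (\(\sqrt{hw_1^2 + hw_0^2}\), plus
\(\varepsilon = 10^{-9}\) against degenerate zero-width intervals); a
window's distance is the mean over its days, and a partitioning's score
is the product of its windows' distances (sum available). For each
\(k \le k_{\max}\), `best_partitioning()` scores every candidate and then
takes the best \(k\); ties prefer smaller \(k\), then the
lexicographically earliest cut selection, so null data returns
deterministically.

Candidates are enumerated as unordered selections of \(k\) cut days from
the \(n\)-day window — \(\binom{n}{k}\) candidates, which for \(n = 60,
k = 3\) is 34,220. A selection of sorted cuts \(c_1 < \dots < c_k\) maps
to contiguous windows half-open on the older side: \([c_1-1, 0]\),
\([c_i-1, c_{i-1}]\), and an oldest window that always extends to the
interval edge. Under this mapping the final cut is absorbed, so distinct
selections can map to the same day partition; the enumeration convention
(rather than the \(\binom{n-1}{k-1}\) count of exact contiguous
compositions) is retained because it defines the search space this
pipeline advertises, and the tie rule makes the search result
well-defined regardless.

# Numerical choices and degenerate inputs

* Coordinate-descent tolerance 1e-9; solutions satisfy the KKT conditions
  to ~1e-5 on the standardized-score scale (tested).
* Penalty factors are normalized to mean 1 inside the solver; the
  penalty-rescaling identity (a factor-\(v\) fit equals a unit-penalty
  fit on columns \(x_j/v_j\) with coefficients rescaled) holds exactly
  and is tested to 1e-6.
* Splits and CV folds are stratified; a split that loses a class is
  redrawn (logged). All randomness flows from a single seed per run.
* Zero denominators return 0 with a flag (classification metrics), 0
  (count/abnormal proportions on empty windows), or documented fallbacks
  (imputation).
* Single-day windows have slope 0; constant scores give AUC 0.5 and
  PR AUC equal to prevalence.

# Problem sizes used by the test suite

The suite exercises the full advertised widths at reduced depths chosen
as the package's own verification sizes: solver checks on a 500-patient
cohort with all 252 FLM features; the evaluation bookkeeping on 909
patients with 100 repeats (CRP baseline); signal recovery on 1,000
patients with 50 repeats across the CRP/BLM/FLM ladder; enumeration
cross-checks exhaustively for all \(n \le 20\). The analysis scripts
under `analysis/` run the same pipeline at 25 evaluation repeats per
variant; `n_repeats` is a single knob away from the full 100.

# Known limitations

* The generator's independence assumptions (above) make the synthetic
  task easier than real EHR data in some respects (no confounded
  correlations to untangle) and harder in others (no cross-test
  redundancy to exploit).
* KNN imputation is within-test only and O(P²·D) per test; the Rcpp
  kernel keeps cohorts of a few thousand patients comfortable, but very
  large cohorts would want a different neighbour search.
* The cost model bills recorded measurements of selected tests; it does
  not model the counterfactual ordering behaviour of clinicians under a
  deployed model.
* The exhaustive partition search is \(\binom{n}{k}\) per test and k; it
  is meant for \(k \le 4\) on a 60-day window, not as a general
  changepoint method.
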