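---
title: "Quantifying the information content of variable assemblages in survival prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the information content of variable assemblages in survival prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survshuffle)
library(dplyr)
```

## The problem

A recurring pattern in clinical proteogenomics: adding a panel of molecular
measurements to established clinicopathological predictors raises the
apparent discrimination of a prognostic model, yet the gain evaporates on
new patients. The apparent concordance index of a Cox model is an
optimistic statistic — with enough predictors it rises even when every
predictor is pure noise — so "the combined model has a higher c-index" is
not, by itself, evidence that the molecular data carry prognostic
information.

survshuffle implements a Monte Carlo answer to the question *"how much
information does this group of variables actually contribute?"*. The unit
of analysis is a **data assemblage**: a named group of predictors (all
proteomic AQUA intensities, say, or all clinicopathological inputs).

## The shuffling test

Let $S(D)$ be a scalar performance statistic computed on dataset $D$ — by
default Harrell's c-index of a Cox proportional hazards model refit on
$D$. For the targeted variables we form $N$ randomised datasets
$D^{(1)}, \dots, D^{(N)}$, where in each $D^{(b)}$ **every targeted
variable is permuted across patients by its own independent permutation**.
This breaks both the variable–outcome correspondence and the correspondence
*among* the targeted variables, while leaving non-targeted variables and
the outcome untouched. The one-tailed empirical p-value is

$$ p \;=\; \frac{\#\{b : S(D^{(b)}) \ge S(D)\}}{N}, $$

ties counting toward the numerator because the c-index is directional. A
high p-value says the real data discriminate prognoses no better than
randomly reassigned values — the assemblage has low information content —
regardless of how high the apparent c-index is. The default is
$N = 10{,}000$; when no permutation reaches the observed statistic the
plain proportion is zero and is reported as $P < 1/N$ (e.g. $P < 0.0001$).
Because the plain proportion can be exactly zero, the add-one variant
$(\#\{\cdot\} + 1)/(N + 1)$ is always computed alongside; it is the
quantity whose null distribution is exactly super-uniform, and it is what
the calibration tests assess.

Two variants matter in practice:

* **Whole-assemblage test** (`mc_test()` with all of a group's variables
  targeted): is there any prognostic information in this group at all?
* **Added-value test** (`added_value_test()`): fit the *combined* model but
  shuffle only the candidate group. The retained group keeps its real
  alignment with outcome, so the p-value measures the candidate group's
  contribution *in the context of* the retained variables. A group that is
  uninformative alone can still show added value here, and vice versa.

### Relation to outcome permutation

Classical permutation tests shuffle the outcome against the predictor
block, preserving all inter-predictor correlation. For a refit Cox model
the apparent-c-index null depends on the predictors only through the
column space of the design, so the two schemes coincide for continuous
predictors in general position; they separate exactly when breaking
inter-variable correspondence changes the effective rank. With redundant
predictors (e.g. duplicated or strongly collinear columns) per-variable
shuffling restores full rank and therefore a *higher* overfitting null
than outcome permutation — the test suite demonstrates this on a
constructed example. More importantly, outcome permutation cannot express
the added-value question at all, because it cannot destroy one group's
alignment while preserving another's.

### The evaluator contract

`mc_test()` accepts any deterministic function `patient_table -> scalar`,
so the machinery applies to any analysis with a scalar performance
measure. `cox_cindex_evaluator()` builds the shipped family: apparent
c-index; optimism-corrected c-index (`cv_correct = TRUE`); and either mode
combined with LASSO selection. Evaluator failures on shuffled data
(non-convergence) are excluded from the null with their count reported —
retrying would bias the null toward convergent configurations — and more
than 5% failures aborts the test.

## The component models

**Cox regression.** `fit_cox()` maximises the Breslow partial
log-likelihood
$$ \ell(\beta) = \sum_{t} \Big( \sum_{i \in D_t} \eta_i - |D_t| \log
   \sum_{j \in R_t} e^{\eta_j} \Big), \qquad \eta = X\beta, $$
with Newton–Raphson (the `survival` engine, `ties = "breslow"` — tie
handling is deliberately bit-specified because tied follow-up days are
common in registry data). Standard errors come from the inverse observed
information. Degenerate columns (constant, or a declared category level
absent from the data) are reported and excluded from inference rather than
silently dropped; monotone likelihood (a predictor that perfectly orders
the events) is detected either by the engine's infinite-coefficient
diagnostic, by an NA coefficient on a full-rank design, or by the
divergence bound $|\beta_j| > 20$, and raised as an error naming the
column. Proportional hazards are checked by `schoenfeld_test()`:
Schoenfeld residuals correlated against the rank of event time (the rank
transform is a deliberate choice; the diagnostic is a numeric p-value, not
a plot).

**Concordance.** `cindex()` uses direct pair enumeration under Harrell's
original comparability rules: the earlier patient of a comparable pair
must have had the event; censored–censored pairs and tied event times with
two events are incomparable; a tied time with exactly one event counts the
event patient as earlier; tied risk scores contribute one half. At
cohort sizes of a few hundred patients the $O(n^2)$ enumeration costs
milliseconds, and the pair index depends only on the outcome, which is
fixed across the permutations of a run, so it is memoised.

**Feature selection.** `lasso_cox_path()` maximises
$\ell(\beta) - \lambda \sum_j |\beta_j^{std}|$, with coefficients
standardised internally (mean 0, variance 1, $1/n$ denominator) so the
penalty is scale-fair across AQUA intensities on a 0–255 scale and 0/1
indicator columns; each indicator of a categorical variable is penalised
separately. The solver is a proximal Newton iteration: the exact local
quadratic model of the partial likelihood is re-formed at each step and
the penalised subproblem solved by soft-thresholded cyclic coordinate
descent (a small compiled kernel), with step-halving on the true penalised
objective and a Karush–Kuhn–Tucker optimality check as the convergence
criterion. `select_features()` chooses $\lambda$ over 100 log-spaced values
in $(0.001, 50)$ by 10-fold cross-validated likelihood in the verification
form $\ell_{\text{all}}(\hat\beta_{-k}) - \ell_{\text{train}}(\hat\beta_{-k})$.
The selected features are then refit *unpenalised* — selection-then-refit,
not penalised prediction — which is how the downstream models use them.

**Cross-validation.** `cross_validate()` runs repeated k-fold CV
(defaults: 10 folds, 100 repeats) with seeded shuffled partitions,
redrawing a partition (up to 10 times) if a fold holds no events. It
reports the mean held-out c-index ("average performance in
cross-validation") and an optimism-corrected c-index. One wording of
optimism — full-data apparent minus held-out — would make the corrected
value collapse to the mean CV c-index; we instead use the resampling
convention of `rms::validate`: per fold, optimism is the fold-trained
model's c-index on its own training patients minus on the held-out
patients, and corrected = apparent − mean optimism. A two-sided one-sample
t-test of the per-fold optimism values against zero (α = 0.05) backs the
overfitting flag; the test behind "significant differences in
cross-validation" is not uniquely determined by the workflow this package
mirrors, and this is our stand-in.

**Selection inside resampling.** Two leakage policies exist and both are
implemented. In cross-validation the default re-runs selection inside
every training split (`selection = "per-fold"`), which is the honest
generalisation estimate; `"fixed"` cross-validates the once-selected
model. In the Monte Carlo test the default fixes the features selected on
the unshuffled data and shuffles their values — matching the workflow the
package reproduces — while `cox_cindex_evaluator(select = TRUE)` re-runs
selection on every shuffled dataset for a more conservative null.

## The synthetic cohort generator

`simulate_cohort()` exists so every claim above is testable without any
patient data. Its default schema mirrors an epithelial ovarian cancer
cohort: 339 patients; age in days (plus the derived over/under-50
stratum), histopathology (6 levels, papillary serous the reference and the
majority), FIGO stage (4 levels, stage 3 most frequent), chemotherapy
regimen (platinum vs platinum + taxane); and 20 proteomic
immunofluorescence intensities on the AQUA 0–255 scale (13 nuclear-only
targets, 3 cytoplasm-only EMT markers, ERβ1/ERβ2 in both compartments),
drawn as truncated Gaussians (mean 100, sd 40) with an optional Gaussian
copula for inter-marker correlation.

Event times follow a Weibull proportional hazards model by inverse
transform, $T = s\,(-\log U)^{1/k} e^{-\eta/k}$, with shape $k = 1.2$
(rising hazard, as for recurrence after primary therapy) and scale tuned
so the median progression-free time at $\eta = 0$ is about 540 days — a
plausible magnitude, not an estimate of any cohort. Censoring is
independent of covariates; its Weibull scale is calibrated on the realised
draws so the censored fraction hits the target (default 30%) to within
one patient, and generation errors out if a target is infeasible beyond
±0.05. An overall-survival outcome adds a positive Weibull gap to each
progression time and shares its follow-up cutoff, so observed OS ≥
observed PFS by construction. With a fixed seed the generator is
bit-reproducible.

What the generator deliberately does **not** emulate: the real cohort's
marker correlations, non-Gaussian AQUA distributions, informative
censoring, missing values, or any violation of proportional hazards.
Passing calibration tests on these synthetic cohorts therefore shows the
*procedure* is correct and calibrated under its own assumptions; it does
not certify behaviour under model misspecification.

## Numerical choices and reproducibility

* Cox convergence: relative log-likelihood change $10^{-10}$, iteration
  cap 50; non-convergence is carried in the `converged` flag, and inside
  Monte Carlo runs surfaces as an excluded evaluation.
* LASSO: KKT tolerance $10^{-7}$ (absolute, on the standardised-scale
  gradient), divergence guard $|\beta^{std}| > 30$, warm starts along the
  decreasing grid; non-converged grid points are flagged and excluded.
* Degenerate categorical levels encode as all-zero columns and are
  reported, not dropped, so design column counts stay schema-determined.
* Seeds: every permutation draw uses a child seed derived from
  (master seed, draw index, variable index), so results are independent of
  evaluation order and two runs with the same configuration produce
  byte-identical JSON reports. Fold assignments take their own derived
  seeds. All derived seeds stay inside the 32-bit range.
* p-value bookkeeping: ties count toward rejection ("equal to or above");
  the plain proportion and the add-one variant are both stored.

Test-suite problem sizes are chosen to make each statistical claim
checkable in minutes on a single core: calibration uses N = 199
permutations with 500 outer replicates (the add-one p-value is exactly
5%-quantised there), power runs use n = 300, overfitting runs p = 40
noise covariates at n = 100, and recovery runs n = 2,000. The method
itself defaults to the full N = 10,000.

## A worked example

```{r example, eval = FALSE}
sch <- dplyr::bind_rows(
  noise_schema(3, group = "clinicopathological", prefix = "clin"),
  noise_schema(4, group = "proteomic", prefix = "prot"))
pt <- simulate_cohort(n = 150, schema = sch,
                      true_beta = c(clin1 = 1.2, clin2 = -0.6),
                      censoring_rate = 0.3, seed = 1)

res <- run_workflow(pt, n_permutations = 1000, folds = 10, repeats = 10,
                    selection = TRUE, seed = 1)
res
```

The printed summary gives, for each of the six analyses (three models,
with and without selection), the apparent and corrected c-index and the
Monte Carlo p-value — the same four-way comparison a practitioner would
make: a high apparent c-index with a non-significant shuffle p-value is
the signature of overfitting, and a significant added-value p-value for
the molecular group in the combined model is the signature of genuine
added information.

## Known limitations

* The evaluator must be deterministic given its configuration; stochastic
  learners need an internal fixed seed.
* Harrell's c-index only; no time-dependent AUC, Uno's c, or IPCW
  weighting.
* No stratified Cox, time-varying covariates, frailty terms, missing-data
  handling, or bootstrap validation.
* Monte Carlo p-values below 1/N are not resolvable; choose N for the
  resolution you need.
* The added-value p-value is conditional on the retained variables being
  modelled correctly; it does not correct a misspecified base model.
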