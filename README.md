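# survshuffle

Per-variable shuffling Monte Carlo tests of the **information content** of
variable assemblages in right-censored survival prognosis.

## The problem

In clinical proteogenomics, adding a block of molecular measurements (e.g.
AQUA immunofluorescence intensities) to established clinicopathological
predictors routinely raises the apparent concordance of a Cox model. The
apparent c-index is an optimistic statistic, though: it also rises when the
added block is pure noise. survshuffle answers the question behind the
comparison — *does this group of variables actually carry prognostic
information, alone or on top of what we already have?*

## The method

For a dataset $D$ and a scalar performance statistic $S$ (by default
Harrell's c-index of a Breslow-tie Cox proportional hazards model refit on
the dataset), form $N$ randomised datasets $D^{(b)}$ in which **each
targeted variable is permuted across patients by its own independent
permutation** — destroying both variable–outcome and variable–variable
correspondence, unlike classical outcome-only permutation. The one-tailed
empirical p-value is

$$p = \frac{\#\{b:\, S(D^{(b)}) \ge S(D)\}}{N},$$

with ties counting toward the numerator; $p = 0$ is reported as $P < 1/N$,
and the add-one variant $(\#+1)/(N+1)$ is computed alongside. A large $p$
means the assemblage discriminates prognoses no better than randomly
reassigned values — low information content — however high the apparent
c-index. Shuffling a *subset* (the added group inside a combined model)
yields the **added-value test**: the contribution of that group in the
context of the retained variables.

Around the core test the package provides the supporting workflow:
L1-penalised Cox feature selection with the sparsity parameter chosen by
10-fold cross-validated likelihood over $0.001 < \lambda < 50$ (selection
then unpenalised refit), repeated 10-fold cross-validation with an
optimism-corrected c-index for overfitting diagnosis, Schoenfeld-residual
proportional-hazards checks, and a synthetic cohort generator with known
Weibull proportional-hazards ground truth (339 patients, 5
clinicopathological + 20 proteomic variables by default).

## Worked example

```r
library(survshuffle)

sch <- dplyr::bind_rows(
  noise_schema(3, group = "clinicopathological", prefix = "clin"),
  noise_schema(4, group = "proteomic", prefix = "prot"))
pt <- simulate_cohort(n = 150, schema = sch,
                      true_beta = c(clin1 = 1.2, clin2 = -0.6),
                      censoring_rate = 0.3, seed = 1)

res <- run_workflow(pt, n_permutations = 1000, folds = 10, repeats = 10,
                    selection = FALSE, seed = 1)
res
```

```
<workflow_result> seed 1 on 150 patients
  added_alone                      c-index 0.542 (corrected 0.492)  P = 0.657
  base_alone                       c-index 0.796 (corrected 0.797)  P < 0.001
  combined_added_shuffled          c-index 0.796 (corrected 0.784)  P = 0.833
```

Reading the three lines: the pure-noise proteomic group alone reaches an
apparent c-index of 0.54 but shuffling it reproduces that easily
(P = 0.657, no information); the clinicopathological group's c-index of
0.80 survives shuffling (P < 0.001, high information content); and
shuffling only the proteomic block inside the combined model leaves the
c-index distribution covering the observed value (P = 0.833) — the
proteomic data add no value in context.

Individual pieces are available as
`mc_test()`, `added_value_test()`, `fit_cox()`, `cindex()`,
`select_features()`, `cross_validate()` and `simulate_cohort()`, all
returning tidy-friendly objects with `tidy()`/`glance()`/`autoplot()`
methods. A command-line front end with `simulate` / `fit` / `mc` /
`added-value` / `crossval` / `workflow` / `calibrate` subcommands lives at
`inst/cli/survshuffle.R`.

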