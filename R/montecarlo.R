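# Per-variable shuffling Monte Carlo test of assemblage information content.
#
# Each targeted variable is permuted across patients independently of every
# other variable and of the outcome, so both variable-outcome and
# variable-variable correspondence is destroyed; non-targeted variables keep
# their patient alignment. This differs from outcome-only permutation,
# which preserves the correlation structure among predictors.

# deterministic child seed from (master seed, draw index, variable index);
# keeps every derived seed inside the 32-bit integer range
derive_seed <- function(seed, draw, var) {
  m <- 2147483647
  s <- ((seed %% m) * 69069 + draw * 40503 + var * 9176 + 1) %% m
  as.integer(s)
}

#' Describe a shuffling plan
#'
#' @param target_variables Variables whose values will be permuted
#'   (non-empty).
#' @param n_permutations Number of randomised datasets N (default 10000).
#' @param seed Master seed; per-draw, per-variable child seeds are derived
#'   from it so results do not depend on evaluation order.
#' @return A `shuffle_plan`.
#' @export
shuffle_plan <- function(target_variables, n_permutations = 10000,
                         seed = 1) {
  stopifnot(length(target_variables) >= 1, n_permutations >= 1)
  structure(list(
    target_variables = as.character(target_variables),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)
  ), class = "shuffle_plan")
}

#' Shuffle the targeted variables of a patient table
#'
#' Applies one independent seeded permutation per targeted variable to the
#' raw (pre-encoding) values, leaving outcomes and non-targeted variables
#' untouched. Each shuffled column is a permutation (multiset-equal) of the
#' original; shuffling before encoding keeps the indicator columns of a
#' categorical variable coherent.
#'
#' @param table A `patient_table`.
#' @param plan A [shuffle_plan()].
#' @param draw_index Which randomised dataset to produce (1..N); the same
#'   `(plan, draw_index)` always yields the same table.
#' @return A `patient_table` with shuffled target columns.
#' @export
shuffle_table <- function(table, plan, draw_index) {
  stopifnot(inherits(table, "patient_table"), inherits(plan, "shuffle_plan"))
  unknown <- setdiff(plan$target_variables, table$schema$name)
  if (length(unknown)) {
    stop("plan targets unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- n_patients(table)
  var_idx <- match(plan$target_variables, table$schema$name)
  dat <- unclass(table$data)            # plain list: cheap column swaps
  for (i in seq_along(var_idx)) {
    nm <- plan$target_variables[i]
    set.seed(derive_seed(plan$seed, draw_index, var_idx[i]))
    dat[[nm]] <- dat[[nm]][sample.int(n)]
  }
  table$data <- tibble::new_tibble(dat, nrow = n)
  table
}

#' Cox / c-index model evaluators
#'
#' Builds an evaluator — a deterministic function mapping a `patient_table`
#' to a scalar performance statistic — for use with [mc_test()]. The shipped
#' statistic is Harrell's c-index of a Breslow-tie Cox model, optionally
#' with LASSO feature selection re-run on each table it sees
#' (`select = TRUE`; for the fixed-features workflow, run
#' [select_features()] once and pass its `selected_variables` as
#' `variables`), and optionally cross-validation-corrected
#' (`cv_correct = TRUE`).
#'
#' @param variables Variables entering the model (`NULL` = all).
#' @param select Re-run feature selection on every table evaluated.
#' @param selection_args Arguments forwarded to [select_features()].
#' @param cv_correct Return the optimism-corrected c-index from
#'   [cross_validate()] instead of the apparent one.
#' @param cv_args Arguments forwarded to [cross_validate()] (e.g. `folds`,
#'   `repeats`).
#' @param seed Seed for the evaluator's internal fold assignments (fixed
#'   configuration, reused for every table).
#' @return A function `patient_table -> scalar`, carrying a
#'   `statistic_name` attribute.
#' @export
cox_cindex_evaluator <- function(variables = NULL, select = FALSE,
                                 selection_args = list(),
                                 cv_correct = FALSE, cv_args = list(),
                                 seed = 1) {
  force(variables); force(select); force(selection_args)
  force(cv_correct); force(cv_args); force(seed)
  f <- function(table) {
    vars <- variables %||% table$schema$name
    if (select) {
      sel <- do.call(select_features, c(
        list(table = table, variables = vars, seed = seed), selection_args))
      vars <- sel$selected_variables
      if (!length(vars)) return(0.5)
    }
    if (cv_correct) {
      cv <- do.call(cross_validate, c(
        list(table = table, variables = vars, seed = seed,
             selection = "none"), cv_args))
      cv$corrected_cindex
    } else {
      fit <- fit_cox(table, variables = vars)
      cindex(risk_scores(fit), table$time, table$event)$cindex
    }
  }
  nm <- paste0(if (cv_correct) "corrected " else "", "c-index",
               if (select) " (LASSO-selected)" else "")
  structure(f, statistic_name = nm)
}

#' Monte Carlo information-content test
#'
#' Evaluates the model on the actual table, then on `N` randomised tables
#' in which every targeted variable has been independently shuffled, and
#' returns the one-tailed empirical p-value: the proportion of randomised
#' datasets whose statistic is equal to or above the observed one. A large
#' p-value means the actual assemblage discriminates prognoses little
#' better than randomly reassigned values — low information content.
#'
#' Evaluator failures on shuffled tables (e.g. non-convergence) are
#' excluded and N reduced accordingly; more than 5% failures aborts, since
#' the null distribution would be unreliable.
#'
#' @param table A `patient_table`.
#' @param plan A [shuffle_plan()].
#' @param evaluator A function `patient_table -> scalar`; default
#'   [cox_cindex_evaluator()] over all variables.
#' @return An `mc_result`: `observed_statistic`, `permuted_statistics`,
#'   `pvalue` (plain proportion), `pvalue_plus_one` (add-one variant, never
#'   exactly zero), `n_failed`, `plan`, `statistic_name`.
#' @examples
#' pt <- simulate_cohort(n = 60, seed = 5)
#' mc_test(pt, shuffle_plan(c("stage", "age"), n_permutations = 20,
#'                          seed = 11))
#' @export
mc_test <- function(table, plan, evaluator = cox_cindex_evaluator()) {
  stopifnot(inherits(table, "patient_table"), inherits(plan, "shuffle_plan"))
  observed <- evaluator(table)
  if (!is.finite(observed)) {
    stop("evaluator failed on the unshuffled table", call. = FALSE)
  }
  N <- plan$n_permutations
  stats <- rep(NA_real_, N)
  for (b in seq_len(N)) {
    tab_b <- shuffle_table(table, plan, b)
    stats[b] <- tryCatch(evaluator(tab_b), error = function(e) NA_real_)
  }
  failed <- sum(!is.finite(stats))
  if (failed > 0.05 * N) {
    stop("evaluator failed on ", failed, " of ", N,
         " shuffled datasets (> 5%): null distribution unreliable",
         call. = FALSE)
  }
  perm <- stats[is.finite(stats)]
  n_eff <- length(perm)
  count_ge <- sum(perm >= observed)
  structure(list(
    observed_statistic = observed,
    permuted_statistics = perm,
    pvalue = count_ge / n_eff,
    pvalue_plus_one = (count_ge + 1) / (n_eff + 1),
    n_permutations = n_eff,
    n_failed = failed,
    plan = plan,
    statistic_name = attr(evaluator, "statistic_name") %||% "statistic"
  ), class = "mc_result")
}

#' Added-value test of one variable group within a combined model
#'
#' Runs the Monte Carlo machinery with subset shuffling: the combined model
#' (base + added groups) is evaluated while only the added group's
#' variables are permuted, so the p-value measures the added group's
#' information content in the context of the base group.
#'
#' @param table A `patient_table`.
#' @param base_group,added_group Group labels from the schema.
#' @param n_permutations,seed Passed to [shuffle_plan()] targeting the
#'   added group's variables.
#' @param evaluator Optional evaluator; default is a Cox / c-index
#'   evaluator over the union of the two groups.
#' @return An `mc_result` (see [mc_test()]).
#' @export
added_value_test <- function(table, base_group, added_group,
                             n_permutations = 10000, seed = 1,
                             evaluator = NULL) {
  base_vars <- group_variables(table, base_group)
  added_vars <- group_variables(table, added_group)
  if (!length(base_vars) || !length(added_vars)) {
    stop("both groups must contain variables", call. = FALSE)
  }
  if (is.null(evaluator)) {
    evaluator <- cox_cindex_evaluator(variables = c(base_vars, added_vars))
  }
  plan <- shuffle_plan(added_vars, n_permutations = n_permutations,
                       seed = seed)
  out <- mc_test(table, plan, evaluator)
  out$base_group <- base_group
  out$added_group <- added_group
  out
}

#' Format a Monte Carlo p-value the way permutation studies report it
#'
#' A plain proportion of exactly zero is rendered as `"< 1/N"` (e.g.
#' `"P < 0.0001"` at N = 10000), since no permutation reached the observed
#' statistic.
#'
#' @param result An `mc_result`.
#' @param digits Significant digits.
#' @return A character scalar like `"P = 0.022"` or `"P < 0.0001"`.
#' @export
format_mc_pvalue <- function(result, digits = 3) {
  stopifnot(inherits(result, "mc_result"))
  if (result$pvalue == 0) {
    paste0("P < ", format(1 / result$n_permutations, scientific = FALSE))
  } else {
    paste0("P = ", signif(result$pvalue, digits))
  }
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result> ", x$statistic_name, ": observed ",
      sprintf("%.4f", x$observed_statistic), ", ", x$n_permutations,
      " permutations (", x$n_failed, " failed)\n", sep = "")
  cat("  shuffled: ", paste(x$plan$target_variables, collapse = ", "),
      "\n", sep = "")
  cat("  ", format_mc_pvalue(x), "  (add-one p = ",
      signif(x$pvalue_plus_one, 3), ")\n", sep = "")
  invisible(x)
}

#' @method tidy mc_result
#' @export
tidy.mc_result <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$permuted_statistics),
                 statistic = x$permuted_statistics)
}

#' @method glance mc_result
#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(
    statistic_name = x$statistic_name,
    observed_statistic = x$observed_statistic,
    pvalue = x$pvalue,
    pvalue_plus_one = x$pvalue_plus_one,
    n_permutations = x$n_permutations,
    n_failed = x$n_failed,
    n_targets = length(x$plan$target_variables)
  )
}
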