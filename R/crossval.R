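#' Repeated k-fold cross-validation of the concordance index
#'
#' Partitions patients into folds by a seeded shuffle, fits the Cox model on
#' the training folds, scores the held-out fold and records its c-index;
#' the whole partition is repeated `repeats` times. Reports the apparent
#' (full-data) c-index, the mean cross-validated c-index, and an
#' optimism-corrected c-index: per fold, optimism = (c-index of the
#' fold-trained model on its own training patients) - (on the held-out
#' patients); corrected = apparent - mean optimism. A two-sided one-sample
#' t-test of the per-fold optimism values against zero drives the
#' overfitting flag.
#'
#' @param table A `patient_table`.
#' @param variables Optional variable subset.
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeated partitions (default 100).
#' @param seed Integer seed for the fold shuffles.
#' @param selection `"none"` (default), `"per-fold"` (re-run LASSO selection
#'   inside every training split, avoiding selection leakage) or `"fixed"`
#'   (select once on the full data, then cross-validate that fixed model).
#' @param selection_args List of arguments forwarded to [select_features()]
#'   (e.g. `folds`, `lambda`).
#' @param alpha Significance level for the overfitting flag.
#' @return A `cv_result`: `fold_cindices` tibble (`repeat_id`, `fold`,
#'   `cindex_train`, `cindex_test`), `apparent_cindex`, `mean_cv_cindex`,
#'   `corrected_cindex`, `optimism`, `overfit_flag`, `overfit_pvalue`,
#'   `folds`, `repeats`, `seed`.
#' @examples
#' pt <- simulate_cohort(n = 100, seed = 2)
#' cross_validate(pt, variables = c("stage", "age"), folds = 5,
#'                repeats = 2, seed = 9)
#' @export
cross_validate <- function(table, variables = NULL, folds = 10,
                           repeats = 100, seed = 1,
                           selection = c("none", "per-fold", "fixed"),
                           selection_args = list(), alpha = 0.05) {
  stopifnot(inherits(table, "patient_table"), folds >= 2)
  selection <- match.arg(selection)
  n <- n_patients(table)
  if (folds > n) stop("more folds than patients", call. = FALSE)

  model_vars <- variables %||% table$schema$name
  if (selection == "fixed") {
    sel <- do.call(select_features, c(
      list(table = table, variables = model_vars,
           seed = derive_seed(seed, 0, 1)),
      selection_args))
    model_vars_fixed <- sel$selected_variables
  }

  apparent_vars <- if (selection == "fixed") model_vars_fixed else model_vars
  apparent <- apparent_cindex_for(table, apparent_vars)

  rows <- vector("list", folds * repeats)
  ri <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- event_balanced_folds(table$event, folds,
                                    seed = derive_seed(seed, r, 0))
    for (k in seq_len(folds)) {
      te <- fold_id == k
      tr_tab <- subset_patients(table, which(!te))
      vars_k <- switch(selection,
        "none" = model_vars,
        "fixed" = model_vars_fixed,
        "per-fold" = {
          sel_k <- do.call(select_features, c(
            list(table = tr_tab, variables = model_vars,
                 seed = derive_seed(seed, r, k)),
            selection_args))
          sel_k$selected_variables
        })
      ri <- ri + 1L
      rows[[ri]] <- cv_fold_row(table, tr_tab, which(te), vars_k, r, k)
    }
  }
  fold_tbl <- dplyr::bind_rows(rows)
  optimism <- fold_tbl$cindex_train - fold_tbl$cindex_test
  usable <- is.finite(optimism)
  mean_cv <- mean(fold_tbl$cindex_test[is.finite(fold_tbl$cindex_test)])
  corrected <- if (any(usable)) apparent - mean(optimism[usable]) else NA_real_
  pval <- if (sum(usable) >= 2 && stats::sd(optimism[usable]) > 0) {
    stats::t.test(optimism[usable], mu = 0)$p.value
  } else {
    1
  }
  mean_optimism <- if (any(usable)) mean(optimism[usable]) else NA_real_
  structure(list(
    fold_cindices = fold_tbl,
    apparent_cindex = apparent,
    mean_cv_cindex = mean_cv,
    corrected_cindex = corrected,
    optimism = mean_optimism,
    overfit_flag = isTRUE(pval < alpha && mean_optimism > 0),
    overfit_pvalue = pval,
    folds = folds, repeats = repeats, seed = seed,
    selection = selection
  ), class = "cv_result")
}

apparent_cindex_for <- function(table, vars) {
  if (!length(vars)) return(0.5)
  fit <- fit_cox(table, variables = vars)
  cindex(risk_scores(fit), table$time, table$event)$cindex
}

cv_fold_row <- function(table, tr_tab, te_idx, vars_k, r, k) {
  te_tab <- subset_patients(table, te_idx)
  if (!length(vars_k)) {
    return(tibble::tibble(repeat_id = r, fold = k,
                          cindex_train = 0.5, cindex_test = 0.5,
                          n_features = 0L))
  }
  fit_k <- tryCatch(fit_cox(tr_tab, variables = vars_k),
                    error = function(e) NULL)
  if (is.null(fit_k)) {
    return(tibble::tibble(repeat_id = r, fold = k,
                          cindex_train = NA_real_, cindex_test = NA_real_,
                          n_features = length(vars_k)))
  }
  ctr <- tryCatch(
    cindex(risk_scores(fit_k), tr_tab$time, tr_tab$event)$cindex,
    error = function(e) NA_real_)
  cte <- tryCatch(
    cindex(risk_scores(fit_k, encode(te_tab, vars_k)),
           te_tab$time, te_tab$event)$cindex,
    error = function(e) NA_real_)
  tibble::tibble(repeat_id = r, fold = k, cindex_train = ctr,
                 cindex_test = cte, n_features = length(vars_k))
}

# seeded partition with >= 1 event per fold where feasible (up to 10 redraws)
event_balanced_folds <- function(event, folds, seed) {
  n <- length(event)
  for (try in 0:10) {
    fold_id <- cv_fold_ids(n, folds, seed + try * 7919)
    if (all(tapply(event, fold_id, sum) >= 1)) return(fold_id)
  }
  if (sum(event) < folds) {
    stop("cannot place an event in every fold", call. = FALSE)
  }
  fold_id
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d-fold x %d repeats\n  apparent c-index %.4f | mean CV %.4f | corrected %.4f\n",
    x$folds, x$repeats, x$apparent_cindex, x$mean_cv_cindex,
    x$corrected_cindex))
  cat(sprintf("  optimism %.4f, overfit flag %s (p = %s)\n", x$optimism,
              x$overfit_flag, format.pval(x$overfit_pvalue, digits = 3)))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$fold_cindices

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    apparent_cindex = x$apparent_cindex,
    mean_cv_cindex = x$mean_cv_cindex,
    corrected_cindex = x$corrected_cindex,
    optimism = x$optimism,
    overfit_flag = x$overfit_flag,
    overfit_pvalue = x$overfit_pvalue,
    folds = x$folds, repeats = x$repeats
  )
}
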