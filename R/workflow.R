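#' Run the full two-group information-content workflow
#'
#' Reproduces the study design around the shuffling test on any conforming
#' dataset: for the added-group-alone, base-group-alone and combined
#' models — each without and (optionally) with LASSO feature selection —
#' it computes the apparent and optimism-corrected c-index and a Monte
#' Carlo p-value. Single-group models shuffle all of their variables;
#' the combined model shuffles only the added group, so its p-value is the
#' added value of that group in the context of the base group. With
#' selection, features are selected once on the unshuffled data and held
#' fixed across permutations.
#'
#' @param table A `patient_table`.
#' @param base_group,added_group Assemblage group labels (defaults match
#'   [ovarian_schema()]).
#' @param n_permutations Randomised datasets per Monte Carlo test
#'   (default 10000).
#' @param folds,repeats Cross-validation settings (defaults 10 and 100).
#' @param selection Also run the three analyses with LASSO-selected
#'   features.
#' @param selection_args Arguments forwarded to [select_features()].
#' @param seed Master seed; every internal seed derives from it.
#' @param out Optional JSON report path (written via [write_report()]).
#' @return A `workflow_result`: `config` plus one entry per analysis with
#'   the fitted model summary, `apparent_cindex`, `corrected_cindex` and
#'   the `mc` result.
#' @export
run_workflow <- function(table, base_group = "clinicopathological",
                         added_group = "proteomic",
                         n_permutations = 10000, folds = 10, repeats = 100,
                         selection = TRUE, selection_args = list(),
                         seed = 1, out = NULL) {
  stopifnot(inherits(table, "patient_table"))
  base_vars <- group_variables(table, base_group)
  added_vars <- group_variables(table, added_group)

  specs <- list(
    list(id = "added_alone", vars = added_vars, shuffle = added_vars,
         select = FALSE),
    list(id = "base_alone", vars = base_vars, shuffle = base_vars,
         select = FALSE),
    list(id = "combined_added_shuffled", vars = c(base_vars, added_vars),
         shuffle = added_vars, select = FALSE)
  )
  if (selection) {
    specs <- c(specs, lapply(specs, function(s) {
      s$id <- paste0(s$id, "_selected")
      s$select <- TRUE
      s
    }))
  }

  analyses <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    analyses[[s$id]] <- run_one_analysis(
      table, s, folds = folds, repeats = repeats,
      n_permutations = n_permutations,
      selection_args = selection_args,
      seed_sel = derive_seed(seed, 100 + i, 1),
      seed_cv = derive_seed(seed, 100 + i, 2),
      seed_mc = derive_seed(seed, 100 + i, 3))
  }

  res <- structure(list(
    config = list(
      package_version = as.character(utils::packageVersion("survshuffle")),
      n_patients = n_patients(table),
      n_events = sum(table$event),
      base_group = base_group, added_group = added_group,
      n_permutations = n_permutations, folds = folds, repeats = repeats,
      selection = selection, seed = seed
    ),
    analyses = analyses
  ), class = "workflow_result")
  if (!is.null(out)) write_report(res, out)
  res
}

run_one_analysis <- function(table, s, folds, repeats, n_permutations,
                             selection_args, seed_sel, seed_cv, seed_mc) {
  vars <- s$vars
  shuffle_vars <- s$shuffle
  selected <- NULL
  if (s$select) {
    sel <- do.call(select_features, c(
      list(table = table, variables = vars, seed = seed_sel),
      selection_args))
    selected <- sel$selected_variables
    shuffle_vars <- intersect(shuffle_vars, selected)
    vars <- selected
  }
  out <- list(model_variables = vars, shuffled_variables = shuffle_vars)
  if (s$select) {
    out$lambda_chosen <- sel$lambda_chosen
    out$selected_columns <- sel$selected
  }
  if (!length(vars)) {
    out$note <- "empty selection: null model"
    out$apparent_cindex <- 0.5
    out$corrected_cindex <- 0.5
    return(out)
  }
  fit <- fit_cox(table, variables = vars)
  # hazard-ratio-ordered coefficient table, the usual reporting order
  td <- tidy(fit)
  out$coefficients <- td[order(-td$hazard_ratio), ]
  cv <- cross_validate(table, variables = vars, folds = folds,
                       repeats = repeats, seed = seed_cv,
                       selection = "none")
  out$apparent_cindex <- cv$apparent_cindex
  out$mean_cv_cindex <- cv$mean_cv_cindex
  out$corrected_cindex <- cv$corrected_cindex
  out$overfit_pvalue <- cv$overfit_pvalue
  if (!length(shuffle_vars)) {
    out$note <- "no shuffle targets after selection"
    return(out)
  }
  ev <- cox_cindex_evaluator(variables = vars)
  out$mc <- mc_test(table, shuffle_plan(shuffle_vars,
                                        n_permutations = n_permutations,
                                        seed = seed_mc), ev)
  out
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("<workflow_result> seed", x$config$seed, "on", x$config$n_patients,
      "patients\n")
  for (nm in names(x$analyses)) {
    a <- x$analyses[[nm]]
    cat(sprintf("  %-32s c-index %.3f (corrected %s)  %s\n", nm,
                a$apparent_cindex,
                ifelse(is.null(a$corrected_cindex), "NA",
                       sprintf("%.3f", a$corrected_cindex)),
                if (!is.null(a$mc)) format_mc_pvalue(a$mc)
                else a$note %||% ""))
  }
  invisible(x)
}

# ---- JSON reports -----------------------------------------------------

as_report_list <- function(x, ...) UseMethod("as_report_list")

#' @export
as_report_list.default <- function(x, ...) x

#' @export
as_report_list.tbl_df <- function(x, ...) as.data.frame(x)

#' @export
as_report_list.mc_result <- function(x, ...) {
  h <- graphics::hist(x$permuted_statistics, breaks = 30, plot = FALSE)
  list(
    statistic_name = x$statistic_name,
    observed_statistic = x$observed_statistic,
    pvalue = x$pvalue,
    pvalue_plus_one = x$pvalue_plus_one,
    pvalue_formatted = format_mc_pvalue(x),
    n_permutations = x$n_permutations,
    n_failed = x$n_failed,
    target_variables = x$plan$target_variables,
    seed = x$plan$seed,
    histogram = list(breaks = h$breaks, counts = h$counts),
    permuted_statistics = x$permuted_statistics
  )
}

#' @export
as_report_list.cv_result <- function(x, ...) {
  list(
    apparent_cindex = x$apparent_cindex,
    mean_cv_cindex = x$mean_cv_cindex,
    corrected_cindex = x$corrected_cindex,
    optimism = x$optimism,
    overfit_flag = x$overfit_flag,
    overfit_pvalue = x$overfit_pvalue,
    folds = x$folds, repeats = x$repeats, seed = x$seed,
    fold_cindices = as.data.frame(x$fold_cindices)
  )
}

#' @export
as_report_list.selection_result <- function(x, ...) {
  list(
    lambda_chosen = x$lambda_chosen,
    selected = x$selected,
    selected_variables = x$selected_variables,
    folds = x$folds, seed = x$seed,
    path = as.data.frame(x$path)
  )
}

#' @export
as_report_list.cox_fit <- function(x, ...) {
  list(coefficients = as.data.frame(tidy(x)),
       summary = as.data.frame(glance(x)))
}

#' @export
as_report_list.concordance_result <- function(x, ...) unclass(x)

#' @export
as_report_list.workflow_result <- function(x, ...) {
  list(config = x$config,
       analyses = lapply(x$analyses, function(a) {
         lapply(a, as_report_list)
       }))
}

#' Write or read a JSON analysis report
#'
#' Serialises any result object of this package (Monte Carlo, CV,
#' selection, fit, or full workflow results) to a JSON document with all
#' fields, permuted-statistic vectors included, in stable key order.
#'
#' @param result A result object.
#' @param path Output file path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   parsed document (lists and data frames).
#' @export
write_report <- function(result, path) {
  jsonlite::write_json(as_report_list(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export permuted statistics as a one-column CSV
#'
#' @param result An `mc_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_permuted_statistics <- function(result, path) {
  stopifnot(inherits(result, "mc_result"))
  readr::write_csv(tibble::tibble(statistic = result$permuted_statistics),
                   path, progress = FALSE)
  invisible(path)
}
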