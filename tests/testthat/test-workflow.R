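small_two_group_cohort <- function(seed, n = 80, clin_beta = 0.9) {
  sch <- dplyr::bind_rows(
    noise_schema(3, group = "clinicopathological", prefix = "clin"),
    noise_schema(4, group = "proteomic", prefix = "prot")
  )
  simulate_cohort(
    n = n, schema = sch,
    true_beta = c(clin1 = clin_beta, clin2 = -clin_beta / 2),
    censoring_rate = 0.3, seed = seed)
}

test_that("the four-analysis workflow emits every report section", {
  pt <- small_two_group_cohort(seed = 41)
  res <- run_workflow(pt, n_permutations = 10, folds = 4, repeats = 1,
                      selection = TRUE,
                      selection_args = list(folds = 4,
                                            lambda = lambda_grid(25)),
                      seed = 9)
  expect_s3_class(res, "workflow_result")
  expect_setequal(
    names(res$analyses),
    c("added_alone", "base_alone", "combined_added_shuffled",
      "added_alone_selected", "base_alone_selected",
      "combined_added_shuffled_selected"))
  for (a in res$analyses) {
    expect_true(is.numeric(a$apparent_cindex))
    expect_true(is.numeric(a$corrected_cindex))
  }
  base <- res$analyses$base_alone
  expect_setequal(base$mc$plan$target_variables,
                  group_variables(pt, "clinicopathological"))
  comb <- res$analyses$combined_added_shuffled
  expect_setequal(comb$mc$plan$target_variables,
                  group_variables(pt, "proteomic"))
  expect_length(comb$mc$permuted_statistics, 10)
})

test_that("workflow reports are byte-identical across reruns of a seed", {
  pt <- small_two_group_cohort(seed = 43)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  run_workflow(pt, n_permutations = 8, folds = 3, repeats = 1,
               selection = FALSE, seed = 5, out = f1)
  run_workflow(pt, n_permutations = 8, folds = 3, repeats = 1,
               selection = FALSE, seed = 5, out = f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".json")
  run_workflow(pt, n_permutations = 8, folds = 3, repeats = 1,
               selection = FALSE, seed = 6, out = f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("known group structure yields the expected qualitative pattern", {
  pt <- small_two_group_cohort(seed = 47, n = 150, clin_beta = 1.2)
  res <- run_workflow(pt, n_permutations = 60, folds = 5, repeats = 1,
                      selection = FALSE, seed = 21)
  # informative clinical group: low p; pure-noise proteomic group: high p
  expect_lt(res$analyses$base_alone$mc$pvalue_plus_one, 0.1)
  expect_gt(res$analyses$added_alone$mc$pvalue_plus_one, 0.1)
})

test_that("evaluators with internal selection and CV correction stay scalar", {
  pt <- small_two_group_cohort(seed = 53)
  ev_sel <- cox_cindex_evaluator(select = TRUE,
                                 selection_args = list(folds = 3,
                                                       lambda = lambda_grid(15)),
                                 seed = 2)
  v1 <- ev_sel(pt)
  expect_true(is.numeric(v1) && length(v1) == 1)
  ev_cv <- cox_cindex_evaluator(cv_correct = TRUE,
                                cv_args = list(folds = 4, repeats = 1),
                                seed = 2)
  v2 <- ev_cv(pt)
  expect_true(is.numeric(v2) && length(v2) == 1)
  expect_identical(ev_cv(pt), v2)
})

test_that("autoplot methods return ggplot objects", {
  pt <- small_two_group_cohort(seed = 59)
  mc <- mc_test(pt, shuffle_plan(c("prot1", "prot2"), 12, seed = 3))
  expect_s3_class(autoplot(mc), "ggplot")
  cv <- cross_validate(pt, folds = 3, repeats = 2, seed = 4)
  expect_s3_class(autoplot(cv), "ggplot")
  sel <- select_features(pt, folds = 3, seed = 5, lambda = lambda_grid(15))
  expect_s3_class(autoplot(sel), "ggplot")
  path <- lasso_cox_path(encode(pt), pt$time, pt$event,
                         lambda = lambda_grid(15))
  expect_s3_class(autoplot(path), "ggplot")
})
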