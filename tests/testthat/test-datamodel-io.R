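test_that("patient table validation enforces outcome and level invariants", {
  sch <- schema(var_spec("marker", "continuous", group = "proteomic"),
                var_spec("stage", "categorical",
                         levels = paste("stage", 1:4),
                         group = "clinicopathological"))
  df <- tibble::tibble(time = c(100, 250, 400), event = c(1, 0, 1),
                       marker = c(1.2, -0.5, 0.3),
                       stage = c("stage 1", "stage 3", "stage 1"))
  pt <- as_patient_table(df, sch)
  expect_s3_class(pt, "patient_table")
  expect_equal(n_patients(pt), 3)

  expect_error(as_patient_table(dplyr::mutate(df, time = c(0, 250, 400)), sch),
               "non-positive follow-up time in row\\(s\\) 1")
  expect_error(as_patient_table(dplyr::mutate(df, event = c(1, 2, 0)), sch),
               "event indicator")
  expect_error(as_patient_table(dplyr::select(df, -marker), sch),
               "lacks column")
  expect_error(
    as_patient_table(dplyr::mutate(df, stage = c("stage 1", "IV", "stage 2")),
                     sch),
    "undeclared level")
  expect_error(as_patient_table(dplyr::mutate(df, marker = c(NA, 1, 2)), sch),
               "missing values")
})

test_that("CSV + sidecar round-trip preserves the table", {
  pt <- simulate_cohort(n = 25, seed = 42)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_patient_table(pt, csv)
  pt2 <- read_patient_table(csv, paste0(sub("\\.csv$", "", csv),
                                        ".schema.yaml"))
  expect_equal(pt2$time, pt$time)
  expect_equal(pt2$event, pt$event)
  expect_equal(pt2$patient_ids, pt$patient_ids)
  expect_equal(as.data.frame(pt2$data), as.data.frame(pt$data))
  expect_equal(pt2$schema$name, pt$schema$name)
  expect_equal(pt2$schema$levels, pt$schema$levels)
  expect_equal(pt2$schema$group, pt$schema$group)
})

test_that("encoding follows the reference-coded L-1 rule in schema order", {
  sch <- schema(var_spec("stage", "categorical",
                         levels = paste("stage", 1:4), group = "clin"))
  df <- tibble::tibble(time = 1:8, event = rep(1, 8),
                       stage = rep(c("stage 1", "stage 2", "stage 3",
                                     "stage 4"), 2))
  d <- encode(as_patient_table(df, sch))
  expect_equal(ncol(d$x), 3)
  expect_equal(colnames(d$x),
               c("stage=stage 2", "stage=stage 3", "stage=stage 4"))
  expect_equal(unname(rowSums(d$x)), rep(c(0, 1, 1, 1), 2))

  # continuous variables pass through unchanged
  sch2 <- schema(var_spec("age", "continuous", group = "clin"))
  df2 <- tibble::tibble(time = 1:5, event = rep(1, 5), age = c(3, 1, 4, 1, 5))
  d2 <- encode(as_patient_table(df2, sch2))
  expect_equal(unname(d2$x[, 1]), df2$age)

  # full cohort schema: 11 clinicopathological design columns
  # (age + age stratum + 5 histopathology + 3 stage + 1 regimen)
  pt <- simulate_cohort(n = 30, seed = 1)
  dc <- encode(pt, group_variables(pt, "clinicopathological"))
  expect_equal(ncol(dc$x), 11)
  dall <- encode(pt)
  expect_equal(ncol(dall$x), 11 + 20)

  # declared-but-absent level yields an all-zero column flagged degenerate
  df3 <- tibble::tibble(time = 1:6, event = rep(1, 6),
                        stage = rep(c("stage 1", "stage 2"), 3))
  d3 <- encode(as_patient_table(df3, sch))
  expect_true(all(c("stage=stage 3", "stage=stage 4") %in% d3$degenerate))
})

test_that("encoding is deterministic and distinguishes different tables", {
  pt <- simulate_cohort(n = 20, seed = 7)
  expect_identical(encode(pt)$x, encode(pt)$x)
  pt2 <- simulate_cohort(n = 20, seed = 8)
  expect_false(identical(encode(pt)$x, encode(pt2)$x))
})

test_that("JSON reports round-trip mc results with all fields", {
  pt <- simulate_cohort(n = 40, seed = 3, censoring_rate = 0.25)
  mc <- mc_test(pt, shuffle_plan(c("stage", "age"), n_permutations = 10,
                                 seed = 2),
                cox_cindex_evaluator(variables = c("stage", "age")))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(mc, path)
  rep <- read_report(path)
  expect_length(rep$permuted_statistics, 10)
  expect_equal(rep$permuted_statistics, mc$permuted_statistics)
  expect_equal(rep$observed_statistic, mc$observed_statistic)
  expect_equal(rep$pvalue, mc$pvalue)
  expect_named(rep$histogram, c("breaks", "counts"))
})

test_that("schema sidecars survive YAML and JSON round-trips", {
  sch <- ovarian_schema()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_schema(sch, path)
    sch2 <- read_schema(path)
    expect_equal(sch2$name, sch$name)
    expect_equal(sch2$kind, sch$kind)
    expect_equal(sch2$levels, sch$levels)
    expect_equal(sch2$probs, sch$probs)
  }
})
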