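test_that("null model log-likelihood matches the closed Breslow form", {
  inst <- random_surv_instance(n = 35, p = 2, seed = 11)
  fit <- fit_cox(structure(list(x = inst$x, mapping = NULL),
                           class = "cox_design"),
                 time = inst$time, event = inst$event)
  # at beta = 0 every risk-set term is log |R_t|
  expected <- 0
  for (t in sort(unique(inst$time[inst$event == 1]))) {
    d_t <- sum(inst$time == t & inst$event == 1)
    expected <- expected - d_t * log(sum(inst$time >= t))
  }
  expect_equal(fit$loglik_null, expected, tolerance = 1e-12)
  expect_equal(breslow_loglik(inst$x, inst$time, inst$event, c(0, 0)),
               expected, tolerance = 1e-12)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("fitted coefficients match a derivative-free oracle maximiser", {
  worst_beta <- 0
  worst_ll <- 0
  for (seed in 1:12) {
    inst <- random_surv_instance(n = 15 + 2 * seed, p = 1 + seed %% 3,
                                 seed = 100 + seed)
    fit <- fit_cox(structure(list(x = inst$x, mapping = NULL),
                             class = "cox_design"),
                   time = inst$time, event = inst$event)
    ref <- oracle_cox_beta(inst$x, inst$time, inst$event)
    worst_beta <- max(worst_beta, max(abs(fit$coefficients - ref)))
    worst_ll <- max(worst_ll, abs(
      fit$loglik - oracle_breslow_loglik(inst$x, inst$time, inst$event, ref)))
  }
  expect_lt(worst_beta, 1e-5)
  expect_lt(worst_ll, 1e-8)
})

test_that("likelihood is invariant to covariate translation", {
  inst <- random_surv_instance(n = 40, p = 2, seed = 21)
  d1 <- structure(list(x = inst$x, mapping = NULL), class = "cox_design")
  d2 <- structure(list(x = inst$x + 100, mapping = NULL),
                  class = "cox_design")
  f1 <- fit_cox(d1, time = inst$time, event = inst$event)
  f2 <- fit_cox(d2, time = inst$time, event = inst$event)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$loglik - f1$loglik_null, f2$loglik - f2$loglik_null,
               tolerance = 1e-8)
})

test_that("degenerate and pathological inputs are reported, not silently fit", {
  inst <- random_surv_instance(n = 30, p = 2, seed = 31)
  x <- cbind(inst$x, constant = 5)
  fit <- fit_cox(structure(list(x = x, mapping = NULL),
                           class = "cox_design"),
                 time = inst$time, event = inst$event)
  expect_true("constant" %in% fit$degenerate)
  expect_equal(unname(fit$coefficients[1:2]),
               unname(fit_cox(structure(list(x = inst$x, mapping = NULL),
                                        class = "cox_design"),
                              time = inst$time,
                              event = inst$event)$coefficients),
               tolerance = 1e-6)

  expect_error(
    fit_cox(structure(list(x = inst$x, mapping = NULL),
                      class = "cox_design"),
            time = inst$time, event = rep(0, 30)),
    "no observed events")

  # a covariate that perfectly separates event order diverges
  n <- 40
  tm <- seq_len(n)
  ev <- rep(1, n)
  x_mono <- matrix(-seq_len(n), ncol = 1,
                   dimnames = list(NULL, "perfect"))
  expect_error(
    fit_cox(structure(list(x = x_mono, mapping = NULL),
                      class = "cox_design"),
            time = tm, event = ev),
    "diverging")
})

test_that("risk scores are X beta and preserve the true risk ordering", {
  pt <- noise_cohort(n = 500, p = 2, seed = 5, beta = c(1, 0.5),
                     censoring = 0.25)
  fit <- fit_cox(pt)
  expect_equal(risk_scores(fit), as.vector(encode(pt)$x %*% fit$coefficients))
  expect_equal(risk_scores(fit, encode(pt)), risk_scores(fit))
  true_eta <- pt$truth$eta
  expect_gt(stats::cor(risk_scores(fit), true_eta, method = "spearman"), 0.9)

  # beta = 0 gives all-zero scores; single column with beta = 1 reproduces it
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(unique(risk_scores(fit0, encode(pt))), 0)
})

test_that("Schoenfeld residuals behave at the optimum and flag violations", {
  pt <- noise_cohort(n = 150, p = 2, seed = 9, beta = c(0.7, 0),
                     censoring = 0.25)
  fit <- fit_cox(pt)
  sch <- schoenfeld_test(fit)
  expect_equal(nrow(sch$residuals), sum(pt$event))
  expect_lt(max(abs(colSums(sch$residuals))), 1e-6)
  expect_true(all(sch$per_column$p.value >= 0 & sch$per_column$p.value <= 1))

  # an effect that reverses sign over time violates proportional hazards
  set.seed(77)
  n <- 400
  x <- stats::rnorm(n)
  u <- stats::runif(n)
  early <- x > stats::median(x)
  tm <- ifelse(early, -log(u) * 100, 200 + -log(u) * 600)
  df <- tibble::tibble(time = tm, event = 1, x1 = x)
  ptv <- as_patient_table(df, noise_schema(1))
  fitv <- fit_cox(ptv)
  schv <- schoenfeld_test(fitv)
  expect_lt(schv$per_column$p.value[1], 0.05)

  few <- subset_patients(pt, 1:4)
  few$event[] <- c(1, 1, 0, 0)
  expect_error(schoenfeld_test(fit_cox(few, variables = "x1")),
               "fewer than 3 events")
})

test_that("tidy and glance expose the fit in conventional form", {
  pt <- noise_cohort(n = 120, p = 3, seed = 13, beta = c(0.8, 0, 0))
  fit <- fit_cox(pt)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "hazard_ratio", "conf.low", "conf.high"))
  expect_equal(td$hazard_ratio, exp(td$estimate))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 120)
  expect_equal(gl$lr_statistic, 2 * (fit$loglik - fit$loglik_null))
})
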