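# Synthetic cohort generator: Weibull proportional-hazards event times with
# known coefficients over a mixed clinicopathological/proteomic schema, and
# independent right-censoring calibrated to a target fraction.

rtruncnorm_u <- function(u, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + u * (pu - pl), mean, sd)
}

#' Schema of p generic continuous predictors
#'
#' Convenience builder for simulation studies: standard-Gaussian continuous
#' variables named `prefix1..prefixp` under one group label.
#'
#' @param p Number of variables.
#' @param group Group label.
#' @param prefix Name prefix.
#' @return A schema tibble.
#' @export
noise_schema <- function(p, group = "predictors", prefix = "x") {
  schema(!!!purrr::map(seq_len(p), function(i) {
    var_spec(paste0(prefix, i), "continuous", group = group)
  }))
}

#' Simulate a right-censored survival cohort with known ground truth
#'
#' Draws predictors per the schema (truncated-Gaussian continuous values —
#' AQUA-like intensities bounded to 0-255 under [ovarian_schema()] — and
#' categorical levels from their configured probabilities), builds the
#' linear predictor `eta = X beta_true` on the encoded design, and samples
#' event times from a Weibull proportional-hazards model by inverse
#' transform: `T = scale * (-log(U) / exp(eta))^(1/shape)`. Censoring times
#' are independent of covariates, drawn from a Weibull of the same shape
#' whose scale is calibrated on the realised draws so the censored fraction
#' matches `censoring_rate` (error if infeasible beyond +/- 0.05).
#'
#' Both a PFS-like and an OS-like outcome are generated; the OS event time
#' adds a positive Weibull gap to the PFS event time and shares its
#' follow-up cutoff, so observed OS >= observed PFS by construction. When
#' the schema contains both `age` and `age_over_50`, the binary stratum is
#' derived from the continuous age at 50 years.
#'
#' @param n Number of patients (default 339).
#' @param schema Schema tibble (default [ovarian_schema()]).
#' @param true_beta Named vector of true log-hazard-ratio coefficients on
#'   design columns (see [encode()] for the naming); unnamed columns get 0.
#' @param baseline_shape,baseline_scale Weibull baseline parameters, days;
#'   the default scale puts the median PFS-like event time near 540 days at
#'   `eta = 0`.
#' @param censoring_rate Target right-censoring fraction in (0, 1).
#' @param correlation Optional correlation matrix (symmetric positive
#'   definite) over the continuous variables, applied via a Gaussian
#'   copula.
#' @param outcome Which outcome the table binds as `time`/`event`:
#'   `"pfs"` or `"os"`. Both are kept as extra columns.
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @return A `patient_table` with a `truth` element recording the full
#'   `true_beta`, the linear predictor and the generator settings.
#' @examples
#' pt <- simulate_cohort(n = 50, seed = 1,
#'                       true_beta = c("stage=stage 4" = 0.7))
#' pt
#' @export
simulate_cohort <- function(n = 339, schema = ovarian_schema(),
                            true_beta = NULL, baseline_shape = 1.2,
                            baseline_scale = 540 / log(2)^(1 / 1.2),
                            censoring_rate = 0.3, correlation = NULL,
                            outcome = c("pfs", "os"), seed = 1) {
  outcome <- match.arg(outcome)
  validate_schema(schema)
  stopifnot(n >= 2, baseline_shape > 0, baseline_scale > 0,
            censoring_rate > 0, censoring_rate < 1)
  set.seed(as.integer(seed))

  cont <- schema$name[schema$kind == "continuous"]
  u <- matrix(stats::runif(n * length(cont)), n, length(cont),
              dimnames = list(NULL, cont))
  if (!is.null(correlation)) {
    stopifnot(nrow(correlation) == length(cont),
              isTRUE(all.equal(correlation, t(correlation))))
    ch <- chol(correlation)   # fails if not positive definite
    z <- matrix(stats::rnorm(n * length(cont)), n) %*% ch
    u <- stats::pnorm(z)
    colnames(u) <- cont
  }

  data <- tibble::tibble(.rows = n)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$kind[i] == "continuous") {
      data[[nm]] <- rtruncnorm_u(u[, nm], schema$mean[i], schema$sd[i],
                                 schema$lower[i], schema$upper[i])
    } else {
      lv <- schema$levels[[i]]
      data[[nm]] <- sample(lv, n, replace = TRUE, prob = schema$probs[[i]])
    }
  }
  if (all(c("age", "age_over_50") %in% schema$name)) {
    data$age_over_50 <- ifelse(data$age > 50 * 365.25, ">50", "<50")
  }

  # linear predictor on the encoded design, centred (absorbed by baseline)
  tmp <- as_patient_table(
    dplyr::bind_cols(tibble::tibble(time = rep(1, n), event = rep(1, n)),
                     data),
    schema)
  design <- encode(tmp)
  beta <- stats::setNames(rep(0, ncol(design$x)), colnames(design$x))
  if (!is.null(true_beta)) {
    unknown <- setdiff(names(true_beta), names(beta))
    if (length(unknown)) {
      stop("true_beta names not design columns: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    beta[names(true_beta)] <- true_beta
  }
  eta <- as.vector(design$x %*% beta)
  eta <- eta - mean(eta)

  weib <- function(v) baseline_scale * (-log(v))^(1 / baseline_shape)
  t_pfs <- weib(stats::runif(n)) * exp(-eta / baseline_shape)
  t_gap <- 0.5 * weib(stats::runif(n))
  t_os <- t_pfs + t_gap

  # calibrate the censoring scale on the realised draws
  w_c <- (-log(stats::runif(n)))^(1 / baseline_shape)
  s_pfs <- stats::quantile(t_pfs / w_c, 1 - censoring_rate, names = FALSE)
  c_pfs <- s_pfs * w_c
  w_c2 <- (-log(stats::runif(n)))^(1 / baseline_shape)
  ratio_os <- (t_os - c_pfs) / w_c2
  s_os <- stats::quantile(ratio_os, 1 - censoring_rate, names = FALSE)
  if (s_os <= 0) s_os <- .Machine$double.eps
  c_os <- c_pfs + s_os * w_c2

  pfs_event <- as.numeric(t_pfs <= c_pfs)
  os_event <- as.numeric(t_os <= c_os)
  for (lab in c("pfs", "os")) {
    realized <- if (lab == "pfs") 1 - mean(pfs_event) else 1 - mean(os_event)
    if (abs(realized - censoring_rate) > 0.05) {
      stop("censoring target ", censoring_rate, " infeasible for ", lab,
           " (realised ", round(realized, 3), ")", call. = FALSE)
    }
  }

  df <- dplyr::bind_cols(
    tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      pfs_time = pmax(pmin(t_pfs, c_pfs), .Machine$double.eps),
      pfs_event = pfs_event,
      os_time = pmax(pmin(t_os, c_os), .Machine$double.eps),
      os_event = os_event
    ),
    data
  )
  df$time <- df[[paste0(outcome, "_time")]]
  df$event <- df[[paste0(outcome, "_event")]]
  pt <- as_patient_table(df, schema, id_col = "patient_id")
  pt$truth <- list(
    true_beta = beta, eta = eta,
    event_time_pfs = t_pfs, event_time_os = t_os,
    baseline_shape = baseline_shape,
    baseline_scale = baseline_scale, censoring_rate = censoring_rate,
    outcome = outcome, seed = as.integer(seed)
  )
  pt
}
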