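# Breslow partial-likelihood machinery shared by the fitter, the LASSO
# path and the cross-validated likelihood criterion.
#
# For each distinct event time t with event set D_t and risk set
# R_t = {j : t_j >= t}, the Breslow partial log-likelihood contributes
#   sum_{i in D_t} eta_i  -  |D_t| * log( sum_{j in R_t} exp(eta_j) ).

# Risk-set structure of one dataset (sort order, tied-time groups, events
# per distinct time), precomputed once and reused across likelihood calls.
breslow_ctx <- function(time, event) {
  o <- order(time)
  t_s <- time[o]
  first <- !duplicated(t_s)
  grp <- cumsum(first)
  d_g <- as.vector(rowsum(event[o], grp))
  ev_g <- d_g > 0
  list(o = o, grp = grp, first_idx = which(first), d_g = d_g, ev_g = ev_g,
       event = event, n = length(time))
}

# Per-patient quantities at linear predictor eta (original order):
#   loglik, mu_i = E[events for i] and w_i = diagonal of -d2/deta2,
# used for gradients and the quadratic approximation.
breslow_parts <- function(time, event, eta, need_weights = FALSE,
                          ctx = NULL) {
  if (is.null(ctx)) ctx <- breslow_ctx(time, event)
  eta <- eta - mean(eta)                      # loglik invariant under shifts
  o <- ctx$o
  e_s <- exp(eta[o])
  n <- ctx$n

  # risk-set denominators per time group (first index of each tied block)
  revcum <- rev(cumsum(rev(e_s)))
  S_g <- revcum[ctx$first_idx]                # sum over {t_j >= t_g}
  d_g <- ctx$d_g
  ev_g <- ctx$ev_g
  loglik <- sum(eta[ctx$event == 1]) - sum(d_g[ev_g] * log(S_g[ev_g]))

  h1 <- numeric(length(d_g))                  # d_t / S_t
  h1[ev_g] <- d_g[ev_g] / S_g[ev_g]
  H1 <- cumsum(h1)[ctx$grp]                   # sum over event times <= t_i
  mu_s <- e_s * H1
  out <- list(loglik = loglik, mu = numeric(n))
  out$mu[o] <- mu_s
  if (need_weights) {
    h2 <- numeric(length(d_g))
    h2[ev_g] <- d_g[ev_g] / S_g[ev_g]^2
    H2 <- cumsum(h2)[ctx$grp]
    w_s <- pmax(e_s * H1 - e_s^2 * H2, 1e-12)
    out$w <- numeric(n)
    out$w[o] <- w_s
  }
  out
}

#' Breslow partial log-likelihood of a Cox model
#'
#' Evaluates the Breslow-tie partial log-likelihood at an arbitrary
#' coefficient vector. At `beta = 0` this reduces to
#' `-sum over events of log |risk set|`.
#'
#' @param x Numeric design matrix (patients x columns).
#' @param time,event Right-censored outcome vectors.
#' @param beta Coefficient vector (length `ncol(x)`).
#' @return The partial log-likelihood (scalar).
#' @export
breslow_loglik <- function(x, time, event, beta) {
  eta <- if (ncol(x)) as.vector(x %*% beta) else rep(0, length(time))
  breslow_parts(time, event, eta)$loglik
}

# Score vector d loglik / d beta at eta = x beta
breslow_score <- function(x, time, event, eta) {
  p <- breslow_parts(time, event, eta)
  as.vector(crossprod(x, event - p$mu))
}

# Exact local quadratic model of the Breslow partial log-likelihood at eta:
# value, score g and negative Hessian H (both in coefficient space), via
# per-risk-set weighted column sums; O(n p + G p^2) per call.
breslow_quad <- function(xs, eta, ctx) {
  eta <- eta - mean(eta)
  o <- ctx$o
  e_s <- exp(eta[o])
  xs_s <- xs[o, , drop = FALSE]
  revcum <- rev(cumsum(rev(e_s)))
  S_g <- revcum[ctx$first_idx]
  d_g <- ctx$d_g
  ev_g <- ctx$ev_g
  loglik <- sum(eta[ctx$event == 1]) - sum(d_g[ev_g] * log(S_g[ev_g]))

  h1 <- numeric(length(d_g))
  h1[ev_g] <- d_g[ev_g] / S_g[ev_g]
  H1 <- cumsum(h1)[ctx$grp]
  mu_s <- e_s * H1
  mu <- numeric(ctx$n)
  mu[o] <- mu_s
  g <- as.vector(crossprod(xs, ctx$event - mu))

  # V[g, ] = sum over the risk set of time-group g of e_i * x_i
  ex <- xs_s * e_s
  n <- ctx$n
  fi <- ctx$first_idx
  V <- vapply(seq_len(ncol(ex)), function(j) {
    cs <- cumsum(ex[, j])
    (cs[n] - c(0, cs[-n]))[fi]
  }, numeric(length(fi)))
  V <- matrix(V, nrow = length(fi))
  cg <- numeric(length(d_g))
  cg[ev_g] <- d_g[ev_g] / S_g[ev_g]^2
  H <- crossprod(xs_s, mu_s * xs_s) - crossprod(V, cg * V)
  list(loglik = loglik, g = g, H = H)
}

fit_cox_mat <- function(x, time, event, tolerance = 1e-8, max_iter = 50) {
  n <- length(time)
  if (n < 2) stop("need at least 2 patients", call. = FALSE)
  if (sum(event) < 1) stop("no observed events: Cox model undefined",
                           call. = FALSE)
  if (ncol(x) == 0) {
    ll0 <- breslow_parts(time, event, rep(0, n))$loglik
    return(structure(list(
      coefficients = numeric(0), std_errors = numeric(0),
      loglik_null = ll0, loglik = ll0, converged = TRUE, iterations = 0L,
      linear_predictors = rep(0, n), var = matrix(0, 0, 0),
      degenerate = character(0), x = x, time = time, event = event
    ), class = "cox_fit"))
  }
  if (any(!is.finite(x))) stop("design matrix contains non-finite values",
                               call. = FALSE)
  storage.mode(x) <- "double"
  infinite_flag <- FALSE
  ran_out <- FALSE
  fit <- withCallingHandlers(
    survival::coxph.fit(
      x, survival::Surv(time, event), strata = NULL, offset = NULL,
      init = NULL, control = survival::coxph.control(eps = 1e-10,
                                                     toler.chol = 1e-12,
                                                     iter.max = max_iter),
      weights = NULL, method = "breslow", rownames = NULL
    ),
    warning = function(w) {
      if (grepl("infinite", conditionMessage(w))) {
        infinite_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("Ran out of iterations", conditionMessage(w))) {
        ran_out <<- TRUE          # reported through the converged flag
        invokeRestart("muffleWarning")
      }
    }
  )
  if (infinite_flag) {
    worst <- colnames(x)[which.max(abs(ifelse(is.na(fit$coefficients), 0,
                                              fit$coefficients)))]
    stop("coefficient diverging (monotone likelihood?) for column(s): ",
         worst, call. = FALSE)
  }
  beta <- fit$coefficients
  degenerate <- names(beta)[is.na(beta)]
  if (is.null(names(beta))) degenerate <- colnames(x)[is.na(beta)]
  if (length(degenerate)) {
    # NA on a full-rank design is a collapsed information matrix from a
    # diverging coefficient, not collinearity
    if (qr(cbind(1, x))$rank == ncol(x) + 1L) {
      stop("coefficient diverging (monotone likelihood?) for column(s): ",
           paste(degenerate, collapse = ", "), call. = FALSE)
    }
  }
  beta0 <- ifelse(is.na(beta), 0, beta)
  big <- abs(beta0) > 20
  if (any(big)) {
    stop("coefficient diverging (monotone likelihood?) for column(s): ",
         paste(colnames(x)[big], collapse = ", "), call. = FALSE)
  }
  eta <- as.vector(x %*% beta0)
  score <- breslow_score(x, time, event, eta)
  ok <- !is.na(beta)
  converged <- !ran_out &&
    (max(abs(score[ok]), 0) <= max(tolerance, 1e-8) || fit$iter < max_iter)
  se <- rep(NA_real_, ncol(x))
  se[ok] <- sqrt(pmax(diag(as.matrix(fit$var))[seq_len(sum(ok))], 0))
  names(beta0) <- colnames(x)
  names(se) <- colnames(x)
  structure(list(
    coefficients = ifelse(is.na(beta), NA_real_, beta0),
    std_errors = se,
    loglik_null = fit$loglik[1], loglik = fit$loglik[2],
    converged = converged, iterations = fit$iter,
    linear_predictors = eta, var = fit$var,
    degenerate = degenerate,
    x = x, time = time, event = event
  ), class = "cox_fit")
}

#' Fit a Cox proportional hazards model (Breslow ties)
#'
#' Maximises the Breslow partial log-likelihood by Newton-Raphson and
#' returns coefficients, standard errors (inverse observed information),
#' log-likelihoods and per-patient risk scores. Tied event times share a
#' single risk-set denominator (Breslow approximation).
#'
#' @param table A `patient_table`, or a `cox_design` (then supply `time` and
#'   `event`).
#' @param variables Optional variable subset (patient-table input only).
#' @param time,event Outcome vectors when `table` is a `cox_design`.
#' @param tolerance Score max-norm declaring convergence.
#' @param max_iter Newton-Raphson iteration cap.
#' @return A `cox_fit` object; see [tidy.cox_fit()] and [glance.cox_fit()].
#' @examples
#' pt <- simulate_cohort(n = 80, seed = 7,
#'                       true_beta = c(pERK_nuc = 0.01))
#' fit <- fit_cox(pt, variables = c("pERK_nuc", "stage"))
#' tidy(fit)
#' @export
fit_cox <- function(table, variables = NULL, time = NULL, event = NULL,
                    tolerance = 1e-8, max_iter = 50) {
  if (inherits(table, "patient_table")) {
    d <- encode(table, variables)
    fit <- fit_cox_mat(d$x, table$time, table$event,
                       tolerance = tolerance, max_iter = max_iter)
    fit$mapping <- d$mapping
    fit
  } else if (inherits(table, "cox_design")) {
    stopifnot(!is.null(time), !is.null(event))
    fit <- fit_cox_mat(table$x, time, event, tolerance = tolerance,
                       max_iter = max_iter)
    fit$mapping <- table$mapping
    fit
  } else {
    stop("`table` must be a patient_table or cox_design", call. = FALSE)
  }
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> ", length(x$time), " patients, ", sum(x$event), " events, ",
      length(x$coefficients), " design columns\n", sep = "")
  cat(sprintf("  loglik %0.3f (null %0.3f), %d iterations, converged: %s\n",
              x$loglik, x$loglik_null, x$iterations, x$converged))
  if (length(x$coefficients)) print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A tibble with one row per design column: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `hazard_ratio`, `conf.low`,
#'   `conf.high` (95% Wald interval on the hazard-ratio scale), sorted in
#'   design order.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$std_errors
  z <- est / se
  tibble::tibble(
    term = names(est) %||% paste0("x", seq_along(est)),
    estimate = unname(est), std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    hazard_ratio = exp(unname(est)),
    conf.low = exp(unname(est - 1.96 * se)),
    conf.high = exp(unname(est + 1.96 * se))
  )
}

#' One-row summary of a Cox fit
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sample size, events, log-likelihoods,
#'   likelihood-ratio statistic, iterations, convergence flag.
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$time), n_events = sum(x$event),
    loglik_null = x$loglik_null, loglik = x$loglik,
    lr_statistic = 2 * (x$loglik - x$loglik_null),
    iterations = x$iterations, converged = x$converged,
    n_degenerate = length(x$degenerate)
  )
}

#' Risk scores (linear predictors) of a Cox fit
#'
#' Returns `X beta`, a monotone transform of the predicted hazard, for the
#' fitting data or for new data encoded with the same columns. Degenerate
#' (inestimable) coefficients contribute zero.
#'
#' @param fit A `cox_fit`.
#' @param newdata Optional: a `cox_design` or numeric matrix with the same
#'   columns as the fit.
#' @return Numeric vector of risk scores.
#' @export
risk_scores <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  if (is.null(newdata)) return(fit$linear_predictors)
  x <- if (inherits(newdata, "cox_design")) newdata$x else as.matrix(newdata)
  if (ncol(x) != length(beta)) {
    stop("newdata has ", ncol(x), " columns but the fit has ", length(beta),
         call. = FALSE)
  }
  if (length(beta) == 0) return(rep(0, nrow(x)))
  as.vector(x %*% beta)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Computes Schoenfeld residuals (observed covariate of each failing patient
#' minus the risk-set weighted mean) and tests each column's residuals for
#' correlation with the rank of event time; a global chi-square test
#' aggregates the columns.
#'
#' @param fit A `cox_fit` (must be converged).
#' @return A `schoenfeld_diagnostics` object: `residuals` (one row per
#'   observed event), `per_column` tibble (`term`, `chisq`, `p.value`) and
#'   `global_pvalue`.
#' @export
schoenfeld_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (sum(fit$event) < 3) {
    stop("fewer than 3 events: Schoenfeld diagnostics unavailable",
         call. = FALSE)
  }
  keep <- !is.na(fit$coefficients) &
    !(names(fit$coefficients) %in% fit$degenerate)
  x <- fit$x[, keep, drop = FALSE]
  df <- data.frame(.time = fit$time, .event = fit$event)
  cfit <- survival::coxph(
    survival::Surv(.time, .event) ~ x, data = df, ties = "breslow"
  )
  zph <- survival::cox.zph(cfit, transform = "rank", global = TRUE)
  res <- stats::residuals(cfit, type = "schoenfeld")
  res <- as.matrix(res)
  colnames(res) <- colnames(x)
  tab <- zph$table
  per <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  structure(list(
    residuals = res,
    per_column = tibble::tibble(
      term = colnames(x),
      chisq = unname(per[, "chisq"]),
      p.value = unname(per[, "p"])
    ),
    global_pvalue = unname(tab["GLOBAL", "p"])
  ), class = "schoenfeld_diagnostics")
}

#' @export
print.schoenfeld_diagnostics <- function(x, ...) {
  cat("<schoenfeld_diagnostics> global p =",
      format.pval(x$global_pvalue, digits = 3), "\n")
  print(x$per_column)
  invisible(x)
}
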