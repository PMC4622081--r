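# Independent oracles, written as plain double loops / closed forms so they
# share no code path with the package internals they check.

# Harrell c-index by explicit pair enumeration
oracle_cindex <- function(scores, time, event) {
  n <- length(scores)
  conc <- disc <- tie <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      earlier <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!earlier) next
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] < scores[j]) disc <- disc + 1
      else tie <- tie + 1
    }
  }
  list(concordant = conc, discordant = disc, tied_risk = tie,
       comparable = conc + disc + tie,
       cindex = if (conc + disc + tie > 0) {
         (conc + 0.5 * tie) / (conc + disc + tie)
       } else {
         NA_real_
       })
}

# Breslow partial log-likelihood by direct risk-set summation
oracle_breslow_loglik <- function(x, time, event, beta) {
  eta <- as.vector(x %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_set <- which(time == t & event == 1)
    r_set <- which(time >= t)
    ll <- ll + sum(eta[d_set]) - length(d_set) * log(sum(exp(eta[r_set])))
  }
  ll
}

# Derivative-free maximisation of the oracle likelihood
oracle_cox_beta <- function(x, time, event) {
  p <- ncol(x)
  nll <- function(b) -oracle_breslow_loglik(x, time, event, b)
  if (p == 1) {
    stats::optimize(function(b) nll(b), interval = c(-10, 10),
                    tol = 1e-10)$minimum
  } else {
    o <- stats::optim(rep(0, p), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 50000))
    stats::optim(o$par, nll, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 50000))$par
  }
}

# small random right-censored instance with possibly tied times
random_surv_instance <- function(n, p, seed, tie_prob = 0.5,
                                 censor_prob = 0.3) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("c", seq_len(p))))
  time <- if (stats::runif(1) < tie_prob) {
    sample(1:12, n, replace = TRUE)                 # many ties
  } else {
    round(stats::rexp(n, 0.01), 3) + 1
  }
  event <- stats::rbinom(n, 1, 1 - censor_prob)
  if (sum(event) < 2) event[sample(n, 2)] <- 1
  list(x = x, time = as.numeric(time), event = as.numeric(event))
}

# cohort of p independent N(0,1) predictors with optional true effects
noise_cohort <- function(n, p, seed, beta = NULL, censoring = 0.3,
                         group = "predictors") {
  sch <- noise_schema(p, group = group)
  tb <- NULL
  if (!is.null(beta)) tb <- stats::setNames(beta, sch$name[seq_along(beta)])
  simulate_cohort(n = n, schema = sch, true_beta = tb,
                  censoring_rate = censoring, seed = seed)
}
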