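# L1-penalised Cox regression by cyclic coordinate descent.
#
# Objective (maximised):  l(beta) - lambda * sum_j |beta_j^std|
# where l is the Breslow partial log-likelihood and beta^std are the
# coefficients on internally standardised columns (mean 0, variance 1 with
# the 1/n denominator), so the penalty is scale-fair across AQUA intensities
# and 0/1 indicators. Coefficients are reported on the original scale.
#
# Proximal Newton: each outer step forms the exact local quadratic model of
# the partial log-likelihood (score + Hessian) and solves the penalised
# quadratic subproblem by soft-thresholded cyclic coordinate descent, with
# step-halving on the true penalised objective.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Cyclic coordinate descent on one quadratic approximation, expressed
# through the Gram matrix:  minimise  1/2 b'Ab - c'b + lambda |b|_1  with
# A = Xs' W Xs and c = A b_cur + score(b_cur). Each coordinate update is
# O(p) via the cached q = A b.
cd_quad <- function(A, c_vec, b, lambda, tol = 1e-9, max_cycles = 50) {
  .cd_quad_cpp(A, c_vec, b, lambda, tol, max_cycles)
}

lasso_fit_one <- function(xs, time, event, lambda, b_init,
                          max_outer = 100, kkt_tol = 1e-7, ctx = NULL) {
  if (is.null(ctx)) ctx <- breslow_ctx(time, event)
  b <- b_init
  penalty <- function(b) lambda * sum(abs(b))
  obj_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    eta <- as.vector(xs %*% b)
    quad <- breslow_quad(xs, eta, ctx)
    g <- quad$g

    # KKT optimality on the standardised scale
    ok_zero <- abs(g[b == 0]) <= lambda + kkt_tol
    ok_nz <- abs(g[b != 0] - lambda * sign(b[b != 0])) <= kkt_tol * (1 + lambda)
    if (all(ok_zero) && all(ok_nz)) {
      converged <- TRUE
      break
    }

    A <- quad$H
    c_vec <- as.vector(A %*% b) + g
    b_prev <- b
    b <- cd_quad(A, c_vec, b, lambda)
    if (any(abs(b) > 30)) return(list(b = b, converged = FALSE))
    if (max(abs(b - b_prev)) < 1e-13) next

    obj <- breslow_parts(time, event, as.vector(xs %*% b),
                         ctx = ctx)$loglik - penalty(b)
    # step-halving toward the previous iterate if the true objective fell
    halvings <- 0
    while (obj < obj_old - 1e-10 && halvings < 20) {
      b <- (b + b_prev) / 2
      obj <- breslow_parts(time, event, as.vector(xs %*% b),
                           ctx = ctx)$loglik - penalty(b)
      halvings <- halvings + 1
    }
    obj_old <- obj
    if (max(abs(b - b_prev)) < 1e-12 && it > 2) {
      converged <- TRUE
      break
    }
  }
  list(b = b, converged = converged)
}

standardize_design <- function(x) {
  ctr <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  keep <- sdev > 0
  xs <- sweep(x[, keep, drop = FALSE], 2, ctr[keep])
  xs <- sweep(xs, 2, sdev[keep], "/")
  list(xs = xs, center = ctr, scale = sdev, keep = keep)
}

#' Default sparsity-parameter grid
#'
#' Log-spaced values across the open interval (0.001, 50) used for the
#' penalised Cox path.
#'
#' @param n_lambda Number of grid points.
#' @return Decreasing numeric vector.
#' @export
lambda_grid <- function(n_lambda = 100) {
  exp(seq(log(50 * (1 - 1e-9)), log(0.001 * (1 + 1e-9)),
          length.out = n_lambda))
}

#' Smallest penalty that zeroes every coefficient
#'
#' Computed from the null-model score: the max-norm of the Breslow
#' partial-likelihood gradient at `beta = 0` on the standardised design.
#'
#' @param design A `cox_design` or numeric matrix.
#' @param time,event Outcome vectors.
#' @return Scalar `lambda_max`.
#' @export
lasso_lambda_max <- function(design, time, event) {
  x <- if (inherits(design, "cox_design")) design$x else as.matrix(design)
  std <- standardize_design(x)
  g0 <- breslow_score(std$xs, time, event, rep(0, length(time)))
  max(abs(g0))
}

#' L1-penalised Cox coefficient path
#'
#' Fits the penalised model at each value of a decreasing sparsity grid
#' (warm-started), maximising the Breslow partial log-likelihood minus
#' `lambda * sum |beta_std|`; coefficients are returned on the original
#' design scale.
#'
#' @param design A `cox_design` or numeric matrix.
#' @param time,event Outcome vectors.
#' @param lambda Penalty grid (any order; refit in decreasing order).
#' @return A `lasso_path`: `lambda` (decreasing), `beta` (columns x lambda,
#'   original scale), `beta_std` (standardised scale), `converged` per grid
#'   point, `n_nonzero`, and the standardisation used.
#' @export
lasso_cox_path <- function(design, time, event, lambda = lambda_grid()) {
  x <- if (inherits(design, "cox_design")) design$x else as.matrix(design)
  stopifnot(all(lambda > 0))
  lambda <- sort(unique(lambda), decreasing = TRUE)
  std <- standardize_design(x)
  xs <- std$xs
  p_all <- ncol(x)
  p <- ncol(xs)
  beta_std <- matrix(0, p, length(lambda))
  conv <- logical(length(lambda))
  b <- rep(0, p)
  ctx <- breslow_ctx(time, event)
  for (k in seq_along(lambda)) {
    fit <- lasso_fit_one(xs, time, event, lambda[k], b_init = b, ctx = ctx)
    conv[k] <- fit$converged
    if (fit$converged) b <- fit$b
    beta_std[, k] <- if (fit$converged) fit$b else NA_real_
  }
  beta <- matrix(0, p_all, length(lambda),
                 dimnames = list(colnames(x), NULL))
  beta[std$keep, ] <- beta_std / std$scale[std$keep]
  beta[, !conv] <- NA_real_
  structure(list(
    lambda = lambda, beta = beta, beta_std = beta_std, converged = conv,
    n_nonzero = colSums(beta_std != 0),
    standardization = std
  ), class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("<lasso_path> ", nrow(x$beta), " columns over ", length(x$lambda),
      " lambda values (", sum(!x$converged), " non-converged)\n", sep = "")
  invisible(x)
}

#' @method tidy lasso_path
#' @export
tidy.lasso_path <- function(x, ...) {
  tibble::tibble(
    lambda = rep(x$lambda, each = nrow(x$beta)),
    term = rep(rownames(x$beta), length(x$lambda)),
    estimate = as.vector(x$beta)
  )
}

cv_fold_ids <- function(n, folds, seed) {
  set.seed(seed)
  sort_order <- sample.int(n)
  rep_len(seq_len(folds), n)[order(sort_order)]
}

#' Select features by cross-validated penalised likelihood
#'
#' Chooses the sparsity parameter maximising the cross-validated partial
#' log-likelihood in its verification form: for each held-out fold,
#' `loglik(all patients at the fold-trained coefficients) - loglik(training
#' patients at the same coefficients)`. The selected feature set is the
#' nonzero-coefficient columns of the full-data path at the chosen lambda;
#' downstream models refit these features unpenalised.
#'
#' @param table A `patient_table`, or a `cox_design` with `time`/`event`.
#' @param variables Optional variable subset (patient-table input only).
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Penalty grid.
#' @param time,event Outcome vectors for `cox_design` input.
#' @return A `selection_result`: `lambda_chosen`, `selected` (design-column
#'   names), `selected_variables` (source variables), `coefficients` at the
#'   chosen lambda, `path` tibble (`lambda`, `cvl`, `n_nonzero`), `folds`,
#'   `seed`.
#' @examples
#' pt <- simulate_cohort(n = 120, seed = 3,
#'                       true_beta = c(pERK_nuc = 0.02))
#' sel <- select_features(pt, folds = 5, seed = 1,
#'                        lambda = lambda_grid(40))
#' sel$selected_variables
#' @export
select_features <- function(table, variables = NULL, folds = 10, seed = 1,
                            lambda = lambda_grid(), time = NULL,
                            event = NULL) {
  stopifnot(folds >= 2)
  if (inherits(table, "patient_table")) {
    design <- encode(table, variables)
    time <- table$time
    event <- table$event
  } else {
    design <- table
    stopifnot(inherits(design, "cox_design"), !is.null(time),
              !is.null(event))
  }
  x <- design$x
  n <- length(time)
  lambda <- sort(unique(lambda), decreasing = TRUE)
  fold_id <- cv_fold_ids(n, folds, seed)

  cvl <- matrix(NA_real_, folds, length(lambda))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    path_k <- lasso_cox_path(x[tr, , drop = FALSE], time[tr], event[tr],
                             lambda = lambda)
    for (l in seq_along(lambda)) {
      bkl <- path_k$beta[, l]
      if (anyNA(bkl)) next
      cvl[k, l] <- breslow_loglik(x, time, event, bkl) -
        breslow_loglik(x[tr, , drop = FALSE], time[tr], event[tr], bkl)
    }
  }
  mean_cvl <- colMeans(cvl)
  usable <- !is.na(mean_cvl)
  if (!any(usable)) stop("penalised fit failed at every lambda",
                         call. = FALSE)
  best <- which(usable)[which.max(mean_cvl[usable])]

  full_path <- lasso_cox_path(x, time, event, lambda = lambda)
  coef_best <- full_path$beta[, best]
  if (anyNA(coef_best)) {
    # fall back to the best lambda whose full-data fit converged
    cand <- which(usable & full_path$converged)
    if (!length(cand)) stop("no converged full-data penalised fit",
                            call. = FALSE)
    best <- cand[which.max(mean_cvl[cand])]
    coef_best <- full_path$beta[, best]
  }
  selected <- colnames(x)[coef_best != 0]
  sel_vars <- unique(design$mapping$variable[
    design$mapping$column %in% selected])
  structure(list(
    lambda_chosen = lambda[best],
    selected = selected,
    selected_variables = sel_vars,
    coefficients = coef_best,
    path = tibble::tibble(lambda = lambda, cvl = mean_cvl,
                          n_nonzero = full_path$n_nonzero),
    full_path = full_path,
    folds = folds, seed = seed
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> lambda =", signif(x$lambda_chosen, 4), "->",
      length(x$selected), "design columns (",
      length(x$selected_variables), "variables )\n")
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 selected = names(x$coefficients) %in% x$selected)
}

#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(lambda_chosen = x$lambda_chosen,
                 n_selected = length(x$selected),
                 n_variables = length(x$selected_variables),
                 folds = x$folds, seed = x$seed)
}
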