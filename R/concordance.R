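comparable_pairs_env <- new.env(parent = emptyenv())

# Comparable-pair index under Harrell's rules: element k pairs patient
# i[k] (the "earlier" member, who must have the event) with j[k]. The
# outcome is fixed across the permutations of a Monte Carlo run, so the
# last outcome's pair index is memoised.
comparable_pairs_idx <- function(time, event) {
  cache <- comparable_pairs_env$last
  if (!is.null(cache) && identical(cache$time, time) &&
      identical(cache$event, event)) {
    return(cache)
  }
  n <- length(time)
  # earlier[i, j]: i is the earlier member of a comparable pair (i, j)
  dt <- outer(time, time, "<")
  eq <- outer(time, time, "==")
  ei <- matrix(event == 1, n, n)
  ej <- t(ei)
  earlier <- (dt & ei) | (eq & ei & !ej)
  diag(earlier) <- FALSE
  w <- which(earlier)
  cache <- list(time = time, event = event,
                i = ((w - 1) %% n) + 1, j = ((w - 1) %/% n) + 1)
  comparable_pairs_env$last <- cache
  cache
}

#' Harrell's concordance index for right-censored outcomes
#'
#' Direct pair enumeration under Harrell's original comparability rules:
#' a pair is comparable iff the patient with the smaller observed time had
#' the event (a censored patient can only be the later member); two censored
#' patients are never comparable; tied event times with both events are
#' incomparable; a tied time with exactly one event counts the event patient
#' as the earlier member. A comparable pair is concordant when the earlier
#' patient carries the higher risk score; tied scores contribute 0.5.
#'
#' @param scores Numeric risk scores (higher = worse prognosis).
#' @param time,event Right-censored outcome vectors, or a `patient_table`
#'   passed as `time` with `event` missing.
#' @return A `concordance_result`: `cindex`, and the pair counts
#'   `concordant`, `discordant`, `tied_risk`, `comparable_pairs`.
#' @examples
#' cindex(c(2, 1, 0), time = c(100, 200, 300), event = c(1, 1, 0))
#' @export
cindex <- function(scores, time, event) {
  if (inherits(time, "patient_table") && missing(event)) {
    event <- time$event
    time <- time$time
  }
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 2) stop("need at least 2 patients", call. = FALSE)

  idx <- comparable_pairs_idx(time, event)
  d <- scores[idx$i] - scores[idx$j]
  conc <- sum(d > 0)
  disc <- sum(d < 0)
  ties <- sum(d == 0)
  comparable <- conc + disc + ties
  if (comparable == 0) {
    stop("no comparable pairs: concordance undefined", call. = FALSE)
  }
  structure(list(
    cindex = (conc + 0.5 * ties) / comparable,
    concordant = conc, discordant = disc, tied_risk = ties,
    comparable_pairs = comparable
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> c-index %.4f (%d concordant, %d discordant, %d tied of %d comparable pairs)\n",
    x$cindex, x$concordant, x$discordant, x$tied_risk, x$comparable_pairs))
  invisible(x)
}

#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) {
  tibble::tibble(
    cindex = x$cindex, concordant = x$concordant,
    discordant = x$discordant, tied_risk = x$tied_risk,
    comparable_pairs = x$comparable_pairs
  )
}
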