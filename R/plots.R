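#' Plot the Monte Carlo null distribution
#'
#' Histogram of the permuted statistics, bars coloured below (green) and
#' above (pink) the observed value, with the observed statistic marked and
#' the one-tailed p-value in the subtitle.
#'
#' @param object An `mc_result`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_result
#' @export
autoplot.mc_result <- function(object, bins = 40, ...) {
  df <- tibble::tibble(statistic = object$permuted_statistics)
  obs <- object$observed_statistic
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic,
                                   fill = .data$statistic >= obs)) +
    ggplot2::geom_histogram(bins = bins, colour = "grey30",
                            linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = obs, linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c("FALSE" = "#5ab56e", "TRUE" = "#e8879c"),
      labels = c("below observed", "at or above"), name = NULL) +
    ggplot2::labs(
      x = object$statistic_name, y = "randomised datasets",
      title = "Per-variable shuffling null distribution",
      subtitle = paste0(format_mc_pvalue(object), " (",
                        object$n_permutations, " permutations; shuffled: ",
                        paste(object$plan$target_variables,
                              collapse = ", "), ")")) +
    ggplot2::theme_minimal()
}

#' Plot fold-level cross-validated c-indices
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$fold_cindices
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$repeat_id),
                                   y = .data$cindex_test)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = object$apparent_cindex,
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$corrected_cindex,
                        colour = "steelblue") +
    ggplot2::labs(x = "repeat", y = "held-out c-index",
                  title = "Repeated cross-validation",
                  subtitle = sprintf(
                    "apparent %.3f (dashed), corrected %.3f (solid)",
                    object$apparent_cindex, object$corrected_cindex)) +
    ggplot2::theme_minimal()
}

#' Plot an L1 coefficient path
#'
#' @param object A `lasso_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lasso_path
#' @export
autoplot.lasso_path <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$estimate) & df$estimate != 0 |
             df$term %in% df$term[df$estimate != 0], ]
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = log(.data$lambda), y = .data$estimate,
                               colour = .data$term)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "log(lambda)", y = "coefficient (original scale)",
                  title = "L1-penalised Cox coefficient path") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validated likelihood curve of a feature selection
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot2::ggplot(object$path,
                  ggplot2::aes(x = log(.data$lambda), y = .data$cvl)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda_chosen),
                        linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)",
                  y = "cross-validated partial log-likelihood",
                  title = "Likelihood cross-validation",
                  subtitle = sprintf("lambda = %.4g, %d columns selected",
                                     object$lambda_chosen,
                                     length(object$selected))) +
    ggplot2::theme_minimal()
}
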