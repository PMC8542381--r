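# ggplot2 display methods for the result objects.

#' Plot a ROC curve
#'
#' @param object A `roc_curve` from [roc_points()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a risk predictiveness curve
#'
#' Predicted mortality risk against the cumulative fraction of children,
#' with the overall cohort CFR as a dashed reference line.
#'
#' @param object A `predictiveness_curve` from [predictiveness_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.predictiveness_curve <- function(object, ...) {
  overall <- attr(object, "overall_risk")
  df <- tibble::as_tibble(object)
  df0 <- dplyr::bind_rows(
    tibble::tibble(cum_fraction = 0, predicted_risk = df$predicted_risk[1]),
    df[c("cum_fraction", "predicted_risk")]
  )
  ggplot2::ggplot(df0, ggplot2::aes(x = .data$cum_fraction,
                                    y = .data$predicted_risk)) +
    ggplot2::geom_hline(yintercept = overall, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_x_continuous(labels = function(v) 100 * v) +
    ggplot2::scale_y_continuous(labels = function(v) 100 * v) +
    ggplot2::labs(x = "Cumulative percentage of children",
                  y = "Predicted mortality risk (%)") +
    ggplot2::theme_minimal()
}

#' Plot sensitivity and specificity across cut-points
#'
#' @param object A `cutpoint_table` from [cutpoint_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cutpoint_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::select("cutpoint", "sensitivity", "specificity") |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutpoint, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Score cut-point (>= rule)", y = "Proportion",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot all ROC curves of a validation run
#'
#' @param object A `pneumo_validation` from [run_validation()].
#' @param ... Unused.
#' @return A ggplot faceted by score.
#' @export
autoplot.pneumo_validation <- function(object, ...) {
  dfs <- purrr::imap(object$results, function(r, nm) {
    if (is.null(r$roc)) return(NULL)
    df <- tibble::as_tibble(r$roc)
    df$score_name <- nm
    df
  })
  df <- dplyr::bind_rows(dfs)
  if (nrow(df) == 0L) abort("No score in this run has a ROC curve.")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$score_name)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}
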