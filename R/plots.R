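#' Scatter plot of point C relative to the external auditory canal
#'
#' The classic cranial-window scatter: occipitofrontal (anterior
#' positive) offset on x, vertical (superior positive) offset on y, one
#' point per subject-side, coloured by the approach decision when the
#' cohort has been classified.
#'
#' @param cohort A cohort tibble (optionally with an `approach` column
#'   from [add_oza_decision()]).
#' @return A ggplot object.
#' @export
plot_point_c <- function(cohort) {
  p <- ggplot2::ggplot(cohort, ggplot2::aes(
    x = .data$c_occipitofrontal_mm, y = .data$c_vertical_mm
  ))
  p <- if ("approach" %in% names(cohort)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$approach), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::labs(
      x = "occipitofrontal offset from EAC (mm, anterior +)",
      y = "vertical offset from EAC (mm, superior +)",
      title = "Distribution of the cranial-window centre (point C)"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a correlation report
#'
#' Dot plot of Pearson r per (outcome, predictor) pair; filled points are
#' significant at the Bonferroni-corrected level.
#'
#' @param object An `oza_correlation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.oza_correlation <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$predictor, y = .data$r,
    shape = .data$significant, colour = .data$outcome
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(
      y = "Pearson r",
      title = sprintf("C-distance correlations (corrected alpha = %.3f, n = %d)",
                      object$corrected_alpha, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
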