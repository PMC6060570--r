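#' Plot a curve estimate
#'
#' Ribbon-and-line plot of a `pp_curve` (posterior mean with 95%
#' pointwise credible band). Curves carrying a `group` column (e.g. from
#' [group_mean_curves()]) are colored by group; curves for several
#' athletes are faceted.
#'
#' @param object A `pp_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pp_curve <- function(object, ...) {
  has_group <- "group" %in% names(object)
  aes_base <- if (has_group) {
    ggplot2::aes(x = .data$day, y = .data$mean, colour = .data$group,
                 fill = .data$group)
  } else {
    ggplot2::aes(x = .data$day, y = .data$mean)
  }
  p <- ggplot2::ggplot(object, aes_base) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day of season", y = "Shot put result (m)") +
    ggplot2::theme_minimal()
  if ("athlete_id" %in% names(object) &&
      length(unique(object$athlete_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~athlete_id)
  }
  p
}

#' Plot a ROC curve
#'
#' @param object A `pp_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object with the AUC in the subtitle.
#' @export
autoplot.pp_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}
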