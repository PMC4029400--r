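# ggplot2 views of the three result types: ROC curves, learning curves, and
# the experiment grid (AUC with CI ribbons versus training size, faceted by
# aggregation level and selection configuration).

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_abline facet_grid labs scale_x_log10 theme_bw
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#' @param object A `ctrss_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctrss_roc
#' @export
autoplot.ctrss_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("ROC-AUC %.3f (95%% CI %.3f-%.3f)",
                         object$auc, object$ci_low, object$ci_high)) +
    theme_bw()
}

#' Plot a learning curve
#'
#' AUC against training-set size with the bootstrap CI as a ribbon; the
#' x-axis is logarithmic because the reduction ladder is geometric.
#'
#' @param object A `ctrss_learning_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctrss_learning_curve
#' @export
autoplot.ctrss_learning_curve <- function(object, ...) {
  ok <- object[object$status == "ok", ]
  p <- ggplot(ok, aes(x = .data$train_n, y = .data$auc))
  if (!all(is.na(ok$ci_low))) {
    p <- p + geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2)
  }
  p + geom_line() + geom_point() + scale_x_log10() +
    labs(x = "Training-set size (patients)", y = "ROC-AUC") +
    theme_bw()
}

#' Plot an experiment grid
#'
#' One panel per aggregation level and selection configuration, model
#' families as coloured lines: the pipeline's full comparison view.
#'
#' @param object A `ctrss_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctrss_grid
#' @export
autoplot.ctrss_grid <- function(object, ...) {
  ok <- object[object$status == "ok", ]
  ggplot(ok, aes(x = .data$train_n, y = .data$auc, colour = .data$family)) +
    geom_line() + geom_point(size = 0.8) +
    facet_grid(rows = ggplot2::vars(.data$method, .data$k),
               cols = ggplot2::vars(.data$level)) +
    scale_x_log10() +
    labs(x = "Training-set size (patients)", y = "ROC-AUC",
         colour = "Model family") +
    theme_bw()
}
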