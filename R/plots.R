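#' Observed-versus-predicted plot for a pipeline run
#'
#' The standard diagnostic for the regression models: observed yield against
#' predicted yield, training and validation points distinguished, identity
#' line overlaid.
#'
#' @param object a `ptml_run` from [run_pipeline()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ptml_run
#' @export
autoplot.ptml_run <- function(object, ...) {
  df <- tibble(
    observed = object$records$yield_pct,
    predicted = unname(object$predictions),
    subset = ifelse(object$records$split_label == "t", "training", "validation")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted,
                                   colour = .data$subset)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Observed yield (%)", y = "Predicted yield (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object a `ptml_roc` tibble from [roc_points()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ptml_roc
#' @export
autoplot.ptml_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Permutation-importance bar plot
#'
#' @param object a `ptml_importance` tibble from [feature_importance()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ptml_importance
#' @export
autoplot.ptml_importance <- function(object, ...) {
  df <- object
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$importance, .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Permutation importance (metric drop)", y = NULL) +
    ggplot2::theme_minimal()
}
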