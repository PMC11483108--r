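#' @importFrom ggplot2 ggplot aes geom_line geom_step geom_point geom_col
#'   geom_ribbon geom_hline geom_abline geom_errorbarh labs theme_minimal
#'   coord_flip autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot methods
#'
#' Every plotting function draws from the numbers already returned by the
#' corresponding computation; no quantity is computed in the plot layer.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name itrboost-plots
NULL

#' @rdname itrboost-plots
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.3f, direction %s)", object$auc,
                         object$direction)) +
    theme_minimal()
}

#' @rdname itrboost-plots
#' @export
autoplot.cutoff_result <- function(object, ...) {
  m <- object$metrics
  if (all(c("sensitivity", "specificity") %in% names(m))) {
    long <- tidyr::pivot_longer(m[, c("cutoff", "sensitivity", "specificity")],
                                -"cutoff", names_to = "metric")
    p <- ggplot(long, aes(x = .data$cutoff, y = .data$value,
                          colour = .data$metric)) +
      geom_line() + geom_point() +
      labs(x = sprintf("%s cutoff", object$biomarker), y = "Value")
  } else {
    p <- ggplot(m, aes(x = .data$cutoff, y = -log10(.data$p_value))) +
      geom_line() + geom_point() +
      labs(x = sprintf("%s cutoff", object$biomarker),
           y = "-log10 p-value")
  }
  p + theme_minimal() +
    labs(title = sprintf("Cutoff metrics (%s); selected = %s", object$method,
                         format(object$selected)))
}

#' @rdname itrboost-plots
#' @export
autoplot.ecdf_result <- function(object, ...) {
  ggplot(object$points, aes(x = .data$value, y = .data$ecdf,
                            colour = .data$group)) +
    geom_step() +
    labs(x = object$biomarker, y = "Empirical CDF") +
    theme_minimal()
}

#' @rdname itrboost-plots
#' @export
autoplot.smooth_contrast <- function(object, ...) {
  p <- ggplot(object$grid, aes(x = .data$x, y = .data$fit)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.2) +
    geom_line() +
    labs(x = object$biomarker,
         y = sprintf("%s (%s scale)", object$kind, object$scale)) +
    theme_minimal()
  if (object$kind == "treatment_contrast") {
    p <- p + geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50")
  }
  p
}

#' @rdname itrboost-plots
#' @export
autoplot.subgroup_model <- function(object, ...) {
  ggplot(object$history, aes(x = .data$round, y = .data$loss)) +
    geom_line() +
    labs(x = "Boosting round", y = "Modified loss (training)") +
    theme_minimal()
}

#' @rdname itrboost-plots
#' @export
autoplot.subgroup_perf_table <- function(object, ...) {
  cc <- object$contrasts[!is.na(object$contrasts$estimate), , drop = FALSE]
  ref <- if (any(cc$contrast %in% c("odds_ratio", "hazard_ratio"))) 1 else 0
  ggplot(cc, aes(x = .data$estimate, y = .data$group)) +
    geom_vline2(ref) +
    geom_errorbarh(aes(xmin = .data$conf_low, xmax = .data$conf_high),
                   height = 0.15) +
    geom_point() +
    labs(x = unique(cc$contrast)[1], y = NULL,
         title = "Per-group treatment contrast") +
    theme_minimal()
}

geom_vline2 <- function(ref) {
  ggplot2::geom_vline(xintercept = ref, linetype = "dashed", colour = "grey50")
}

#' Bar plot of biomarker importance
#'
#' @param model A fitted `subgroup_model`.
#' @param top_n Show at most this many biomarkers.
#' @return A ggplot object.
#' @export
plot_importance <- function(model, top_n = 20) {
  imp <- head(biomarker_importance(model), top_n)
  ggplot(imp, aes(x = .data$gain,
                  y = stats::reorder(.data$biomarker, .data$gain))) +
    geom_col() +
    labs(x = "Gain share", y = NULL, title = "Predictive biomarker importance") +
    theme_minimal()
}
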