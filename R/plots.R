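#' Plot methods
#'
#' ggplot2 views of the main result types: the qualification tensor as a
#' per-criterion heat map, per-fold experiment metrics, the weight-sweep
#' landscape (metric against mean qualification, coloured by region), and
#' the optimiser trace.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name technome-plots
NULL

#' @rdname technome-plots
#' @method autoplot tn_qual
#' @export
autoplot.tn_qual <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$surrogate, y = .data$feature,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~criterion) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "surrogate", y = "feature", fill = "score")
}

#' @rdname technome-plots
#' @method autoplot tn_experiment
#' @export
autoplot.tn_experiment <- function(object, ...) {
  df <- tidy(object)
  ylab <- if (object$mode == "stabilisation") "variance reduction" else "AUC"
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$metric)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_metric, linetype = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "fold", y = ylab,
                  title = sprintf("%s (%s), mean %.3f", object$mode,
                                  object$scheme, object$mean_metric))
}

#' @rdname technome-plots
#' @method autoplot tn_sweep
#' @export
autoplot.tn_sweep <- function(object, ...) {
  df <- object$samples
  ylab <- if (object$mode == "stabilisation") "variance reduction" else "AUC"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_qualification,
                                   y = .data$metric,
                                   colour = .data$region)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "mean qualification of selected surrogates", y = ylab,
                  colour = "region")
}

#' @rdname technome-plots
#' @method autoplot tn_opt
#' @export
autoplot.tn_opt <- function(object, ...) {
  df <- object$trace
  df$best_so_far <- cummin(df$loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eval)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$loss), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_so_far),
                       colour = "firebrick") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "evaluation", y = "loss")
}

#' @rdname technome-plots
#' @param results Output of [run_baseline_suite()].
#' @export
plot_baseline_comparison <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$method, y = .data$metric)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "held-out metric")
}
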