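#' Plot methods
#'
#' `autoplot()` methods render the package's result objects as ggplot2
#' figures: median paths with quantile ribbons for ensembles and
#' lattices, steady-state branches (stable solid, unstable dashed) with
#' fold markers for bifurcation diagrams, likelihood curves with the
#' 0.95/0.5/0.05 guide levels, and transition-interval curves per variant
#' for sweeps.
#'
#' @param object A package result object.
#' @param variables Which state variables to show (envelope plots).
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name gli-autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname gli-autoplot
#' @export
autoplot.gli_ensemble <- function(object, variables = c("A", "R", "T", "P"),
                                  ...) {
  envelope_plot(tidy(object), variables,
                sprintf("%d stochastic replicates (epsilon = %g)",
                        object$n_replicates, object$config$epsilon))
}

#' @rdname gli-autoplot
#' @export
autoplot.gli_lattice <- function(object, variables = c("T", "P"), ...) {
  envelope_plot(tidy(object), variables,
                sprintf("%d x %d lattice, coupling %s", object$rows,
                        object$cols, if (object$coupling) "on" else "off"))
}

envelope_plot <- function(df, variables, subtitle) {
  df <- dplyr::filter(df, .data$variable %in% variables)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$median)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable)) +
    ggplot2::labs(x = "time (days)", y = "concentration",
                  title = "Median path and quantile envelope",
                  subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' @rdname gli-autoplot
#' @export
autoplot.gli_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                            names_to = "variable", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "concentration",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname gli-autoplot
#' @export
autoplot.gli_likelihood <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$likelihood)) +
    ggplot2::geom_hline(yintercept = c(0.05, 0.5, 0.95),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "MN differentiation likelihood") +
    ggplot2::theme_minimal()
}

#' @rdname gli-autoplot
#' @export
autoplot.gli_bifurcation <- function(object, ...) {
  br <- object$branches
  folds <- dplyr::filter(object$fold_points, is.finite(.data$R_fold))
  p <- ggplot2::ggplot(br, ggplot2::aes(.data$R, .data$T_star)) +
    ggplot2::geom_point(
      ggplot2::aes(shape = .data$stable, colour = .data$stable), size = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "grey60"),
      labels = c(`TRUE` = "stable", `FALSE` = "unstable"), name = NULL) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1),
      labels = c(`TRUE` = "stable", `FALSE` = "unstable"), name = NULL) +
    ggplot2::labs(x = "GliR", y = "Tgfb steady state",
                  title = "Tgfb bifurcation diagram") +
    ggplot2::theme_minimal()
  if (nrow(folds) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = folds$R_fold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @rdname gli-autoplot
#' @export
autoplot.gli_sweep <- function(object, ...) {
  metric <- if (unique(object$param) == "lambda") "t_switch" else "delta_t"
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$value, .data[[metric]],
                               colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$param),
                  y = paste(metric, "(days)"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname gli-autoplot
#' @param panel A `gli_mutant_panel`.
#' @export
plot_mutant_panel <- function(panel, ...) {
  stopifnot(inherits(panel, "gli_mutant_panel"))
  ggplot2::ggplot(panel$curves,
                  ggplot2::aes(.data$time, .data$likelihood,
                               colour = .data$preset)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "MN differentiation likelihood",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
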