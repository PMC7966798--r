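#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result types: violin plots of
#' the score distributions by population and sex, a magnitude/angle view of
#' the trajectory analysis, and the posterior compatibility corridor of a
#' quap regression.
#'
#' @param object A dimorph result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name dimorph-autoplot
NULL

#' @rdname dimorph-autoplot
#' @export
autoplot.sshd_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$scores,
    cols = dplyr::starts_with("score_"),
    names_to = "component", values_to = "score",
    names_prefix = "score_"
  )
  long$component <- factor(long$component,
                           levels = c("overall", "allometric", "nonallometric"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population, y = .data$score,
                                     fill = .data$sex)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         linewidth = 0.2) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "sexscore (female-inverted)",
                  title = "Sexual shape dimorphism by population") +
    ggplot2::theme_minimal()
}

#' @rdname dimorph-autoplot
#' @export
autoplot.trajectory_result <- function(object, ...) {
  ggplot2::ggplot(object$magnitudes,
                  ggplot2::aes(x = stats::reorder(.data$population,
                                                  .data$magnitude),
                               y = .data$magnitude)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|MM - FM| (Procrustes units)",
                  title = "Magnitude of the sex-difference vector") +
    ggplot2::theme_minimal()
}

#' @rdname dimorph-autoplot
#' @param x_grid Predictor grid for the corridor (default: 80 points over
#'   the fitted range or \[-2, 2\]).
#' @param data Optional tibble with `x`, `y` columns overplotted as points.
#' @param seed Seed for the posterior draws.
#' @export
autoplot.quap_fit <- function(object, x_grid = seq(-2, 2, length.out = 80),
                              data = NULL, seed = 1L, ...) {
  corridor <- posterior_corridor(object, x_grid, seed = seed)
  p <- ggplot2::ggplot(corridor, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower_89,
                                      ymax = .data$upper_89),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "x (standardized)", y = "y (standardized)",
                  title = "Posterior mean and 89% compatibility corridor") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, alpha = 0.6
    )
  }
  p
}

#' Plot a consensus shape with an effect vector
#'
#' Draws the mean configuration and arrows showing a shape-space vector
#' (e.g. a sex-difference vector), magnified for visibility.
#'
#' @param consensus Flat 2k consensus shape.
#' @param effect Flat 2k displacement vector.
#' @param magnify Arrow magnification (default 3).
#' @return A ggplot.
#' @export
plot_shape_effect <- function(consensus, effect, magnify = 3) {
  cfg <- as_config(consensus)
  eff <- as_config(effect) * magnify
  df <- tibble::tibble(
    x = cfg[, 1], y = cfg[, 2],
    xend = cfg[, 1] + eff[, 1], yend = cfg[, 2] + eff[, 2]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Shape effect (x", magnify, ")")) +
    ggplot2::theme_minimal()
}
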