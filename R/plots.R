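# ggplot2 display helpers.

#' @export
autoplot.periodogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$period_h, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "dominant_period_h"),
                        linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Period (h)", y = "Lomb-Scargle power")
}

#' @export
autoplot.prc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pulse_phase_h, .data$shift_h)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Pulse onset after Per peak (h)",
                  y = "Steady-state phase shift (h)")
}

#' @export
autoplot.gene_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("P", "B", "R"), names_to = "gene",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h / 24, .data$value,
                                     colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (days)", y = "Expression (a.u.)",
                  colour = NULL)
}

#' Period-map heat map
#'
#' @param map Tibble `row`, `col`, `period_h` from [pixelwise_period_map()].
#' @return A ggplot object.
#' @export
plot_period_map <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(.data$col, .data$row,
                                    fill = .data$period_h)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Period (h)")
}

#' Jet-lag shift curves
#'
#' @param shifts Tibble `day`, `shift_per_h`, `shift_bmal_h` (phase /
#'   Poincare models) or `day`, `shift_p_h`, `shift_b_h`, `shift_r_h`
#'   (gene circuit).
#' @return A ggplot object.
#' @export
plot_shift_curves <- function(shifts) {
  long <- tidyr::pivot_longer(shifts, -"day", names_to = "loop",
                              values_to = "shift_h")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$shift_h,
                                     colour = .data$loop)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Days after shift", y = "Acrophase shift (h)",
                  colour = NULL)
}

#' RSS fitness landscape
#'
#' @param landscape Tibble `k`, `z`, `log_rss` from [rss_fitness()].
#' @return A ggplot object.
#' @export
plot_fitness_landscape <- function(landscape) {
  ggplot2::ggplot(landscape, ggplot2::aes(.data$k, .data$z,
                                          fill = .data$log_rss)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "Coupling K (rad/h)", y = "Zeitgeber strength z",
                  fill = "log10 RSS")
}
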