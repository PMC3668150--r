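# ggplot2 views of the standard result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_col
#'   facet_wrap labs scale_x_continuous position_dodge theme_bw
NULL

#' @export
ggplot2::autoplot

hours <- function(x) x / 3600

#' Plot isoform dynamics of an ensemble (units representation)
#'
#' Mono-, di- and tri-ubiquitylated PCNA ensemble means over time, with a
#' +/- 1 sd ribbon for the across-run stochastic fluctuation.
#'
#' @param object A `prr_ensemble`.
#' @param channels Channels to draw. Default mono/di/tri.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prr_ensemble <- function(object, channels = c("mono", "di", "tri"),
                                  ...) {
  ur <- units_representation(object) %>%
    filter(.data$channel %in% channels) %>%
    mutate(channel = factor(.data$channel, levels = channels))
  ggplot(ur, aes(hours(.data$time), .data$mean,
                 colour = .data$channel, fill = .data$channel)) +
    geom_ribbon(aes(ymin = pmax(.data$mean - .data$std, 0),
                    ymax = .data$mean + .data$std),
                alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = "time after irradiation (h)", y = "molecules per nucleus",
         colour = "isoform", fill = "isoform") +
    theme_bw()
}

#' Side-by-side NR bar comparison
#'
#' Stacked isoform-ratio bars for a simulated and an experimental (or
#' synthetic-blot) ratio series at the shared detected time points.
#'
#' @param sim,exp Ratio series tibbles (`time`, `isoform`, `ratio`,
#'   `below_detection`).
#' @return A ggplot.
#' @export
plot_ratio_comparison <- function(sim, exp) {
  both <- bind_rows(
    sim %>% mutate(origin = "simulated"),
    exp %>% mutate(origin = "experimental")
  ) %>% filter(!.data$below_detection)
  ggplot(both, aes(factor(hours(.data$time)), .data$ratio, fill = .data$isoform)) +
    geom_col(position = "stack", width = 0.8) +
    facet_wrap(~origin) +
    labs(x = "time after irradiation (h)", y = "fraction of modified PCNA",
         fill = "isoform") +
    theme_bw()
}

#' Plot a parameter sweep
#'
#' Mono and poly (di + tri) channel time courses, one line per swept value.
#'
#' @param sweep A `prr_sweep`.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  df <- purrr::map2_dfr(sweep$value, sweep$ensemble, function(v, ens) {
    mono_poly_series(ens) %>% mutate(value = v)
  })
  ggplot(df, aes(hours(.data$time), .data$mean,
                 colour = factor(signif(.data$value, 4)))) +
    geom_line() +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "time after irradiation (h)", y = "molecules per nucleus",
         colour = sweep$target[1]) +
    theme_bw()
}

#' Plot Morris screening results
#'
#' The classic mu*-sigma plane, one panel per output.
#'
#' @param object A `prr_ee`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prr_ee <- function(object, ...) {
  df <- as_tibble(unclass(object))
  ggplot(df, aes(.data$mu_star, .data$sigma)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(aes(label = .data$factor), vjust = -0.6, size = 3) +
    facet_wrap(~output, scales = "free") +
    labs(x = expression(mu * "*"), y = expression(sigma)) +
    theme_bw()
}
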