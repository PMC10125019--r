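# ggplot2 views of the main result types.

#' Plot a propagation map
#'
#' Mean ripple lag against medio-lateral position, one line per
#' strong/common class when present.
#'
#' @param map_df Tibble from [propagation_map()].
#' @return A ggplot.
#' @export
plot_propagation_map <- function(map_df) {
  p <- ggplot2::ggplot(map_df,
                       ggplot2::aes(x = .data$ml, y = .data$mean_lag_ms))
  if ("class" %in% names(map_df)) {
    p <- p + ggplot2::aes(colour = .data$class)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "M-L position (µm)", y = "mean lag (ms)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot peri-ripple spike histograms
#'
#' @param hist_df Tibble from [peri_ripple_histogram()] (optionally with a
#'   `seed_type` column).
#' @return A ggplot, one facet per probe.
#' @export
plot_peri_ripple_histogram <- function(hist_df) {
  p <- ggplot2::ggplot(hist_df,
                       ggplot2::aes(x = .data$time_ms, y = .data$mean_count))
  if ("seed_type" %in% names(hist_df)) {
    p <- p + ggplot2::aes(colour = .data$seed_type)
  }
  p + ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$probe_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from ripple start (ms)",
                  y = "spikes / bin / ripple", colour = "seed") +
    ggplot2::theme_minimal()
}

#' Plot a medial-minus-lateral seed difference map
#'
#' @param dmap Tibble from [seed_difference_map()].
#' @return A ggplot heat map (space x time).
#' @export
plot_seed_difference_map <- function(dmap) {
  ggplot2::ggplot(dmap, ggplot2::aes(x = .data$time_ms, y = .data$ml,
                                     fill = .data$diff_count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::geom_vline(xintercept = c(0, 50, 120), linetype = "dashed") +
    ggplot2::labs(x = "time from ripple start (ms)",
                  y = "M-L position (µm)",
                  fill = "medial - lateral\n(spikes/bin/ripple)") +
    ggplot2::theme_minimal()
}

#' Baseline-vs-ripple firing-rate scatter
#'
#' Identity line marks absent modulation; the red dashed line a 50% rate
#' increase.
#'
#' @param rates Tibble from [baseline_ripple_rates()].
#' @return A ggplot.
#' @export
plot_modulation_scatter <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$baseline_hz,
                                      y = .data$ripple_hz,
                                      colour = .data$area)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = 1.5, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "baseline rate (Hz)", y = "ripple rate (Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
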