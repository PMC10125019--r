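# Peri-ripple spiking engagement across the medio-lateral axis.
#
# Units are represented as a tibble with one row per sorted cluster and a
# `spike_times` list column (sorted seconds), plus metadata: `cluster_id`,
# `probe_id`, `area`, `ml`, `waveform_duration_ms`, QC metrics and
# `firing_rate`.

spike_counts_in_windows <- function(spikes, starts, window) {
  # counts per window [start + window[1], start + window[2]) for one cluster
  findInterval(starts + window[2], spikes, left.open = TRUE) -
    findInterval(starts + window[1], spikes, left.open = TRUE)
}

#' Peri-ripple spike-time histogram per probe
#'
#' Histogram of spiking around ripple start (a 0.5 s window centred on the
#' start by default), pooled over the clusters of each probe and averaged
#' over ripples: counts per bin per ripple.
#'
#' @param units Unit tibble (see module header) with `spike_times`,
#'   `probe_id`.
#' @param ripple_starts Ripple start times, seconds.
#' @param bin_s Histogram bin, seconds (default 10 ms).
#' @param half_window_s Half-width of the histogram window, seconds.
#' @return Tibble `probe_id`, `time_ms` (bin centre relative to ripple
#'   start), `mean_count` (spikes per bin per ripple, summed over the
#'   probe's clusters).
#' @export
peri_ripple_histogram <- function(units, ripple_starts, bin_s = 0.01,
                                  half_window_s = 0.25) {
  if (length(ripple_starts) == 0) {
    abort("no qualifying ripples for the peri-ripple histogram")
  }
  edges <- seq(-half_window_s, half_window_s, by = bin_s)
  nb <- length(edges) - 1
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  out <- units |>
    group_by(.data$probe_id) |>
    summarise(counts = {
      all_spikes <- sort(unlist(spike_times))
      acc <- numeric(nb)
      for (s in ripple_starts) {
        lo <- findInterval(s - half_window_s, all_spikes, left.open = TRUE) + 1
        hi <- findInterval(s + half_window_s, all_spikes)
        if (hi >= lo) {
          rel <- all_spikes[lo:hi] - s
          b <- pmin(nb, pmax(1L, floor((rel + half_window_s) / bin_s) + 1L))
          acc <- acc + tabulate(b, nbins = nb)
        }
      }
      list(acc / length(ripple_starts))
    }, .groups = "drop") |>
    unnest("counts") |>
    group_by(.data$probe_id) |>
    mutate(time_ms = centres * 1000) |>
    ungroup() |>
    rename(mean_count = "counts")
  out[, c("probe_id", "time_ms", "mean_count")]
}

#' Medial-minus-lateral seed difference map
#'
#' Difference between the peri-ripple histograms of medially and laterally
#' seeded ripples, interpolated over the medio-lateral axis onto a common
#' grid for every time bin. Positive values mean more spiking during
#' medially generated ripples.
#'
#' @param hist_medial,hist_lateral Histograms from [peri_ripple_histogram()]
#'   on identical time grids.
#' @param probe_ml Tibble `probe_id`, `ml`.
#' @param grid_n Number of M-L grid points (no extrapolation).
#' @return Tibble `ml`, `time_ms`, `diff_count`.
#' @export
seed_difference_map <- function(hist_medial, hist_lateral, probe_ml,
                                grid_n = 50) {
  if (!identical(sort(unique(hist_medial$time_ms)),
                 sort(unique(hist_lateral$time_ms)))) {
    abort("histograms must share the same time grid")
  }
  diff_df <- inner_join(hist_medial, hist_lateral,
                        by = c("probe_id", "time_ms"),
                        suffix = c("_med", "_lat")) |>
    mutate(diff_count = .data$mean_count_med - .data$mean_count_lat) |>
    left_join(probe_ml, by = "probe_id")
  if (length(unique(diff_df$probe_id)) < 2) {
    # single probe: column map, no spatial interpolation
    return(diff_df[, c("ml", "time_ms", "diff_count")])
  }
  interpolate_ml(diff_df, "diff_count", grid = grid_n, groups = "time_ms")[,
    c("ml", "time_ms", "diff_count")]
}

#' Fraction of active neurons per ripple
#'
#' For every ripple, the fraction of clusters firing at least one spike in a
#' window anchored at ripple start (0-120 ms by default). Clusters should be
#' restricted to the hippocampal formation upstream (see `areas`).
#'
#' @param units Unit tibble.
#' @param ripple_starts Ripple start times, seconds.
#' @param window Window relative to ripple start, seconds.
#' @param areas Restrict to these areas first (default: hippocampal
#'   formation); `NULL` keeps all clusters.
#' @return Tibble `ripple_start_s`, `active_fraction`; mean and standard
#'   error over ripples in attributes `"mean"` and `"se"`.
#' @export
active_fraction <- function(units, ripple_starts, window = c(0, 0.12),
                            areas = HPF_AREAS) {
  if (!is.null(areas)) units <- filter(units, .data$area %in% areas)
  if (nrow(units) == 0) abort("no clusters after area restriction")
  active <- vapply(units$spike_times, function(sp) {
    spike_counts_in_windows(sp, ripple_starts, window) > 0
  }, logical(length(ripple_starts)))
  if (length(ripple_starts) == 1) active <- matrix(active, nrow = 1)
  frac <- rowMeans(active)
  out <- tibble(ripple_start_s = ripple_starts, active_fraction = frac)
  attr(out, "mean") <- mean(frac)
  attr(out, "se") <- sd(frac) / sqrt(length(frac))
  out
}

#' Per-cluster spiking rate during ripples
#'
#' Spikes in the window divided by the window length, averaged over ripples
#' within each cluster; the grand mean then averages over clusters.
#'
#' @inheritParams active_fraction
#' @return Tibble `cluster_id`, `rate_hz` (one row per cluster); grand mean
#'   over clusters in attribute `"mean"`.
#' @export
ripple_spike_rate <- function(units, ripple_starts, window = c(0, 0.12),
                              areas = HPF_AREAS) {
  if (!is.null(areas)) units <- filter(units, .data$area %in% areas)
  if (nrow(units) == 0) abort("no clusters after area restriction")
  len <- diff(window)
  rates <- vapply(units$spike_times, function(sp) {
    mean(spike_counts_in_windows(sp, ripple_starts, window)) / len
  }, numeric(1))
  out <- tibble(cluster_id = units$cluster_id, rate_hz = rates)
  attr(out, "mean") <- mean(rates)
  out
}

#' Putative excitatory / inhibitory split by waveform duration
#'
#' Labels clusters with waveform duration at or below `threshold_ms` as
#' putative inhibitory (narrow-spiking) and the rest as putative excitatory.
#' Clusters with missing duration stay unlabelled (`NA`) and should be
#' excluded from E/I-split analyses.
#'
#' @param units Unit tibble with `waveform_duration_ms`.
#' @param threshold_ms Duration threshold, milliseconds.
#' @return `units` with a `putative_class` column
#'   (`"putative_inhibitory"` / `"putative_excitatory"` / `NA`).
#' @export
split_putative_ei <- function(units, threshold_ms = 0.4) {
  units |>
    mutate(putative_class = dplyr::case_when(
      is.na(.data$waveform_duration_ms) ~ NA_character_,
      .data$waveform_duration_ms <= threshold_ms ~ "putative_inhibitory",
      .default = "putative_excitatory"))
}
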