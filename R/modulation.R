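# Ripple modulation of sorted units by seed type (medial vs lateral).

#' Default analysis windows relative to ripple start (seconds)
#'
#' `full` 0-120 ms, `early` 0-50 ms, `late` 50-120 ms, `pre` -20-0 ms;
#' the baseline window is the 120 ms before ripple start.
#'
#' @return Named list of 2-vectors.
#' @export
modulation_windows <- function() {
  list(full = c(0, 0.12), early = c(0, 0.05), late = c(0.05, 0.12),
       pre = c(-0.02, 0))
}

#' Quality-control filter for sorted units
#'
#' Keeps clusters with waveform peak-trough ratio < 5, ISI violations < 0.5,
#' amplitude cutoff < 0.1, presence ratio > 0.1, and (for modulation
#' analyses) firing rate > 0.1 spikes/s. Exclusion counts per criterion are
#' attached as attribute `"qc_counts"`.
#'
#' @param units Unit tibble with columns `peak_trough_ratio`,
#'   `isi_violations`, `amplitude_cutoff`, `presence_ratio`, `firing_rate`.
#' @param min_firing_rate Firing-rate floor (Hz); `NULL` skips it.
#' @return Filtered unit tibble.
#' @export
qc_filter <- function(units, min_firing_rate = 0.1) {
  checks <- list(
    peak_trough_ratio = units$peak_trough_ratio < 5,
    isi_violations = units$isi_violations < 0.5,
    amplitude_cutoff = units$amplitude_cutoff < 0.1,
    presence_ratio = units$presence_ratio > 0.1)
  if (!is.null(min_firing_rate)) {
    checks$firing_rate <- units$firing_rate > min_firing_rate
  }
  fails <- vapply(checks, function(ok) sum(!ok, na.rm = TRUE), integer(1))
  keep <- Reduce(`&`, lapply(checks, function(ok) !is.na(ok) & ok))
  out <- units[keep, ]
  attr(out, "qc_counts") <- fails
  out
}

#' Ripple modulation index per cluster, seed type and window
#'
#' For each cluster and seed type, spiking rates are computed per window as
#' the mean over that seed type's ripples of spikes-in-window / window
#' length; the baseline rate uses the 120 ms before ripple start. The
#' modulation index is `(ripple rate - baseline rate) / baseline rate`.
#'
#' @param units QC-filtered unit tibble (see [qc_filter()]).
#' @param ripples Tibble with `start_s` and `seed_section` (values `medial` /
#'   `lateral`; others are dropped), already restricted to well-propagating
#'   clusters (spatial engagement > 0.5) upstream.
#' @param windows Named list of windows, see [modulation_windows()].
#' @param baseline_window Baseline window relative to ripple start.
#' @return Long tibble: `cluster_id`, `area`, `ml`, `seed_type`, `window`,
#'   `rate_hz`, `baseline_hz`, `modulation`. Clusters with zero baseline
#'   rate get `NA` modulation (flagged with a warning).
#' @export
modulation_index <- function(units, ripples, windows = modulation_windows(),
                             baseline_window = c(-0.12, 0)) {
  ripples <- filter(ripples, .data$seed_section %in% c("medial", "lateral"))
  if (nrow(ripples) == 0) abort("no medial/lateral-seeded ripples")
  seed_types <- split(ripples$start_s, as.character(ripples$seed_section))
  base_len <- diff(baseline_window)
  rows <- lapply(names(seed_types), function(st) {
    starts <- seed_types[[st]]
    base <- vapply(units$spike_times, function(sp) {
      mean(spike_counts_in_windows(sp, starts, baseline_window)) / base_len
    }, numeric(1))
    per_win <- lapply(names(windows), function(w) {
      len <- diff(windows[[w]])
      rate <- vapply(units$spike_times, function(sp) {
        mean(spike_counts_in_windows(sp, starts, windows[[w]])) / len
      }, numeric(1))
      tibble(cluster_id = units$cluster_id, area = units$area,
             ml = units$ml, seed_type = st, window = w,
             rate_hz = rate, baseline_hz = base,
             modulation = ifelse(base > 0, (rate - base) / base, NA_real_))
    })
    list_rbind(per_win)
  })
  out <- list_rbind(rows)
  if (anyNA(out$modulation)) {
    warn("clusters with zero baseline rate: modulation undefined (NA)")
  }
  out
}

mod_wide <- function(records, window) {
  records |>
    filter(.data$window == !!window) |>
    select("cluster_id", "area", "ml", "seed_type", "modulation") |>
    pivot_wider(names_from = "seed_type", values_from = "modulation",
                names_prefix = "modulation_")
}

#' Flag ripple-modulated clusters
#'
#' A cluster is modulated when it shows at least a `threshold` (default 50%)
#' rate increase during either medial or lateral ripples (inclusive bound).
#'
#' @param records Long tibble from [modulation_index()].
#' @param threshold Modulation threshold.
#' @param window Window to classify on (default `full`).
#' @return Tibble, one row per cluster: `cluster_id`, `area`, `ml`,
#'   `modulation_medial`, `modulation_lateral`, `is_modulated`.
#' @export
classify_modulated <- function(records, threshold = 0.5, window = "full") {
  w <- mod_wide(records, window)
  if (!"modulation_medial" %in% names(w)) w$modulation_medial <- NA_real_
  if (!"modulation_lateral" %in% names(w)) w$modulation_lateral <- NA_real_
  w |>
    mutate(is_modulated =
             pmax(.data$modulation_medial, .data$modulation_lateral,
                  na.rm = TRUE) >= threshold)
}

#' Seed-type preference of clusters
#'
#' A cluster prefers medial ripples when its medial modulation is at least
#' `min_modulation` (50%) and at least twice the lateral modulation; the
#' ratio rule is applied as `other <= preferred / 2`, which also covers
#' non-positive comparison modulations. Lateral preference is symmetric;
#' everything else is `none`.
#'
#' @inheritParams classify_modulated
#' @param min_modulation Absolute modulation required for the preferred type.
#' @param ratio Required modulation ratio between types.
#' @return Tibble per cluster with `preference` in
#'   `c("medial", "lateral", "none")`; class fractions in
#'   `attr(, "fractions")`.
#' @export
classify_preference <- function(records, min_modulation = 0.5, ratio = 2,
                                window = "full") {
  w <- mod_wide(records, window)
  pref <- dplyr::case_when(
    w$modulation_medial >= min_modulation &
      w$modulation_lateral <= w$modulation_medial / ratio ~ "medial",
    w$modulation_lateral >= min_modulation &
      w$modulation_medial <= w$modulation_lateral / ratio ~ "lateral",
    .default = "none")
  w$preference <- factor(pref, levels = c("medial", "lateral", "none"))
  attr(w, "fractions") <- prop.table(table(w$preference))
  w
}

#' Variance in seed-contrast modulation explained by M-L position
#'
#' Per area (hippocampal subfield) and window, the fraction of variance in
#' the medial-minus-lateral modulation contrast explained by the cluster's
#' medio-lateral position (OLS R^2). Set `contrast = FALSE` to regress raw
#' modulation (pooled over seed types) instead.
#'
#' @param records Long tibble from [modulation_index()].
#' @param window Window name.
#' @param areas Areas to fit (default: those present).
#' @param contrast Use the medial-lateral contrast (default) or raw
#'   modulation.
#' @return Tibble `area`, `window`, `r_squared`, `p_value`, `n`.
#' @export
ml_variance_explained <- function(records, window = "early", areas = NULL,
                                  contrast = TRUE) {
  w <- mod_wide(records, window)
  if (contrast) {
    w$response <- w$modulation_medial - w$modulation_lateral
  } else {
    w$response <- (w$modulation_medial + w$modulation_lateral) / 2
  }
  if (is.null(areas)) areas <- unique(w$area)
  rows <- lapply(areas, function(a) {
    sub <- w[w$area == a & complete.cases(w[, c("response", "ml")]), ]
    if (nrow(sub) < 4 || var(sub$ml) == 0) {
      return(tibble(area = a, window = window, r_squared = NA_real_,
                    p_value = NA_real_, n = nrow(sub)))
    }
    fit <- axis_variance_explained(sub, "response", "ml")
    tibble(area = a, window = window, r_squared = fit$r_squared,
           p_value = glance(fit)$p.value, n = fit$n)
  })
  list_rbind(rows)
}

#' Baseline-vs-ripple rate table
#'
#' Per cluster, the baseline and full-window ripple rates averaged between
#' responses to medial and lateral ripples (the identity-line scatter of
#' modulated vs unmodulated regions).
#'
#' @param records Long tibble from [modulation_index()].
#' @return Tibble `cluster_id`, `area`, `baseline_hz`, `ripple_hz`.
#' @export
baseline_ripple_rates <- function(records) {
  records |>
    filter(.data$window == "full") |>
    group_by(.data$cluster_id, .data$area) |>
    summarise(baseline_hz = mean(.data$baseline_hz),
              ripple_hz = mean(.data$rate_hz), .groups = "drop")
}
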