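# Ground-truth benchmarking utilities: score pipeline output against the
# simulator's truth tables.

match_to_truth <- function(detected_starts, true_starts, tol_s = 0.02) {
  # index of the nearest true start within tol, NA otherwise
  if (length(true_starts) == 0) return(rep(NA_integer_, length(detected_starts)))
  vapply(detected_starts, function(s) {
    i <- which.min(abs(true_starts - s))
    if (abs(true_starts[i] - s) <= tol_s) i else NA_integer_
  }, integer(1))
}

#' Score detected ripples against simulator ground truth
#'
#' Recall is computed over true events whose injected amplitude is at least
#' `min_amplitude_sd` (on that probe) outside running bouts; precision over
#' all detected events against all true events; the start error over
#' recalled events.
#'
#' @param events Detected events ([detect_all_probes()] output).
#' @param truth_by_probe The session's `truth$by_probe` table.
#' @param min_amplitude_sd Amplitude floor (envelope SD units) defining the
#'   events recall is measured on.
#' @param tol_s Matching tolerance, seconds.
#' @return One-row tibble: `recall`, `precision`, `median_start_error_ms`,
#'   `n_true`, `n_detected`.
#' @export
evaluate_detection <- function(events, truth_by_probe, min_amplitude_sd = 7,
                               tol_s = 0.02) {
  target <- truth_by_probe[truth_by_probe$amplitude_sd >= min_amplitude_sd &
                             !truth_by_probe$during_running, ]
  hits <- numeric(0)
  errors <- numeric(0)
  for (p in unique(target$probe_id)) {
    tr <- target[target$probe_id == p, ]
    de <- events$start_s[events$probe_id == p]
    err <- vapply(tr$start_s, function(t) {
      if (length(de) == 0) return(NA_real_)
      d <- de - t
      d[which.min(abs(d))]
    }, numeric(1))
    hit <- !is.na(err) & abs(err) <= tol_s
    hits <- c(hits, hit)
    errors <- c(errors, err[hit])
  }
  # precision: every detected event should sit near some true event
  prec <- vapply(seq_len(nrow(events)), function(i) {
    tr <- truth_by_probe$start_s[
      truth_by_probe$probe_id == events$probe_id[i]]
    length(tr) > 0 && min(abs(tr - events$start_s[i])) <= tol_s
  }, logical(1))
  tibble(recall = mean(hits), precision = mean(prec),
         median_start_error_ms = stats::median(abs(errors)) * 1000,
         n_true = length(hits), n_detected = nrow(events))
}

#' Score pairwise lag recovery against ground truth
#'
#' Matches each reference ripple of the most medial / most lateral probe
#' pair to its true event, and compares the recovered nearest-neighbour lag
#' with the true per-event lag (difference of injected start times).
#'
#' @param events Detected events across probes.
#' @param truth_by_probe The session's `truth$by_probe` table.
#' @param probes Character vector of two probe ids (reference, target);
#'   default: most medial and most lateral probes with events.
#' @param half_window_s Matching half-window.
#' @return One-row tibble: `median_lag_error_ms`, `median_abs_swap_sum_ms`
#'   (median of lag(a->b) + lag(b->a) over events matched both ways; 0 under
#'   perfect antisymmetry), `n_matched`.
#' @export
evaluate_lag_recovery <- function(events, truth_by_probe, probes = NULL,
                                  half_window_s = 0.06) {
  bp <- truth_by_probe
  if (is.null(probes)) {
    ml_of <- tapply(bp$ml, bp$probe_id, unique)
    with_events <- intersect(names(sort(ml_of)), unique(events$probe_id))
    probes <- c(with_events[1], with_events[length(with_events)])
  }
  ref <- sort(events$start_s[events$probe_id == probes[1]])
  tgt <- sort(events$start_s[events$probe_id == probes[2]])
  lags <- nearest_neighbor_lags(ref, tgt, half_window_s)
  # true lag per matched reference event
  tr_ref <- bp[bp$probe_id == probes[1], ]
  tr_tgt <- bp[bp$probe_id == probes[2], ]
  idx <- match_to_truth(lags$ref_start_s, tr_ref$start_s)
  true_lag <- (tr_tgt$start_s[match(tr_ref$event_id[idx], tr_tgt$event_id)] -
                 tr_ref$start_s[idx]) * 1000
  ok <- lags$matched & !is.na(true_lag)
  err <- lags$lag_ms[ok] - true_lag[ok]
  # antisymmetry under reference swap
  swap <- nearest_neighbor_lags(tgt, ref, half_window_s)
  sum_ab <- vapply(which(lags$matched), function(i) {
    t_t <- lags$ref_start_s[i] + lags$lag_ms[i] / 1000
    j <- which(abs(swap$ref_start_s - t_t) < 1e-6)
    if (length(j) == 1 && isTRUE(swap$matched[j])) {
      lags$lag_ms[i] + swap$lag_ms[j]
    } else NA_real_
  }, numeric(1))
  tibble(median_lag_error_ms = stats::median(err),
         median_abs_swap_sum_ms = stats::median(abs(sum_ab), na.rm = TRUE),
         n_matched = sum(ok))
}

#' Score seed-section recovery against ground truth
#'
#' Builds propagation clusters from the detected events, keeps those with
#' spatial engagement above 0.5, and compares each recovered seed section
#' with the generator's seed label of the matched true event.
#'
#' @param events Detected events across probes.
#' @param truth The session's `truth` list.
#' @param min_engagement Engagement floor for scored clusters.
#' @return List with `accuracy`, `n_clusters`, `clusters` (scored tibble)
#'   and `sections`.
#' @export
evaluate_seed_recovery <- function(events, truth, min_engagement = 0.5) {
  sections <- truth$sections
  ref_counts <- table(events$probe_id)
  ref_probe <- names(ref_counts)[which.max(ref_counts)]
  ref_events <- events[events$probe_id == ref_probe, ]
  ref_events <- ref_events[order(ref_events$start_s), ]
  members <- build_clusters(ref_events, events)
  clusters <- summarize_clusters(members, sections,
                                 detecting_probes = names(ref_counts))
  clusters <- clusters[clusters$spatial_engagement > min_engagement, ]
  tr <- truth$by_probe[truth$by_probe$probe_id == ref_probe, ]
  idx <- match_to_truth(clusters$ref_start_s, tr$start_s)
  clusters$true_seed_section <- tr$seed_section[idx]
  scored <- clusters[!is.na(idx), ]
  list(accuracy = mean(as.character(scored$seed_section) ==
                         scored$true_seed_section),
       n_clusters = nrow(scored), clusters = scored, sections = sections)
}

#' Modulated fraction per region group
#'
#' Convenience wrapper: QC-filter units, compute modulation indices for the
#' given seed-labelled ripples, and report the fraction of clusters
#' classified as ripple-modulated per region group.
#'
#' @param units Unit tibble (with a `region_group` column from the
#'   generator, or `area` used as the group).
#' @param ripples Tibble with `start_s` and `seed_section`.
#' @return Tibble `region_group`, `modulated_fraction`, `n`.
#' @export
modulated_fraction_by_region <- function(units, ripples) {
  units <- qc_filter(units)
  grp <- units$region_group %||% units$area
  records <- modulation_index(units, ripples)
  flags <- classify_modulated(records)
  flags$region_group <- grp[match(flags$cluster_id, units$cluster_id)]
  flags |>
    group_by(.data$region_group) |>
    summarise(modulated_fraction = mean(.data$is_modulated), n = n(),
              .groups = "drop")
}
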