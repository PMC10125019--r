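#' Track reference ripples across probes
#'
#' Groups, for every ripple on the reference channel, the ripples detected on
#' the other probes within a +/- `half_window_s` window of its start into a
#' propagation cluster. When a probe has several events inside the window
#' only the first (earliest) is kept.
#'
#' @param reference_events Event tibble of the reference channel
#'   (needs `start_s`; `is_strong` is carried through if present).
#' @param events_by_probe Event tibble across probes (needs `probe_id`,
#'   `start_s`, `strength`, `duration_s`), including the reference probe.
#' @param half_window_s Matching half-window, seconds.
#' @return Long tibble, one row per cluster member: `cluster_id`,
#'   `ref_start_s`, `is_strong` (reference label, if available), `probe_id`,
#'   `start_s`, `lag_ms`, `strength`, `duration_s`.
#' @export
build_clusters <- function(reference_events, events_by_probe,
                           half_window_s = 0.06) {
  probes <- unique(events_by_probe$probe_id)
  ref <- arrange(reference_events, .data$start_s)
  has_strong <- "is_strong" %in% names(ref)
  members <- lapply(probes, function(p) {
    ev <- events_by_probe |>
      filter(.data$probe_id == p) |>
      arrange(.data$start_s)
    if (nrow(ev) == 0) return(NULL)
    # first event in [ref - w, ref + w] per reference ripple
    lo <- findInterval(ref$start_s - half_window_s, ev$start_s,
                       left.open = TRUE) + 1
    ok <- lo <= nrow(ev) & ev$start_s[pmin(lo, nrow(ev))] <=
      ref$start_s + half_window_s
    i <- which(ok)
    if (length(i) == 0) return(NULL)
    tibble(cluster_id = i,
           ref_start_s = ref$start_s[i],
           is_strong = if (has_strong) ref$is_strong[i] else NA,
           probe_id = p,
           start_s = ev$start_s[lo[i]],
           lag_ms = (ev$start_s[lo[i]] - ref$start_s[i]) * 1000,
           strength = ev$strength[lo[i]],
           duration_s = ev$duration_s[lo[i]])
  })
  list_rbind(members) |> arrange(.data$cluster_id, .data$probe_id)
}

#' Identify the seed of each propagation cluster
#'
#' The seed is the member with the earliest start time; ties resolve to the
#' more medial probe.
#'
#' @param members Long cluster tibble from [build_clusters()].
#' @param sections Section assignment from [assign_sections()] (needs
#'   `probe_id`, `ml`, `section`).
#' @return Tibble, one row per cluster: `cluster_id`, `seed_probe`,
#'   `seed_section`, `seed_ml`, `seed_lag_ms`.
#' @export
identify_seeds <- function(members, sections) {
  members |>
    left_join(select(sections, "probe_id", "ml", "section"), by = "probe_id") |>
    group_by(.data$cluster_id) |>
    arrange(.data$start_s, .data$ml, .by_group = TRUE) |>
    summarise(seed_probe = first(.data$probe_id),
              seed_section = first(.data$section),
              seed_ml = first(.data$ml),
              seed_lag_ms = first(.data$lag_ms),
              .groups = "drop")
}

#' Per-section strength thresholds
#'
#' For each medio-lateral section, the 90th percentile of ripple strength on
#' the section's channel with the strongest ripple activity (the probe with
#' the most detected events), over the whole session. These thresholds define
#' "top 10% strength" section-wise for the strength conservation index.
#'
#' @param events_by_probe Session event tibble (`probe_id`, `strength`).
#' @param sections Section assignment from [assign_sections()].
#' @return Tibble `section`, `reference_probe`, `threshold`.
#' @export
section_strength_thresholds <- function(events_by_probe, sections) {
  events_by_probe |>
    left_join(select(sections, "probe_id", "section"), by = "probe_id") |>
    filter(!is.na(.data$section)) |>
    group_by(.data$section, .data$probe_id) |>
    summarise(n = n(), strengths = list(.data$strength), .groups = "drop") |>
    group_by(.data$section) |>
    arrange(dplyr::desc(.data$n), .by_group = TRUE) |>
    summarise(reference_probe = first(.data$probe_id),
              threshold = quantile(first(.data$strengths), 0.9, names = FALSE),
              .groups = "drop")
}

#' Summarise propagation clusters
#'
#' One row per cluster with its seed, spatial engagement (members /
#' ripple-detecting probes), strength conservation index (fraction of
#' detecting sections in which the cluster stays in the section's top 10% of
#' strength) and propagation speed (slope of member M-L position on lag,
#' µm/ms; requires at least 3 members spanning 2 sections and a lag range of
#' at least `min_lag_range_ms`, otherwise `NA`).
#'
#' @param members Long cluster tibble from [build_clusters()].
#' @param sections Section assignment from [assign_sections()].
#' @param thresholds Tibble from [section_strength_thresholds()]; computed
#'   from `members`' events if `NULL` (pass the full session event table for
#'   the faithful definition).
#' @param detecting_probes Probes with ripple activity in the session;
#'   defaults to the probes present in `members`.
#' @param min_lag_range_ms Minimum lag spread for a defined speed.
#' @return Tibble, one row per cluster, with `seed_*` columns,
#'   `spatial_engagement`, `sci`, `speed_um_per_ms`, `n_members`,
#'   `is_strong`.
#' @export
summarize_clusters <- function(members, sections, thresholds = NULL,
                               detecting_probes = NULL,
                               min_lag_range_ms = 1) {
  if (is.null(detecting_probes)) detecting_probes <- unique(members$probe_id)
  n_detecting <- length(detecting_probes)
  sec_of <- stats::setNames(as.character(sections$section), sections$probe_id)
  detecting_sections <- unique(sec_of[detecting_probes])
  detecting_sections <- detecting_sections[!is.na(detecting_sections)]
  if (is.null(thresholds)) {
    thresholds <- section_strength_thresholds(members, sections)
  }
  thr_of <- stats::setNames(thresholds$threshold,
                            as.character(thresholds$section))
  seeds <- identify_seeds(members, sections)
  mem <- members |>
    left_join(select(sections, "probe_id", "ml", "section"), by = "probe_id")
  per <- mem |>
    group_by(.data$cluster_id) |>
    summarise(
      ref_start_s = first(.data$ref_start_s),
      is_strong = first(.data$is_strong),
      n_members = n(),
      spatial_engagement = n() / n_detecting,
      sci = {
        sec <- as.character(section)
        above <- tapply(strength > thr_of[sec], sec, any)
        sum(above, na.rm = TRUE) / length(detecting_sections)
      },
      speed_um_per_ms = {
        ok <- n() >= 3 && length(unique(section)) >= 2 &&
          diff(range(lag_ms)) >= min_lag_range_ms
        if (ok) unname(coef(lm(ml ~ lag_ms))[2]) else NA_real_
      },
      .groups = "drop")
  left_join(per, seeds, by = "cluster_id")
}

#' Average spatio-temporal propagation map
#'
#' Mean lag per probe (optionally split by the reference strong/common
#' label), i.e. the session's propagation map along the medio-lateral axis.
#'
#' @param members Long cluster tibble from [build_clusters()].
#' @param sections Section assignment (for probe M-L positions).
#' @param by_class Split by the reference `is_strong` label.
#' @return Tibble `probe_id`, `ml`, (`class`), `mean_lag_ms`, `n`.
#' @export
propagation_map <- function(members, sections, by_class = TRUE) {
  mem <- members |>
    left_join(select(sections, "probe_id", "ml"), by = "probe_id")
  grouping <- if (by_class && !all(is.na(mem$is_strong))) {
    mem |> mutate(class = if_else(.data$is_strong, "strong", "common")) |>
      group_by(.data$probe_id, .data$ml, .data$class)
  } else {
    group_by(mem, .data$probe_id, .data$ml)
  }
  grouping |>
    summarise(mean_lag_ms = mean(.data$lag_ms), n = n(), .groups = "drop") |>
    arrange(.data$ml)
}

#' Interpolate per-probe profiles onto a common M-L grid
#'
#' Linear interpolation of a per-probe quantity onto an evenly spaced
#' medio-lateral grid spanning the observed range; no extrapolation (grid
#' points outside a session's probe range are `NA`), so maps from sessions
#' with different probe geometries can be averaged.
#'
#' @param data Tibble with `ml` and a value column.
#' @param value Name of the value column.
#' @param grid Either a number of grid points (default 50) or the grid
#'   itself.
#' @param groups Optional column names to interpolate within.
#' @return Tibble `ml`, (`groups`), `value`.
#' @export
interpolate_ml <- function(data, value, grid = 50, groups = NULL) {
  if (length(grid) == 1) {
    grid <- seq(min(data$ml), max(data$ml), length.out = grid)
  }
  interp_one <- function(df) {
    if (nrow(df) < 2) {
      return(tibble(ml = grid, value = NA_real_))
    }
    tibble(ml = grid,
           value = approx(df$ml, df[[value]], xout = grid, rule = 1,
                          ties = mean)$y)
  }
  if (is.null(groups)) {
    out <- interp_one(data)
  } else {
    out <- data |>
      group_by(across(dplyr::all_of(groups))) |>
      dplyr::group_modify(~ interp_one(.x)) |>
      ungroup()
  }
  rename(out, !!value := "value")
}

#' Partial correlation of lag with each anatomical axis
#'
#' Squared partial correlation of per-member lag with the medio-lateral and
#' antero-posterior coordinates, each controlling for the other axis, with
#' t-test p-values. Quantifies which axis carries the propagation gradient.
#'
#' @param data Tibble with columns `lag_ms`, `ml`, `ap`.
#' @return Tibble `axis`, `r_partial`, `r_squared`, `p_value`, `n`.
#' @export
axis_partial_correlation <- function(data) {
  data <- as_tibble(data)[, c("lag_ms", "ml", "ap")]
  data <- data[complete.cases(data), ]
  n <- nrow(data)
  if (n < 4) abort("need at least 4 complete observations")
  if (var(data$ml) == 0 || var(data$ap) == 0) {
    abort("both coordinates must vary")
  }
  r_xy <- cor(data$lag_ms, data$ml)
  r_xz <- cor(data$lag_ms, data$ap)
  r_yz <- cor(data$ml, data$ap)
  if (abs(r_yz) > 1 - 1e-12) abort("axes are collinear; partial r undefined")
  pc <- function(rxy, rxz, ryz) {
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  r_ml <- pc(r_xy, r_xz, r_yz)
  r_ap <- pc(r_xz, r_xy, r_yz)
  pval <- function(r) {
    tt <- r * sqrt((n - 3) / pmax(1e-300, 1 - r^2))
    2 * pt(abs(tt), df = n - 3, lower.tail = FALSE)
  }
  tibble(axis = c("ml", "ap"),
         r_partial = c(r_ml, r_ap),
         r_squared = c(r_ml^2, r_ap^2),
         p_value = c(pval(r_ml), pval(r_ap)),
         n = n)
}
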