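#' Per-ripple strength on every channel
#'
#' For each reference ripple start, integrates the band-passed envelope of
#' every (non-excluded) channel over a broad window around the start (100 ms
#' before to 200 ms after by default, accommodating travel delays). This is
#' the per-ripple, per-channel ripple strength used for the pairwise
#' strength-correlation analysis.
#'
#' @param rec [lfp_recording()].
#' @param ripple_starts Reference ripple start times, seconds.
#' @param params [detection_params()].
#' @param window Window around each start, seconds (c(before, after)).
#' @param area Restrict to channels of this area (default CA1).
#' @return Matrix, ripples x channels, with channel ids as colnames and the
#'   per-channel envelope variance attached as attribute `"env_var"`.
#' @export
per_ripple_strengths <- function(rec, ripple_starts,
                                 params = detection_params(),
                                 window = c(-0.1, 0.2), area = "CA1") {
  info <- rec$channel_info
  idx <- which(!info$excluded & info$area == area)
  if (length(idx) == 0) abort(paste0("no usable channels in area ", area))
  fs <- rec$sampling_rate
  n <- ncol(rec$samples)
  i0 <- pmax(1, round((ripple_starts - rec$start_time + window[1]) * fs) + 1)
  i1 <- pmin(n, round((ripple_starts - rec$start_time + window[2]) * fs))
  out <- matrix(NA_real_, length(ripple_starts), length(idx),
                dimnames = list(NULL, info$channel_id[idx]))
  env_var <- numeric(length(idx))
  for (j in seq_along(idx)) {
    env <- ripple_envelope(
      ripple_bandpass(rec$samples[idx[j], ], fs, params))
    env_var[j] <- var(env[!rec$artifact_mask])
    cum <- c(0, cumsum((env[-1] + env[-n]) / 2) / fs)  # trapezoid prefix sums
    out[, j] <- cum[i1] - cum[i0]
  }
  attr(out, "env_var") <- stats::setNames(env_var, info$channel_id[idx])
  out
}

#' Pairwise ripple-strength correlation matrix
#'
#' Pearson correlation, across ripples, of per-ripple strength between
#' channel pairs. Channels with weak ripple activity (envelope variance below
#' `min_env_variance`, in the recording's native units squared) are
#' discarded first.
#'
#' @param strengths Ripples x channels matrix from [per_ripple_strengths()].
#' @param min_env_variance Channel activity filter threshold; set to `NULL`
#'   to skip (e.g. when `strengths` lacks the `env_var` attribute).
#' @return Symmetric correlation matrix (diagonal 1). Pairs with fewer than
#'   3 complete ripples are `NA`.
#' @export
strength_correlation <- function(strengths, min_env_variance = 5) {
  ev <- attr(strengths, "env_var")
  if (!is.null(min_env_variance) && !is.null(ev)) {
    strengths <- strengths[, ev >= min_env_variance, drop = FALSE]
  }
  if (ncol(strengths) < 2) abort("need at least 2 channels after filtering")
  if (nrow(strengths) < 3) abort("need at least 3 ripples")
  r <- stats::cor(strengths, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Pair table from a correlation matrix and channel positions
#'
#' One row per unordered channel pair, with the more medial channel as the
#' reference, the 3D distance, and the strength correlation.
#'
#' @param corr Correlation matrix from [strength_correlation()].
#' @param channels Channel metadata with CCF coordinates.
#' @return Tibble `reference_channel`, `target_channel`, `distance_um`,
#'   `strength_correlation`.
#' @export
pair_records <- function(corr, channels) {
  channels <- as_channel_info(channels)
  ids <- colnames(corr)
  pos <- channels[match(ids, channels$channel_id), ]
  d <- pairwise_distances(pos)
  pairs <- which(upper.tri(corr), arr.ind = TRUE)
  a <- ids[pairs[, 1]]; b <- ids[pairs[, 2]]
  ml_a <- pos$ml[pairs[, 1]]; ml_b <- pos$ml[pairs[, 2]]
  swap <- ml_b < ml_a
  tibble(
    reference_channel = ifelse(swap, b, a),
    target_channel = ifelse(swap, a, b),
    distance_um = d[pairs],
    strength_correlation = corr[pairs])
}

#' Regression of strength correlation on distance
#'
#' Ordinary least squares of the pairwise strength correlation on the
#' distance between recording sites, quantifying how much of the correlation
#' variability distance explains.
#'
#' @param pairs Tibble from [pair_records()] (needs `distance_um` and
#'   `strength_correlation`).
#' @return A `ripple_fit` object; see [tidy()] / [glance()]. `$r_squared`,
#'   `$slope` and `$intercept` are directly accessible.
#' @export
distance_regression <- function(pairs) {
  if (nrow(pairs) < 3) abort("need at least 3 pairs")
  if (var(pairs$distance_um) == 0) abort("degenerate distance variance")
  fit <- lm(strength_correlation ~ distance_um, data = pairs)
  new_ripple_fit(fit, "strength correlation ~ distance")
}

#' Classify pairs as short / mid / long distance
#'
#' Distance classes from the quantiles (default 25% and 75%, linear
#' interpolation) of all pair distances: short below the lower quantile,
#' long above the upper, mid otherwise.
#'
#' @param pairs Tibble with `distance_um`.
#' @param probs Two quantile probabilities.
#' @return `pairs` with a `distance_class` factor column; the thresholds are
#'   in `attr(, "thresholds")`.
#' @export
classify_pair_distance <- function(pairs, probs = c(0.25, 0.75)) {
  if (nrow(pairs) < 4) abort("need at least 4 pairs")
  q <- quantile(pairs$distance_um, probs, names = FALSE, type = 7)
  cls <- dplyr::case_when(
    pairs$distance_um < q[1] ~ "short",
    pairs$distance_um > q[2] ~ "long",
    .default = "mid")
  pairs$distance_class <- factor(cls, levels = c("short", "mid", "long"))
  attr(pairs, "thresholds") <- q
  pairs
}

#' Nearest-neighbour ripple lags between two channels
#'
#' For each reference ripple, finds the nearest target-channel ripple start
#' within a +/- `half_window_s` window (120 ms total by default) and reports
#' the lag `start_target - start_reference` in milliseconds. The reference
#' should be the more medial site of the pair, so positive lags mean
#' medial-to-lateral travel. Equidistant candidates resolve to the earlier
#' target event.
#'
#' @param reference_starts,target_starts Sorted ripple start times, seconds.
#' @param half_window_s Matching half-window, seconds.
#' @return Tibble, one row per reference ripple: `ref_start_s`, `lag_ms`,
#'   `matched`. The fraction of matched reference ripples is in
#'   `attr(, "propagation_fraction")`.
#' @export
nearest_neighbor_lags <- function(reference_starts, target_starts,
                                  half_window_s = 0.06) {
  nr <- length(reference_starts)
  if (length(target_starts) == 0) {
    out <- tibble(ref_start_s = reference_starts,
                  lag_ms = rep(NA_real_, nr), matched = rep(FALSE, nr))
    attr(out, "propagation_fraction") <- 0
    return(out)
  }
  pos <- findInterval(reference_starts, target_starts)
  lo <- pmax(pos, 1)
  hi <- pmin(pos + 1, length(target_starts))
  d_lo <- abs(target_starts[lo] - reference_starts)
  d_hi <- abs(target_starts[hi] - reference_starts)
  d_lo[pos < 1] <- Inf
  d_hi[pos + 1 > length(target_starts)] <- Inf
  use_lo <- d_lo <= d_hi  # tie -> earlier target event
  nn <- ifelse(use_lo, lo, hi)
  lag_s <- target_starts[nn] - reference_starts
  matched <- abs(lag_s) <= half_window_s
  out <- tibble(ref_start_s = reference_starts,
                lag_ms = ifelse(matched, lag_s * 1000, NA_real_),
                matched = matched)
  attr(out, "propagation_fraction") <- mean(matched)
  out
}
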