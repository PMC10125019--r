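#' Ripple detection parameters
#'
#' Parameters of the sharp-wave-ripple detector. Defaults follow the source
#' study's pipeline: a sixth-order Butterworth band-pass between 120 and
#' 250 Hz applied forward-backward (zero phase), a Hilbert-transform envelope,
#' a 5 SD peak threshold with 2 SD boundaries on the 5-sample smoothed
#' envelope, candidates with start times closer than 50 ms merged, durations
#' gated to the open interval (0.015, 0.25) s, a constant-detrend periodogram
#' check requiring the spectral peak above `spectral_floor_hz` to exceed
#' 100 Hz, and exclusion of candidates during running (standardized speed
#' above its 10th percentile plus 0.06) or missing behaviour.
#'
#' @param band_low,band_high Band edges, Hz.
#' @param filter_order Polynomial order of the designed band-pass (per pass).
#' @param peak_threshold_sd Peak threshold, in SDs of the envelope above its
#'   mean.
#' @param boundary_threshold_sd Boundary threshold on the smoothed envelope.
#' @param smooth_window_samples Trailing moving-average window, samples.
#' @param merge_gap_s Candidates whose starts differ by less than this are
#'   merged (transitively).
#' @param min_duration_s,max_duration_s Open duration bounds, seconds.
#' @param spectral_floor_hz Lower frequency bound for the periodogram argmax.
#' @param spectral_peak_hz Accepted events must have their periodogram peak
#'   above this frequency.
#' @param speed_margin Added to the 10th percentile of standardized speed to
#'   form the running threshold.
#' @param speed_percentile Percentile (0-100) of standardized speed used for
#'   the running threshold.
#' @param threshold_mode `"mean_plus_sd"` (default) thresholds the envelope at
#'   mean + k SD; `"sd_only"` at k SD.
#' @param spectral_peak_mode `"argmax"` (default) requires the global argmax
#'   above the floor to exceed `spectral_peak_hz`; `"local_max"` accepts any
#'   local periodogram maximum above it.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(band_low = 120, band_high = 250, filter_order = 6,
                             peak_threshold_sd = 5, boundary_threshold_sd = 2,
                             smooth_window_samples = 5, merge_gap_s = 0.05,
                             min_duration_s = 0.015, max_duration_s = 0.25,
                             spectral_floor_hz = 50, spectral_peak_hz = 100,
                             speed_margin = 0.06, speed_percentile = 10,
                             threshold_mode = c("mean_plus_sd", "sd_only"),
                             spectral_peak_mode = c("argmax", "local_max")) {
  p <- list(band_low = band_low, band_high = band_high,
            filter_order = filter_order,
            peak_threshold_sd = peak_threshold_sd,
            boundary_threshold_sd = boundary_threshold_sd,
            smooth_window_samples = smooth_window_samples,
            merge_gap_s = merge_gap_s,
            min_duration_s = min_duration_s, max_duration_s = max_duration_s,
            spectral_floor_hz = spectral_floor_hz,
            spectral_peak_hz = spectral_peak_hz,
            speed_margin = speed_margin, speed_percentile = speed_percentile,
            threshold_mode = match.arg(threshold_mode),
            spectral_peak_mode = match.arg(spectral_peak_mode))
  stopifnot(p$band_low < p$band_high,
            p$min_duration_s < p$max_duration_s,
            p$peak_threshold_sd > 0, p$boundary_threshold_sd > 0,
            p$filter_order >= 2, p$filter_order %% 2 == 0)
  structure(p, class = "detection_params")
}

ripple_filter <- function(fs, params) {
  if (fs <= 2 * params$band_high) {
    abort(sprintf("sampling rate %g Hz too low for band up to %g Hz",
                  fs, params$band_high))
  }
  signal::butter(params$filter_order / 2,
                 c(params$band_low, params$band_high) / (fs / 2),
                 type = "pass")
}

#' Zero-phase ripple-band filtering
#'
#' Band-pass filters a single LFP trace with the Butterworth design of
#' `params`, applied forward and backward so event boundaries are not
#' phase-shifted.
#'
#' @param x Numeric vector, one channel of LFP.
#' @param fs Sampling rate, Hz.
#' @param params [detection_params()].
#' @return Filtered trace, same length as `x`.
#' @export
ripple_bandpass <- function(x, fs, params = detection_params()) {
  if (length(x) <= 3 * params$filter_order) abort("trace too short to filter")
  b <- ripple_filter(fs, params)
  as.numeric(signal::filtfilt(b, x))
}

#' Envelope via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal, computed by the FFT
#' construction. For lengths with large prime factors the trace is
#' mirror-padded to a 5-smooth length before the transform and truncated
#' afterwards, which leaves the envelope unchanged away from the very edges.
#'
#' @param x Numeric vector (typically a band-passed trace).
#' @return Non-negative envelope, same length as `x`.
#' @export
ripple_envelope <- function(x) {
  if (!all(is.finite(x))) abort("envelope input must be finite")
  n <- length(x)
  n2 <- stats::nextn(n, c(2, 3, 5))
  xx <- if (n2 > n) c(x, rev(x)[seq_len(n2 - n)]) else x
  m <- length(xx)
  X <- fft(xx)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1; h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((m + 1) / 2)] <- 2
  }
  env <- Mod(fft(X * h, inverse = TRUE) / m)
  env[seq_len(n)]
}

smooth_envelope <- function(env, window) {
  # trailing moving average; the first window-1 samples have no full window
  # and are treated as sub-threshold (mirrors a strict rolling window)
  sm <- as.numeric(stats::filter(env, rep(1 / window, window), sides = 1))
  sm[is.na(sm)] <- -Inf
  sm
}

envelope_thresholds <- function(env, params, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(env))
  mu <- mean(env[valid])
  s <- sd(env[valid])
  base <- if (params$threshold_mode == "mean_plus_sd") mu else 0
  list(mean = mu, sd = s,
       peak = base + params$peak_threshold_sd * s,
       boundary = base + params$boundary_threshold_sd * s)
}

#' Extract candidate ripple intervals from an envelope
#'
#' Candidate events are contiguous runs where the smoothed envelope exceeds
#' the boundary threshold (mean + 2 SD by default) that contain at least one
#' raw-envelope sample above the peak threshold (mean + 5 SD). Envelope mean
#' and SD are computed over `valid` samples only (artifact-free,
#' behaviour-covered, non-running).
#'
#' @param env Envelope of the band-passed trace.
#' @param fs Sampling rate, Hz.
#' @param params [detection_params()].
#' @param valid Logical vector of samples to use for the envelope statistics;
#'   defaults to all.
#' @param start_time Time of the first sample, seconds.
#' @return Tibble with half-open intervals `start_s`, `stop_s`.
#' @export
detect_candidates <- function(env, fs, params = detection_params(),
                              valid = NULL, start_time = 0) {
  thr <- envelope_thresholds(env, params, valid)
  if (!isTRUE(thr$sd > 0)) {
    warn("envelope has zero variance; no events detected")
    return(tibble(start_s = numeric(), stop_s = numeric()))
  }
  sm <- smooth_envelope(env, params$smooth_window_samples)
  above <- sm > thr$boundary
  r <- rle(above)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1
  begs <- begs[r$values]
  ends <- ends[r$values]
  if (length(begs) == 0) return(tibble(start_s = numeric(), stop_s = numeric()))
  keep <- vapply(seq_along(begs), function(i) {
    any(env[begs[i]:ends[i]] > thr$peak)
  }, logical(1))
  tibble(start_s = start_time + (begs[keep] - 1) / fs,
         stop_s = start_time + ends[keep] / fs)
}

#' Merge candidates with nearby start times
#'
#' Candidates whose start times differ by less than `merge_gap_s` are joined
#' transitively (chained); the merged event spans the earliest start to the
#' latest stop.
#'
#' @param candidates Tibble `start_s`, `stop_s`, sorted by start.
#' @param params [detection_params()].
#' @return Merged candidate tibble.
#' @export
merge_candidates <- function(candidates, params = detection_params()) {
  if (nrow(candidates) < 2) return(candidates)
  grp <- cumsum(c(1, diff(candidates$start_s) >= params$merge_gap_s))
  candidates |>
    group_by(grp = grp) |>
    summarise(start_s = min(.data$start_s), stop_s = max(.data$stop_s),
              .groups = "drop") |>
    select(!"grp")
}

#' Gate events by duration
#'
#' Keeps events with `min_duration_s < duration < max_duration_s` (strict
#' bounds on both sides).
#'
#' @inheritParams merge_candidates
#' @return Filtered tibble.
#' @export
gate_duration <- function(candidates, params = detection_params()) {
  dur <- candidates$stop_s - candidates$start_s
  candidates[dur > params$min_duration_s & dur < params$max_duration_s, ]
}

#' Spectral validation of a candidate event
#'
#' Computes a constant-detrended periodogram of the raw LFP between event
#' start and stop and accepts the candidate iff the frequency of maximum
#' power above `spectral_floor_hz` exceeds `spectral_peak_hz`. This guards
#' against broadband or line-noise transients that cross the amplitude
#' thresholds without ripple-band content.
#'
#' @param segment Raw LFP samples of the candidate.
#' @param fs Sampling rate, Hz.
#' @param params [detection_params()].
#' @return List with `accepted` (logical) and `peak_hz`.
#' @export
validate_spectrum <- function(segment, fs, params = detection_params()) {
  if (length(segment) < 4) {
    warn("segment too short for spectral validation; rejected")
    return(list(accepted = FALSE, peak_hz = NA_real_))
  }
  p <- spec.pgram(ts(segment, frequency = fs), taper = 0, detrend = FALSE,
                  demean = TRUE, plot = FALSE, fast = FALSE)
  sel <- p$freq >= params$spectral_floor_hz
  if (!any(sel)) return(list(accepted = FALSE, peak_hz = NA_real_))
  fr <- p$freq[sel]
  sp <- p$spec[sel]
  if (params$spectral_peak_mode == "argmax") {
    peak <- fr[which.max(sp)]
    list(accepted = peak > params$spectral_peak_hz, peak_hz = peak)
  } else {
    k <- length(sp)
    is_local <- sp >= c(-Inf, sp[-k]) & sp >= c(sp[-1], -Inf)
    cand <- fr[is_local & fr > params$spectral_peak_hz]
    peak <- fr[which.max(sp)]
    list(accepted = length(cand) > 0, peak_hz = peak)
  }
}

#' Per-sample running mask from a speed trace
#'
#' A sample counts as running when the standardized speed exceeds its
#' `speed_percentile`-th percentile plus `speed_margin`. `NA` speed means no
#' behavioural data at that time.
#'
#' @param speed Tibble from [speed_trace()].
#' @param params [detection_params()].
#' @return Logical vector along the speed trace (NA where behaviour missing).
#' @export
running_mask <- function(speed, params = detection_params()) {
  z <- speed$standardized_speed
  thr <- quantile(z, params$speed_percentile / 100, na.rm = TRUE, names = FALSE) +
    params$speed_margin
  z > thr
}

speed_state_at <- function(times, speed, params) {
  # running state of arbitrary times: value of the most recent speed sample;
  # NA outside the trace coverage (no behavioural data)
  if (is.null(speed) || nrow(speed) == 0) {
    return(rep(NA, length(times)))
  }
  run <- running_mask(speed, params)
  dt <- if (nrow(speed) > 1) stats::median(diff(speed$time_s)) else 0
  idx <- findInterval(times, speed$time_s)
  state <- rep(NA, length(times))
  covered <- idx >= 1 & times <= max(speed$time_s) + dt
  state[covered] <- run[idx[covered]]
  state
}

#' Remove events during running or missing behaviour
#'
#' Drops events whose start falls in a running sample of the standardized
#' speed trace, or in a stretch with no behavioural data (`NA` speed or
#' before/after the trace).
#'
#' @param events Tibble with a `start_s` column.
#' @param speed Tibble from [speed_trace()].
#' @param params [detection_params()].
#' @return Filtered events.
#' @export
exclude_running <- function(events, speed, params = detection_params()) {
  if (is.null(speed) || nrow(speed) == 0) {
    warn("no behavioural data; all candidates discarded")
    return(events[0, ])
  }
  state <- speed_state_at(events$start_s, speed, params)
  before <- events$start_s < min(speed$time_s)
  events[!is.na(state) & !state & !before, ]
}

trapezoid <- function(y, dx) {
  if (length(y) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2) * dx
}

#' Compute per-event strength metrics
#'
#' For each event: `strength` (the ripple strength, i.e. the trapezoidal
#' integral of the band-passed envelope over `[start, stop)`), `rivd` (the
#' ripple-induced voltage deflection, integral of the raw-LFP envelope over
#' the 100 ms pre-start / 200 ms post-start window), `amplitude` (90th
#' percentile of the band-passed envelope within the event), `peak_time_s`
#' (envelope maximum) and `duration_s`.
#'
#' @param events Tibble `start_s`, `stop_s`.
#' @param env Band-passed envelope of the detection channel.
#' @param raw_env Envelope of the raw LFP on the same channel.
#' @param fs Sampling rate, Hz.
#' @param start_time Time of the first sample, seconds.
#' @param rivd_window Window around event start for RIVD, seconds.
#' @return `events` with metric columns appended.
#' @export
compute_ripple_metrics <- function(events, env, raw_env, fs, start_time = 0,
                                   rivd_window = c(-0.1, 0.2)) {
  n <- length(env)
  to_idx <- function(t) round((t - start_time) * fs) + 1
  res <- lapply(seq_len(nrow(events)), function(i) {
    i0 <- to_idx(events$start_s[i])
    i1 <- to_idx(events$stop_s[i]) - 1  # half-open [start, stop)
    i0 <- max(1, i0); i1 <- min(n, max(i1, i0))
    seg <- env[i0:i1]
    w0 <- to_idx(events$start_s[i] + rivd_window[1])
    w1 <- to_idx(events$start_s[i] + rivd_window[2]) - 1
    if (w0 < 1 || w1 > n) {
      warn("RIVD window truncated at trace bounds")
      w0 <- max(1, w0); w1 <- min(n, w1)
    }
    tibble(
      peak_time_s = start_time + (i0 + which.max(seg) - 2) / fs,
      duration_s = events$stop_s[i] - events$start_s[i],
      amplitude = quantile(seg, 0.9, names = FALSE),
      strength = trapezoid(seg, 1 / fs),
      rivd = trapezoid(raw_env[w0:w1], 1 / fs))
  })
  bind_cols(events, list_rbind(res))
}

#' Flag strong ripples
#'
#' Marks events whose strength strictly exceeds the 90th percentile of
#' strengths on the session's reference channel as strong; the remainder are
#' "common". Ties at the percentile fall to common. With fewer than 10 events
#' all are common (with a warning).
#'
#' @param events Event tibble with a `strength` column.
#' @param reference_strengths Strengths defining the percentile; defaults to
#'   `events$strength`.
#' @return `events` with a logical `is_strong` column.
#' @export
classify_strength <- function(events, reference_strengths = NULL) {
  s <- reference_strengths %||% events$strength
  if (length(s) < 10) {
    warn("fewer than 10 events; all classified common")
    events$is_strong <- rep(FALSE, nrow(events))
    return(events)
  }
  thr <- quantile(s, 0.9, names = FALSE)
  events$is_strong <- events$strength > thr
  events
}

#' Select the best ripple channel in an area
#'
#' Returns the channel with the largest SD of the band-passed envelope. When
#' several channels are local maxima of envelope SD along the depth axis
#' (multiple SD peaks, as caused by sharp waves in stratum radiatum vs ripples
#' in stratum pyramidale), the one with the larger envelope skewness wins.
#'
#' @param rec [lfp_recording()].
#' @param area Area label to restrict to (default CA1).
#' @param params [detection_params()].
#' @param probe Optional probe id to restrict to.
#' @return The selected channel id. The per-channel envelope SDs are attached
#'   as attribute `"env_sd"`.
#' @export
best_ripple_channel <- function(rec, area = "CA1",
                                params = detection_params(), probe = NULL) {
  info <- rec$channel_info
  keep <- !info$excluded & info$area == area
  if (!is.null(probe)) keep <- keep & info$probe_id == probe
  idx <- which(keep)
  if (length(idx) == 0) abort(paste0("no usable channels in area ", area))
  ord <- idx[order(info$dv[idx])]  # depth order
  stats_tbl <- vapply(ord, function(i) {
    env <- ripple_envelope(
      ripple_bandpass(rec$samples[i, ], rec$sampling_rate, params))
    ok <- !rec$artifact_mask
    c(sd = sd(env[ok]), skew = e1071::skewness(env[ok]))
  }, numeric(2))
  sds <- stats_tbl["sd", ]
  skews <- stats_tbl["skew", ]
  k <- length(sds)
  best <- if (k == 1) 1 else {
    is_peak <- sds >= c(-Inf, sds[-k]) & sds >= c(sds[-1], -Inf)
    peaks <- which(is_peak)
    if (length(peaks) >= 2) peaks[which.max(skews[peaks])] else which.max(sds)
  }
  out <- info$channel_id[ord[best]]
  attr(out, "env_sd") <- stats::setNames(sds, info$channel_id[ord])
  out
}

mask_overlap <- function(events, mask, fs, start_time) {
  # TRUE where an event overlaps any artifact-masked sample
  if (!any(mask)) return(rep(FALSE, nrow(events)))
  vapply(seq_len(nrow(events)), function(i) {
    i0 <- max(1, round((events$start_s[i] - start_time) * fs) + 1)
    i1 <- min(length(mask), round((events$stop_s[i] - start_time) * fs))
    any(mask[i0:i1])
  }, logical(1))
}

#' Detect ripples on one channel
#'
#' Full single-channel detection chain: zero-phase band-pass, Hilbert
#' envelope, dual-threshold candidate extraction (envelope statistics over
#' artifact-free, behaviour-covered, non-running samples), transitive merging
#' of nearby starts, strict duration gating, periodogram validation on the
#' raw trace, exclusion of running / behaviour-less candidates and of events
#' touching artifact-masked samples, then the per-event strength metrics and
#' the strong/common split.
#'
#' @param rec [lfp_recording()].
#' @param channel_id Channel to detect on; default: [best_ripple_channel()]
#'   of `area`.
#' @param area Area used when `channel_id` is `NULL`.
#' @param params [detection_params()].
#' @param speed Optional speed trace ([speed_trace()]); when `NULL`, no
#'   behavioural exclusion is applied.
#' @param classify When `TRUE` (default) add the `is_strong` column.
#' @return Tibble, one row per ripple: `channel_id`, `probe_id`, `start_s`,
#'   `stop_s`, `peak_time_s`, `duration_s`, `amplitude`, `strength`, `rivd`,
#'   `spectral_peak_hz`, `is_strong`.
#' @export
detect_ripples <- function(rec, channel_id = NULL, area = "CA1",
                           params = detection_params(), speed = NULL,
                           classify = TRUE) {
  fs <- rec$sampling_rate
  if (is.null(channel_id)) {
    channel_id <- as.character(best_ripple_channel(rec, area, params))
  }
  ci <- match(channel_id, rec$channel_info$channel_id)
  if (is.na(ci)) abort(paste0("unknown channel ", channel_id))
  x <- rec$samples[ci, ]
  filt <- ripple_bandpass(x, fs, params)
  env <- ripple_envelope(filt)
  times <- lfp_times(rec)
  valid <- !rec$artifact_mask
  if (!is.null(speed)) {
    state <- speed_state_at(times, speed, params)
    valid <- valid & !is.na(state) & !state
  }
  empty <- tibble(channel_id = character(), probe_id = character(),
                  start_s = numeric(), stop_s = numeric(),
                  peak_time_s = numeric(), duration_s = numeric(),
                  amplitude = numeric(), strength = numeric(),
                  rivd = numeric(), spectral_peak_hz = numeric(),
                  is_strong = logical())
  cand <- detect_candidates(env, fs, params, valid, rec$start_time)
  cand <- merge_candidates(cand, params)
  cand <- gate_duration(cand, params)
  if (nrow(cand) == 0) return(empty)
  spec <- lapply(seq_len(nrow(cand)), function(i) {
    i0 <- max(1, round((cand$start_s[i] - rec$start_time) * fs) + 1)
    i1 <- min(length(x), round((cand$stop_s[i] - rec$start_time) * fs))
    validate_spectrum(x[i0:i1], fs, params)
  })
  cand$spectral_peak_hz <- vapply(spec, `[[`, numeric(1), "peak_hz")
  cand <- cand[vapply(spec, `[[`, logical(1), "accepted"), ]
  if (!is.null(speed)) cand <- exclude_running(cand, speed, params)
  cand <- cand[!mask_overlap(cand, rec$artifact_mask, fs, rec$start_time), ]
  if (nrow(cand) == 0) return(empty)
  raw_env <- ripple_envelope(x)
  ev <- compute_ripple_metrics(cand, env, raw_env, fs, rec$start_time)
  ev <- bind_cols(
    tibble(channel_id = channel_id,
           probe_id = rec$channel_info$probe_id[ci])[rep(1, nrow(ev)), ], ev)
  if (classify) ev <- classify_strength(ev)
  ev |> select("channel_id", "probe_id", "start_s", "stop_s", "peak_time_s",
               "duration_s", "amplitude", "strength", "rivd",
               "spectral_peak_hz", dplyr::any_of("is_strong"))
}

#' Detect ripples on every probe
#'
#' Runs [detect_ripples()] on the best channel of `area` for each probe and
#' stacks the results. The strong/common split is made per channel. Probes
#' whose best channel has weak ripple activity (band-envelope variance below
#' `min_env_variance`, native units squared) are dropped.
#'
#' @inheritParams detect_ripples
#' @param min_env_variance Channel activity floor; `NULL` disables it.
#' @return Tibble of events across probes.
#' @export
detect_all_probes <- function(rec, area = "CA1", params = detection_params(),
                              speed = NULL, min_env_variance = NULL) {
  info <- rec$channel_info
  probes <- unique(info$probe_id[!info$excluded & info$area == area])
  out <- lapply(probes, function(p) {
    ch <- best_ripple_channel(rec, area, params, probe = p)
    env_sd <- attr(ch, "env_sd")[[as.character(ch)]]
    if (!is.null(min_env_variance) && env_sd^2 < min_env_variance) {
      return(NULL)
    }
    detect_ripples(rec, as.character(ch), area, params, speed)
  })
  list_rbind(out)
}
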