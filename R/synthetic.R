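# Forward simulator: multi-probe LFP with embedded propagating ripples,
# ripple-locked spiking and a behavioural speed trace, with full ground truth.

#' Generator configuration
#'
#' Parameters of the synthetic-session generator. Defaults emulate the
#' statistical structure of awake multi-probe CA1 recordings: ~6 probes
#' spanning ~3 mm of the medio-lateral (M-L) axis, a ripple incidence of
#' ~2.5 per 10 s outside running, 1/f background noise, Gaussian-windowed
#' 150 Hz ripple transients with a sharp-wave deflection, distance-dependent
#' propagation lags (~18 ms over the span) with a few ms of jitter,
#' direction-dependent strength attenuation (stronger lateral-to-medial),
#' section-dependent seed probabilities (common ripples seeded mostly
#' laterally, strong ripples medially), ripple-locked Poisson spiking with
#' seed-type-dependent late-phase persistence, and intermittent running
#' bouts.
#'
#' Ripple amplitudes are parameterised in detection units: an amplitude of
#' `k` "SD" places the peak of the injected ripple envelope at
#' mean + k standard deviations of the channel's background ripple-band
#' envelope.
#'
#' @param n_probes Number of probes (one CA1 channel each).
#' @param ml_start_um,ml_span_um M-L position of the most medial probe and
#'   the span covered by the probes, µm.
#' @param ap_um,ap_jitter_um Base antero-posterior coordinate and the SD of
#'   per-probe jitter, µm.
#' @param dv_um Dorso-ventral coordinate, µm.
#' @param sampling_rate LFP sampling rate, Hz.
#' @param session_length_s Session duration, seconds.
#' @param ripple_rate_per_s Ripple incidence (events per second).
#' @param min_event_gap_s Minimum separation between consecutive seeds.
#' @param strong_fraction Fraction of events drawn from the strong amplitude
#'   class.
#' @param seed_probs_common,seed_probs_strong Seed-section probabilities
#'   (medial, central, lateral) per event class.
#' @param propagation_speed_um_per_ms Planted propagation speed.
#' @param lag_jitter_sd_ms Gaussian lag jitter SD (truncated at +/- 60 ms);
#'   the seed probe itself has no jitter.
#' @param attenuation_m2l_per_mm,attenuation_l2m_per_mm Exponential amplitude
#'   attenuation per mm of travel, for medial-to-lateral and
#'   lateral-to-medial propagation.
#' @param amp_common_mean,amp_common_sd,amp_strong_mean,amp_strong_sd,amp_min
#'   Amplitude-class distributions (truncated normal), in envelope SD units.
#' @param ripple_freq_hz,ripple_freq_jitter_hz Ripple centre frequency and
#'   per-event jitter.
#' @param duration_mean_s,duration_sd_s,duration_min_s,duration_max_s Event
#'   duration distribution (normal, clipped).
#' @param duration_ml_slope_s_per_mm Planted duration gradient: added
#'   duration per mm of (max M-L - seed M-L), so medial seeds produce longer
#'   ripples when positive.
#' @param rise_time_s Ripple envelope attack time.
#' @param sharp_wave_rel Sharp-wave deflection amplitude relative to the
#'   ripple envelope peak.
#' @param noise_exponent,noise_sd 1/f noise exponent and SD (native units).
#' @param n_clusters_per_probe Hippocampal-formation units per probe.
#' @param subfield_probs Subfield probabilities for hippocampal units.
#' @param n_other_units Named vector of unit counts in non-hippocampal
#'   regions (Isocortex, TH, MB).
#' @param baseline_rate_meanlog,baseline_rate_sdlog,baseline_rate_min
#'   Log-normal baseline firing-rate distribution, Hz.
#' @param gain_profiles Data frame with columns `region_group`,
#'   `frac_responsive`, `gain_early_medial`, `gain_early_lateral`,
#'   `gain_late_medial`, `gain_late_lateral`, `gain_pre_medial`,
#'   `gain_pre_lateral`; see [default_gain_profiles()].
#' @param early_gain_distance_decay_per_mm Spatial decay of the early-window
#'   gain with distance from the seed (models seed-proximity engagement).
#' @param ei_inhibitory_fraction,waveform_e_mean_ms,waveform_e_sd_ms,waveform_i_mean_ms,waveform_i_sd_ms
#'   Putative E/I mixture of waveform durations.
#' @param qc_fail_fraction Fraction of units planted to fail one QC metric.
#' @param speed_sampling_rate Speed-trace sampling rate, Hz.
#' @param n_running_bouts,bout_min_s,bout_max_s,bout_speed Running bouts.
#' @param speed_baseline,speed_noise_sd Resting speed level and noise.
#' @param rng_seed Seed for all randomness; identical seeds give identical
#'   sessions.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(
    n_probes = 6, ml_start_um = 1200, ml_span_um = 3000,
    ap_um = 8000, ap_jitter_um = 150, dv_um = 2200,
    sampling_rate = 1250, session_length_s = 600,
    ripple_rate_per_s = 0.249, min_event_gap_s = 0.3,
    strong_fraction = 0.1,
    seed_probs_common = c(medial = 0.25, central = 0.30, lateral = 0.45),
    seed_probs_strong = c(medial = 0.45, central = 0.30, lateral = 0.25),
    propagation_speed_um_per_ms = 170,
    lag_jitter_sd_ms = 3,
    attenuation_m2l_per_mm = 0.20, attenuation_l2m_per_mm = 0.40,
    amp_common_mean = 8.5, amp_common_sd = 1.3,
    amp_strong_mean = 13, amp_strong_sd = 1.5, amp_min = 5.5,
    ripple_freq_hz = 150, ripple_freq_jitter_hz = 5,
    duration_mean_s = 0.065, duration_sd_s = 0.02,
    duration_min_s = 0.025, duration_max_s = 0.22,
    duration_ml_slope_s_per_mm = 0,
    rise_time_s = 0.006, sharp_wave_rel = 1.5,
    noise_exponent = 1, noise_sd = 100,
    n_clusters_per_probe = 15,
    subfield_probs = c(CA1 = 0.40, CA3 = 0.15, DG = 0.20,
                       SUB = 0.15, ProS = 0.10),
    n_other_units = c(Isocortex = 0, TH = 0, MB = 0),
    baseline_rate_meanlog = log(3), baseline_rate_sdlog = 0.6,
    baseline_rate_min = 0.3,
    gain_profiles = default_gain_profiles(),
    early_gain_distance_decay_per_mm = 0.3,
    ei_inhibitory_fraction = 0.2,
    waveform_e_mean_ms = 0.7, waveform_e_sd_ms = 0.05,
    waveform_i_mean_ms = 0.25, waveform_i_sd_ms = 0.03,
    qc_fail_fraction = 0.08,
    speed_sampling_rate = 10,
    n_running_bouts = 5, bout_min_s = 5, bout_max_s = 15, bout_speed = 30,
    speed_baseline = 0.5, speed_noise_sd = 0.05,
    rng_seed = 1) {
  cfg <- as.list(environment())
  problems <- character()
  if (abs(sum(cfg$seed_probs_common) - 1) > 1e-8)
    problems <- c(problems, "seed_probs_common must sum to 1")
  if (abs(sum(cfg$seed_probs_strong) - 1) > 1e-8)
    problems <- c(problems, "seed_probs_strong must sum to 1")
  for (f in c("sampling_rate", "session_length_s", "propagation_speed_um_per_ms",
              "noise_sd", "amp_common_mean", "amp_strong_mean")) {
    if (!isTRUE(cfg[[f]] > 0)) problems <- c(problems, paste(f, "must be > 0"))
  }
  if (cfg$lag_jitter_sd_ms < 0) problems <- c(problems, "lag_jitter_sd_ms < 0")
  if (cfg$n_probes < 1) problems <- c(problems, "n_probes must be >= 1")
  if (length(problems) > 0) {
    abort(paste0("invalid generator config: ",
                 paste(problems, collapse = "; ")))
  }
  structure(cfg, class = "generator_config")
}

#' Default region gain profiles
#'
#' Ripple gains per region group, seed type and window. Hippocampal
#' formation (HPF) units are strongly modulated, with a late-phase gain that
#' persists for medially seeded ripples but decays for lateral ones, and a
#' small anticipatory (pre-onset) medial bias; a minority of isocortical
#' units are moderately modulated; thalamus and midbrain are unmodulated.
#'
#' @return Tibble of gain profiles; see [generator_config()].
#' @export
default_gain_profiles <- function() {
  tibble(
    region_group = c("HPF", "Isocortex", "TH", "MB"),
    frac_responsive = c(0.90, 0.08, 0.00, 0.01),
    gain_early_medial = c(3.0, 1.8, 1.0, 1.8),
    gain_early_lateral = c(3.0, 1.8, 1.0, 1.8),
    gain_late_medial = c(2.4, 1.8, 1.0, 1.8),
    gain_late_lateral = c(1.4, 1.8, 1.0, 1.8),
    gain_pre_medial = c(1.15, 1.0, 1.0, 1.0),
    gain_pre_lateral = c(1.0, 1.0, 1.0, 1.0))
}

gen_pink_noise <- function(n, exponent, sd_target) {
  nf <- n %/% 2
  f <- seq_len(nf) / n
  amp <- f^(-exponent / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  even <- n %% 2 == 0
  full <- c(0, spec,
            if (even) complex(modulus = Mod(spec[nf]), argument = 0),
            Conj(rev(spec[seq_len(nf - !even)])))
  full <- full[seq_len(n)]
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x) * sd_target
}

ripple_waveform_envelope <- function(tt, duration, rise) {
  tau <- pmax(duration - rise, 0.005) / 3
  pmin(1, pmax(0, tt / rise)) * exp(-pmax(0, tt - rise) / tau)
}

# envelope attenuation of the injected waveform through the detection filter,
# by duration (the band-pass removes attack-transient sidebands)
amp_calibration <- function(fs, rise, freq, params = detection_params()) {
  durations <- seq(0.02, 0.24, by = 0.02)
  b <- ripple_filter(fs, params)
  ratio <- vapply(durations, function(d) {
    m <- round(fs * (d + 0.4))
    tt <- (seq_len(m) - 1) / fs - 0.2
    w <- ripple_waveform_envelope(tt, d, rise) * sin(2 * pi * freq * tt)
    max(ripple_envelope(as.numeric(signal::filtfilt(b, w))))
  }, numeric(1))
  function(d) approx(durations, ratio, xout = d, rule = 2)$y
}

probe_layout <- function(cfg) {
  ml <- cfg$ml_start_um + seq(0, cfg$ml_span_um, length.out = cfg$n_probes)
  tibble(
    probe_id = sprintf("probe%02d", seq_len(cfg$n_probes)),
    channel_id = sprintf("probe%02d_ca1", seq_len(cfg$n_probes)),
    area = "CA1",
    ap = cfg$ap_um + round(rnorm(cfg$n_probes, 0, cfg$ap_jitter_um)),
    dv = cfg$dv_um,
    ml = ml)
}

#' Simulate ripple events and their propagation (no LFP)
#'
#' Draws seed times, classes, seed sections/probes, per-probe arrival times
#' (seed time + M-L distance / speed + truncated Gaussian jitter; the seed
#' probe has no jitter), per-probe amplitudes (direction-dependent
#' exponential attenuation) and durations (optionally with a planted M-L
#' gradient).
#'
#' @param cfg [generator_config()].
#' @param probes Probe layout (internal; defaults to the configured layout).
#' @return List with `events` (one row per event) and `by_probe` (one row
#'   per event x probe), plus `probes` and `sections`.
#' @export
simulate_events <- function(cfg, probes = NULL) {
  if (is.null(probes)) probes <- probe_layout(cfg)
  sections <- assign_sections(probes)
  sec_probes <- split(sections$probe_id, sections$section)
  L <- cfg$session_length_s
  margin <- 3
  mean_gap <- 1 / cfg$ripple_rate_per_s
  exp_mean <- max(mean_gap - cfg$min_event_gap_s, 0.05)
  t <- margin + cumsum(cfg$min_event_gap_s +
                         rexp(ceiling(L / mean_gap * 1.5) + 50, 1 / exp_mean))
  t <- t[t < L - margin]
  n <- length(t)
  is_strong <- runif(n) < cfg$strong_fraction
  draw_sec <- function(strong) {
    p <- if (strong) cfg$seed_probs_strong else cfg$seed_probs_common
    sample(c("medial", "central", "lateral"), 1, prob = p)
  }
  seed_section <- vapply(is_strong, draw_sec, character(1))
  seed_probe <- vapply(seed_section, function(s) {
    ids <- sec_probes[[s]]
    ids[sample.int(length(ids), 1)]
  }, character(1))
  seed_ml <- probes$ml[match(seed_probe, probes$probe_id)]
  amp <- ifelse(is_strong,
                rnorm(n, cfg$amp_strong_mean, cfg$amp_strong_sd),
                rnorm(n, cfg$amp_common_mean, cfg$amp_common_sd))
  amp <- pmax(amp, cfg$amp_min)
  max_ml <- max(probes$ml)
  dur <- cfg$duration_mean_s +
    cfg$duration_ml_slope_s_per_mm * (max_ml - seed_ml) / 1000 +
    rnorm(n, 0, cfg$duration_sd_s)
  dur <- pmin(pmax(dur, cfg$duration_min_s), cfg$duration_max_s)
  freq <- cfg$ripple_freq_hz + rnorm(n, 0, cfg$ripple_freq_jitter_hz)
  freq <- pmin(pmax(freq, 125), 245)
  events <- tibble(event_id = seq_len(n), t_seed = t,
                   class = ifelse(is_strong, "strong", "common"),
                   seed_section = seed_section, seed_probe = seed_probe,
                   seed_ml = seed_ml, amplitude_sd = amp,
                   duration_s = dur, freq_hz = freq)
  # per-probe propagation
  by_probe <- tidyr::expand_grid(event_id = events$event_id,
                                 probe_id = probes$probe_id) |>
    left_join(events, by = "event_id") |>
    mutate(ml = probes$ml[match(.data$probe_id, probes$probe_id)],
           dist_mm = abs(.data$ml - .data$seed_ml) / 1000,
           to_lateral = .data$ml >= .data$seed_ml,
           lag_true_ms = .data$dist_mm * 1000 / cfg$propagation_speed_um_per_ms)
  jit <- rnorm(nrow(by_probe), 0, cfg$lag_jitter_sd_ms)
  jit <- pmin(pmax(jit, -60), 60)
  jit[by_probe$dist_mm == 0] <- 0
  atten <- ifelse(by_probe$to_lateral,
                  cfg$attenuation_m2l_per_mm, cfg$attenuation_l2m_per_mm)
  by_probe <- by_probe |>
    mutate(lag_true_ms = .data$lag_true_ms + jit,
           start_s = .data$t_seed + .data$lag_true_ms / 1000,
           amplitude_sd = .data$amplitude_sd * exp(-atten * .data$dist_mm),
           detectable = .data$amplitude_sd >= 5) |>
    select("event_id", "probe_id", "ml", "start_s", "lag_true_ms",
           "amplitude_sd", "duration_s", "freq_hz", "seed_ml", "seed_section",
           "class", "detectable")
  # snap starts to the sample grid (what actually lands in the LFP)
  by_probe$start_s <- round(by_probe$start_s * cfg$sampling_rate) /
    cfg$sampling_rate
  list(events = events, by_probe = by_probe, probes = probes,
       sections = sections)
}

simulate_speed <- function(cfg) {
  L <- cfg$session_length_s
  nt <- floor(L * cfg$speed_sampling_rate)
  times <- (seq_len(nt) - 1) / cfg$speed_sampling_rate
  speed <- pmax(0, cfg$speed_baseline + rnorm(nt, 0, cfg$speed_noise_sd))
  bouts <- NULL
  if (cfg$n_running_bouts > 0) {
    starts <- sort(runif(cfg$n_running_bouts, 0.05 * L, 0.9 * L))
    durs <- runif(cfg$n_running_bouts, cfg$bout_min_s, cfg$bout_max_s)
    bouts <- tibble(bout_start_s = starts, bout_stop_s = starts + durs)
    for (i in seq_len(nrow(bouts))) {
      inb <- times >= bouts$bout_start_s[i] & times < bouts$bout_stop_s[i]
      speed[inb] <- speed[inb] + cfg$bout_speed
    }
  }
  st <- speed_trace(times, speed)
  attr(st, "bouts") <- bouts
  st
}

simulate_lfp <- function(sim, cfg, params = detection_params()) {
  probes <- sim$probes
  fs <- cfg$sampling_rate
  n <- round(cfg$session_length_s * fs)
  calib <- amp_calibration(fs, cfg$rise_time_s, cfg$ripple_freq_hz, params)
  samples <- matrix(0, nrow(probes), n)
  for (ci in seq_len(nrow(probes))) {
    x <- gen_pink_noise(n, cfg$noise_exponent, cfg$noise_sd)
    # background ripple-band envelope statistics (first 60 s is plenty)
    m0 <- min(n, 60 * fs)
    env0 <- ripple_envelope(ripple_bandpass(x[seq_len(m0)], fs, params))
    mu_e <- mean(env0); sd_e <- sd(env0)
    ev <- sim$by_probe[sim$by_probe$probe_id == probes$probe_id[ci], ]
    for (k in seq_len(nrow(ev))) {
      t0 <- ev$start_s[k]; d <- ev$duration_s[k]
      i0 <- round(t0 * fs); i1 <- min(n - 1, i0 + ceiling((d + 0.06) * fs))
      if (i0 < 0 || i0 >= n - 10) next
      idx <- i0:i1
      tt <- idx / fs - t0
      envs <- ripple_waveform_envelope(tt, d, cfg$rise_time_s)
      A <- (mu_e + ev$amplitude_sd[k] * sd_e) / calib(d)
      phase <- runif(1, 0, 2 * pi)
      wave <- A * envs * sin(2 * pi * ev$freq_hz[k] * tt + phase)
      sw <- -cfg$sharp_wave_rel * (mu_e + ev$amplitude_sd[k] * sd_e) *
        sin(pi * pmin(tt / (d + 0.02), 1)) * (tt >= 0)
      samples[ci, idx + 1] <- samples[ci, idx + 1] + wave + sw
    }
    samples[ci, ] <- samples[ci, ] + x
  }
  channels <- tibble(channel_id = probes$channel_id,
                     probe_id = probes$probe_id, area = probes$area,
                     ap = probes$ap, dv = probes$dv, ml = probes$ml)
  lfp_recording(samples, fs, channels, start_time = 0, unit = "uV")
}

simulate_units <- function(sim, cfg) {
  probes <- sim$probes
  hpf <- tidyr::expand_grid(probe_id = probes$probe_id,
                            k = seq_len(cfg$n_clusters_per_probe)) |>
    mutate(area = sample(names(cfg$subfield_probs),
                         n(), TRUE, cfg$subfield_probs),
           region_group = "HPF")
  other <- NULL
  n_other <- cfg$n_other_units[cfg$n_other_units > 0]
  if (length(n_other) > 0) {
    other <- list_rbind(lapply(names(n_other), function(reg) {
      tibble(probe_id = rep(probes$probe_id,
                            length.out = n_other[[reg]]),
             k = seq_len(n_other[[reg]]), area = reg, region_group = reg)
    }))
  }
  units <- bind_rows(hpf, other) |>
    mutate(cluster_id = sprintf("unit%04d", row_number()),
           ml = probes$ml[match(.data$probe_id, probes$probe_id)] +
             runif(n(), -100, 100),
           ap = probes$ap[match(.data$probe_id, probes$probe_id)] +
             runif(n(), -100, 100),
           baseline_rate = pmax(cfg$baseline_rate_min,
                                rlnorm(n(), cfg$baseline_rate_meanlog,
                                       cfg$baseline_rate_sdlog)),
           true_ei = ifelse(runif(n()) < cfg$ei_inhibitory_fraction,
                            "putative_inhibitory", "putative_excitatory"),
           waveform_duration_ms = ifelse(
             .data$true_ei == "putative_inhibitory",
             rnorm(n(), cfg$waveform_i_mean_ms, cfg$waveform_i_sd_ms),
             rnorm(n(), cfg$waveform_e_mean_ms, cfg$waveform_e_sd_ms)))
  prof <- cfg$gain_profiles
  units <- left_join(units, prof, by = "region_group") |>
    mutate(responsive = runif(n()) < .data$frac_responsive)
  gain_cols <- grep("^gain_", names(units), value = TRUE)
  for (gc in gain_cols) {
    units[[gc]] <- ifelse(units$responsive, units[[gc]], 1)
  }
  # QC metrics: mostly passing, a planted fraction failing one criterion
  nu <- nrow(units)
  units <- units |>
    mutate(peak_trough_ratio = runif(nu, 0.5, 4),
           isi_violations = runif(nu, 0, 0.4),
           amplitude_cutoff = runif(nu, 0, 0.08),
           presence_ratio = runif(nu, 0.5, 1))
  fail <- which(runif(nu) < cfg$qc_fail_fraction)
  if (length(fail) > 0) {
    metric <- sample(c("peak_trough_ratio", "isi_violations",
                       "amplitude_cutoff", "presence_ratio"),
                     length(fail), TRUE)
    bad_value <- c(peak_trough_ratio = 6, isi_violations = 0.8,
                   amplitude_cutoff = 0.2, presence_ratio = 0.05)
    for (i in seq_along(fail)) {
      units[[metric[i]]][fail[i]] <- bad_value[[metric[i]]]
    }
  }
  select(units, !"k")
}

#' Simulate ripple-locked spike trains
#'
#' Inhomogeneous Poisson spiking: a homogeneous baseline plus window-specific
#' rate gains around each ripple (early 0-50 ms, late 50-120 ms, pre -20-0 ms
#' relative to the event's arrival at the unit's probe). The early-window
#' gain decays with distance from the ripple seed
#' (`early_gain_distance_decay_per_mm`), modelling seed-proximity
#' engagement; gains below 1 thin the baseline train.
#'
#' @param units Unit tibble from the generator (with gain columns).
#' @param by_probe Per-event, per-probe arrival table from
#'   [simulate_events()].
#' @param cfg [generator_config()].
#' @return `units` with `spike_times` and `firing_rate` columns.
#' @export
simulate_spike_trains <- function(units, by_probe, cfg) {
  L <- cfg$session_length_s
  windows <- list(early = c(0, 0.05), late = c(0.05, 0.12),
                  pre = c(-0.02, 0))
  decay <- cfg$early_gain_distance_decay_per_mm
  ev_by_probe <- split(by_probe, by_probe$probe_id)
  spikes <- vector("list", nrow(units))
  for (u in seq_len(nrow(units))) {
    lam <- units$baseline_rate[u]
    base <- sort(runif(rpois(1, lam * L), 0, L))
    ev <- ev_by_probe[[units$probe_id[u]]]
    extra <- NULL
    drop <- rep(FALSE, length(base))
    if (!is.null(ev) && nrow(ev) > 0) {
      seed_med <- ev$seed_section == "medial"
      dist_mm <- abs(units$ml[u] - ev$seed_ml) / 1000
      for (w in names(windows)) {
        win <- windows[[w]]
        len <- diff(win)
        g <- ifelse(seed_med,
                    units[[paste0("gain_", w, "_medial")]][u],
                    units[[paste0("gain_", w, "_lateral")]][u])
        if (w == "early" && decay > 0) {
          g <- 1 + (g - 1) * exp(-decay * dist_mm)
        }
        up <- g > 1
        if (any(up)) {
          n_ex <- rpois(sum(up), (g[up] - 1) * lam * len)
          t0 <- ev$start_s[up][n_ex > 0]
          reps <- n_ex[n_ex > 0]
          if (length(reps) > 0) {
            extra <- c(extra, rep(t0, reps) + win[1] +
                         runif(sum(reps), 0, len))
          }
        }
        dn <- which(g < 1)
        for (i in dn) {
          inw <- base >= ev$start_s[i] + win[1] & base < ev$start_s[i] + win[2]
          drop[inw] <- drop[inw] | (runif(sum(inw)) > g[i])
        }
      }
    }
    sp <- sort(c(base[!drop], extra))
    spikes[[u]] <- sp[sp >= 0 & sp <= L]
  }
  units$spike_times <- spikes
  units$firing_rate <- lengths(spikes) / L
  units
}

#' Generate a complete synthetic session
#'
#' Draws events, LFP, units, spike trains and a speed trace under one RNG
#' seed. Identical configurations (including `rng_seed`) give identical
#' sessions.
#'
#' @param cfg [generator_config()].
#' @param lfp Set to `FALSE` to skip LFP synthesis (events + spikes only,
#'   much faster; `$lfp` is then `NULL`).
#' @param params [detection_params()] used to calibrate injected amplitudes.
#' @return List of class `ripple_session`: `lfp`, `units`, `speed`, `truth`
#'   (list with `events`, `by_probe`, `sections`, `probes`, running bouts)
#'   and `config`.
#' @export
simulate_session <- function(cfg = generator_config(), lfp = TRUE,
                             params = detection_params()) {
  withr::with_seed(cfg$rng_seed, {
    sim <- simulate_events(cfg)
    speed <- simulate_speed(cfg)
    bouts <- attr(speed, "bouts")
    # flag events during running bouts
    in_bout <- function(t) {
      if (is.null(bouts) || nrow(bouts) == 0) return(rep(FALSE, length(t)))
      vapply(t, function(ti) {
        any(ti >= bouts$bout_start_s & ti < bouts$bout_stop_s)
      }, logical(1))
    }
    sim$by_probe$during_running <- in_bout(sim$by_probe$start_s)
    sim$events$during_running <- in_bout(sim$events$t_seed)
    units <- simulate_units(sim, cfg)
    units <- simulate_spike_trains(units, sim$by_probe, cfg)
    rec <- if (lfp) simulate_lfp(sim, cfg, params) else NULL
    structure(
      list(lfp = rec, units = units, speed = speed,
           truth = list(events = sim$events, by_probe = sim$by_probe,
                        probes = sim$probes, sections = sim$sections,
                        running_bouts = bouts),
           config = cfg),
      class = "ripple_session")
  })
}

#' @export
print.ripple_session <- function(x, ...) {
  cat(sprintf(
    "<ripple_session> %d probes, %.0f s, %d true events, %d units\n",
    x$config$n_probes, x$config$session_length_s,
    nrow(x$truth$events), nrow(x$units)))
  invisible(x)
}

#' Inject artifacts into a recording
#'
#' Adds clipped line-noise bursts (square wave at the line frequency,
#' default 60 Hz, whose odd harmonics land in the ripple band and cross the
#' amplitude thresholds while the raw spectrum still peaks at the line
#' frequency) or flat segments, optionally flagging them in the artifact
#' mask.
#'
#' @param rec [lfp_recording()].
#' @param kind `"line_noise"` or `"flat_segments"`.
#' @param at_s Segment start times, seconds.
#' @param duration_s Segment duration.
#' @param amplitude Burst amplitude (native units).
#' @param freq_hz Line frequency.
#' @param channels Channel indices to affect (default: all).
#' @param mask Also set the artifact mask over the segments.
#' @return Modified recording.
#' @export
inject_artifacts <- function(rec, kind = c("line_noise", "flat_segments"),
                             at_s, duration_s = 0.1, amplitude = 1500,
                             freq_hz = 60, channels = NULL, mask = FALSE) {
  kind <- match.arg(kind)
  if (length(at_s) == 0) return(rec)
  fs <- rec$sampling_rate
  n <- ncol(rec$samples)
  if (is.null(channels)) channels <- seq_len(nrow(rec$samples))
  for (t0 in at_s) {
    i0 <- max(1, round((t0 - rec$start_time) * fs) + 1)
    i1 <- min(n, i0 + round(duration_s * fs) - 1)
    if (i1 <= i0) next
    idx <- i0:i1
    if (kind == "line_noise") {
      tt <- (idx - i0) / fs
      rec$samples[channels, idx] <-
        sweep(rec$samples[channels, idx, drop = FALSE], 2,
              amplitude * sign(sin(2 * pi * freq_hz * tt)), `+`)
    } else {
      rec$samples[channels, idx] <- 0
    }
    if (mask) rec$artifact_mask[idx] <- TRUE
  }
  rec
}
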