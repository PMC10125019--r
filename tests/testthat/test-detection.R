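fs <- 1250

test_that("band-pass passes 150 Hz, rejects 10 Hz by >= 40 dB, zero phase", {
  t <- (0:9999) / fs
  p <- detection_params()
  in_band <- ripple_bandpass(sin(2 * pi * 150 * t), fs, p)
  expect_lt(abs(max(abs(in_band[3000:7000])) - 1), 0.01)
  low <- ripple_bandpass(sin(2 * pi * 10 * t), fs, p)
  # oracle: attenuation from the designed filter frequency response at 10 Hz,
  # squared for the forward-backward pass
  b <- signal::butter(p$filter_order / 2,
                      c(p$band_low, p$band_high) / (fs / 2), "pass")
  z <- exp(-1i * 2 * pi * 10 / fs)
  h10 <- Mod(sum(b$b * z^(0:(length(b$b) - 1))) /
               sum(b$a * z^(0:(length(b$a) - 1))))^2
  expect_lt(20 * log10(h10), -40)
  expect_lt(20 * log10(max(abs(low[3000:7000]))), -40)
  # impulse response symmetric around the impulse (zero-phase)
  x <- numeric(2001); x[1001] <- 1
  y <- ripple_bandpass(x, fs, p)
  expect_equal(y[1001 + 1:300], y[1001 - 1:300], tolerance = 1e-6)
  expect_error(ripple_bandpass(sin(t), 400, p), "too low")
})

test_that("envelope recovers amplitude, zero and a Gaussian modulator", {
  t <- (0:9999) / fs
  env <- ripple_envelope(2.5 * sin(2 * pi * 150 * t))
  expect_equal(env[500:9500], rep(2.5, 9001), tolerance = 0.01)
  expect_equal(ripple_envelope(numeric(1000)), numeric(1000))
  mod <- exp(-(t - 4)^2 / (2 * 0.5^2))
  env2 <- ripple_envelope(mod * sin(2 * pi * 150 * t))
  mid <- 1000:9000
  expect_lt(max(abs(env2[mid] - mod[mid]) / max(mod)), 0.02)
  # envelope >= |signal| at oscillation peaks
  x <- sin(2 * pi * 150 * t)
  env3 <- ripple_envelope(x)
  expect_true(all(env3[100:9900] >= abs(x[100:9900]) - 1e-6))
})

test_that("dual-threshold candidate extraction matches a sample scan", {
  env <- bump_envelope(bumps = list(list(at = 5, height_sd = 8,
                                         width_s = 0.03)))
  cand <- detect_candidates(env, fs)
  expect_equal(nrow(cand), 1)
  expect_true(cand$start_s < 5 & cand$stop_s > 5)

  none <- detect_candidates(
    bump_envelope(bumps = list(list(at = 5, height_sd = 4.5,
                                    width_s = 0.03))), fs)
  expect_equal(nrow(none), 0)

  env2 <- bump_envelope(bumps = list(list(at = 5, height_sd = 8, width_s = 0.03),
                                     list(at = 9, height_sd = 9, width_s = 0.04)))
  cand2 <- detect_candidates(env2, fs)
  expect_equal(nrow(cand2), 2)
  # brute-force oracle: scan the smoothed envelope for threshold runs
  mu <- mean(env2); s <- sd(env2)
  sm <- as.numeric(stats::filter(env2, rep(1 / 5, 5), sides = 1))
  sm[is.na(sm)] <- -Inf
  above <- sm > mu + 2 * s
  runs <- rle(above)
  stops <- cumsum(runs$lengths); starts <- stops - runs$lengths + 1
  keep <- runs$values & vapply(seq_along(starts), function(i) {
    runs$values[i] && any(env2[starts[i]:stops[i]] > mu + 5 * s)
  }, logical(1))
  expect_equal(cand2$start_s, (starts[keep] - 1) / fs)
  expect_equal(cand2$stop_s, stops[keep] / fs)

  expect_warning(detect_candidates(rep(1, 1000), fs), "zero variance")
})

test_that("candidate merging is transitive on close starts", {
  p <- detection_params()
  two <- tibble::tibble(start_s = c(1.000, 1.030), stop_s = c(1.02, 1.05))
  expect_equal(nrow(merge_candidates(two, p)), 1)
  far <- tibble::tibble(start_s = c(1.000, 1.060), stop_s = c(1.02, 1.08))
  expect_equal(nrow(merge_candidates(far, p)), 2)
  chain <- tibble::tibble(start_s = c(1.000, 1.040, 1.080),
                          stop_s = c(1.02, 1.06, 1.10))
  merged <- merge_candidates(chain, p)
  # oracle: transitive closure by repeated pairwise linking of member starts
  # until fixpoint, then aggregation per group
  grp <- seq_len(nrow(chain))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(chain) - 1)) {
      if (chain$start_s[i + 1] - chain$start_s[i] < p$merge_gap_s &&
          grp[i + 1] != grp[i]) {
        grp[grp == grp[i + 1]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  oracle <- tibble::tibble(
    start_s = as.numeric(tapply(chain$start_s, grp, min)),
    stop_s = as.numeric(tapply(chain$stop_s, grp, max)))
  expect_equal(merged, oracle)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start_s, 1.0)
  expect_equal(merged$stop_s, 1.10)
})

test_that("duration gate uses strict open bounds", {
  p <- detection_params()
  ev <- tibble::tibble(start_s = c(0, 0, 0, 0),
                       stop_s = c(0.1, 0.3, 0.015, 0.25))
  kept <- gate_duration(ev, p)
  # 0.10 kept; 0.30 too long; 0.015 and 0.25 exactly on the open bounds
  expect_equal(kept$stop_s, 0.1)
})

test_that("spectral validation accepts ripples and rejects line noise", {
  t <- (0:249) / fs
  p <- detection_params()
  v <- validate_spectrum(sin(2 * pi * 150 * t), fs, p)
  expect_true(v$accepted)
  expect_equal(v$peak_hz, 150, tolerance = 0.05)
  expect_false(validate_spectrum(sin(2 * pi * 60 * t), fs, p)$accepted)
  # constant detrend removes a DC offset; oracle: the raw power spectrum
  # (mean retained) peaks at 0 Hz, so without detrending the candidate would
  # be rejected
  seg <- sin(2 * pi * 150 * t) + 50
  p_raw <- Mod(fft(seg))^2
  freqs <- (seq_along(seg) - 1) * fs / length(seg)
  expect_equal(freqs[which.max(p_raw)], 0)
  expect_true(validate_spectrum(seg, fs, p)$accepted)
  expect_warning(out <- validate_spectrum(numeric(2), fs, p), "short")
  expect_false(out$accepted)
})

test_that("running exclusion follows the P10 + margin rule on z-scored speed", {
  sp <- speed_with_bout(dur_s = 60, bout = c(20, 30))
  ev <- tibble::tibble(start_s = c(5, 25, 45))
  kept <- exclude_running(ev, sp)
  expect_equal(kept$start_s, c(5, 45))
  # oracle: recompute the threshold and mask by direct scan
  z <- sp$standardized_speed
  thr <- quantile(z, 0.10, names = FALSE) + 0.06
  run <- z > thr
  state <- run[findInterval(ev$start_s, sp$time_s)]
  expect_equal(kept$start_s, ev$start_s[!state])
  # missing behaviour: events outside the trace are removed
  ev2 <- tibble::tibble(start_s = c(-5, 70, 5))
  expect_equal(exclude_running(ev2, sp)$start_s, 5)
  expect_warning(out <- exclude_running(ev, sp[0, ]), "no behavioural")
  expect_equal(nrow(out), 0)
})

test_that("strength metrics integrate the envelope correctly", {
  ev <- tibble::tibble(start_s = 1, stop_s = 1.1)
  env <- rep(1, 3 * fs)   # constant 1 (native units)
  raw <- rep(2, 3 * fs)
  m <- compute_ripple_metrics(ev, env, raw, fs)
  expect_equal(m$strength, 0.1, tolerance = 0.01)
  expect_equal(m$amplitude, 1)
  expect_equal(m$rivd, 2 * 0.3, tolerance = 0.01)
  m2 <- compute_ripple_metrics(ev, 2 * env, raw, fs)
  expect_equal(m2$strength, 2 * m$strength)   # linearity
  expect_equal(m2$amplitude, 2 * m$amplitude)
  # triangular envelope, area h*d/2
  h <- 4; d <- 0.2
  tt <- (0:(3 * fs - 1)) / fs
  tri <- pmax(0, h * (1 - abs(tt - 1.1) / (d / 2)))
  m3 <- compute_ripple_metrics(tibble::tibble(start_s = 1, stop_s = 1.2),
                               tri, raw, fs)
  expect_equal(m3$strength, h * d / 2, tolerance = 0.01)
  expect_warning(
    compute_ripple_metrics(tibble::tibble(start_s = 0.05, stop_s = 0.1),
                           env, raw, fs), "truncated")
})

test_that("strong ripples are the strict top decile of strength", {
  ev <- tibble::tibble(strength = 1:100)
  out <- classify_strength(ev)
  expect_equal(which(out$is_strong), 91:100)
  ev20 <- tibble::tibble(strength = 1:20)
  expect_equal(which(classify_strength(ev20)$is_strong), 19:20)
  ties <- tibble::tibble(strength = rep(5, 30))
  expect_false(any(classify_strength(ties)$is_strong))  # strict >
  expect_warning(out <- classify_strength(tibble::tibble(strength = 1:5)),
                 "fewer than 10")
  expect_false(any(out$is_strong))
})

test_that("best channel maximises envelope SD, skewness breaks SD-peak ties", {
  t <- (0:(5 * fs - 1)) / fs
  base <- sin(2 * pi * 150 * t)
  withr::with_seed(1, {
    # three channels, envelope SDs ordered 1 < 5 > 2 -> middle channel
    mods <- list(1 + 1.0 * sin(2 * pi * 0.5 * t),
                 1 + 5.0 * sin(2 * pi * 0.5 * t),
                 1 + 2.0 * sin(2 * pi * 0.5 * t))
    samples <- do.call(rbind, lapply(mods, function(m) m * base))
    rec <- lfp_recording(samples, fs, tiny_channels(3, probe = "probe01"))
    expect_equal(as.character(best_ripple_channel(rec)), "ch02")
    # two separated SD peaks of equal height: higher skewness wins
    sym <- 1 + 3 * sin(2 * pi * 0.5 * t)                  # low skew
    skewed <- 1 + 3 * sqrt(2) * pmax(sin(2 * pi * 0.5 * t), 0)  # high skew
    flat <- rep(1, length(t))
    samples2 <- rbind(sym * base, flat * base, skewed * base)
    rec2 <- lfp_recording(samples2, fs, tiny_channels(3, probe = "probe01"))
    env_sd <- attr(best_ripple_channel(rec2), "env_sd")
    # both outer channels are local SD maxima
    expect_true(env_sd[["ch01"]] > env_sd[["ch02"]] &&
                  env_sd[["ch03"]] > env_sd[["ch02"]])
    expect_equal(as.character(best_ripple_channel(rec2)), "ch03")
    one <- lfp_recording(samples2[1, , drop = FALSE], fs, tiny_channels(1))
    expect_equal(as.character(best_ripple_channel(one)), "ch01")
    expect_error(best_ripple_channel(rec2, area = "DG"), "no usable")
  })
})

test_that("detection is deterministic and monotone in the peak threshold", {
  cfg <- generator_config(session_length_s = 60, n_probes = 3,
                          n_clusters_per_probe = 2, n_running_bouts = 1,
                          rng_seed = 21)
  ses <- simulate_session(cfg)
  ev1 <- detect_ripples(ses$lfp, speed = ses$speed, classify = FALSE)
  ev2 <- detect_ripples(ses$lfp, speed = ses$speed, classify = FALSE)
  expect_identical(ev1, ev2)
  counts <- vapply(c(3, 5, 7, 9), function(k) {
    nrow(detect_ripples(ses$lfp, params = detection_params(peak_threshold_sd = k),
                        speed = ses$speed, classify = FALSE))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("events never overlap artifact-masked samples", {
  cfg <- generator_config(session_length_s = 60, n_probes = 3,
                          n_clusters_per_probe = 2, n_running_bouts = 0,
                          rng_seed = 33)
  ses <- simulate_session(cfg)
  ev0 <- detect_ripples(ses$lfp, channel_id = "probe01_ca1", classify = FALSE)
  expect_gt(nrow(ev0), 0)
  # mask a window containing the first detected event
  rec <- ses$lfp
  i0 <- round(ev0$start_s[1] * rec$sampling_rate)
  rec$artifact_mask[max(1, i0 - 10):(i0 + 50)] <- TRUE
  ev <- detect_ripples(rec, channel_id = "probe01_ca1", classify = FALSE)
  masked_t <- lfp_times(rec)[rec$artifact_mask]
  for (i in seq_len(nrow(ev))) {
    expect_false(any(masked_t >= ev$start_s[i] & masked_t < ev$stop_s[i]))
  }
  expect_lt(nrow(ev), nrow(ev0) + 1)
})

test_that("false-positive rate on pure noise stays within budget", {
  # band-limited gaussian noise only, no injected ripples: after spectral
  # validation the detector should emit under 0.1 events/s
  cfg <- generator_config(session_length_s = 120, n_probes = 3,
                          ripple_rate_per_s = 1e-6, n_clusters_per_probe = 2,
                          n_running_bouts = 0, rng_seed = 8)
  ses <- simulate_session(cfg)
  ev <- detect_ripples(ses$lfp, channel_id = "probe02_ca1", classify = FALSE)
  expect_lt(nrow(ev) / cfg$session_length_s, 0.1)
})
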