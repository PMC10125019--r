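# Shared fixtures, all built in code.

tiny_channels <- function(n = 3, area = "CA1", ml = NULL, probe = NULL) {
  tibble::tibble(
    channel_id = sprintf("ch%02d", seq_len(n)),
    probe_id = probe %||% sprintf("probe%02d", seq_len(n)),
    area = area,
    ap = 8000,
    dv = 2000 + 10 * seq_len(n),
    ml = ml %||% seq(1000, by = 300, length.out = n))
}

# single-channel recording holding a given trace
trace_recording <- function(x, fs = 1250, start_time = 0) {
  ripplemapr::lfp_recording(matrix(x, nrow = 1), fs, tiny_channels(1),
                            start_time = start_time)
}

# envelope with gaussian bumps at given times/heights (in SD units of the
# deterministic sinusoidal floor), used to test the candidate extractor
# without any filtering involved
bump_envelope <- function(fs = 1250, dur_s = 20, bumps = list(),
                          floor_mean = 10, floor_amp = 1) {
  n <- fs * dur_s
  tt <- (seq_len(n) - 1) / fs
  floor_sd <- floor_amp / sqrt(2)  # SD of a sinusoid
  env <- floor_mean + floor_amp * sin(2 * pi * 0.3 * tt)
  for (b in bumps) {
    env <- env + (b$height_sd * floor_sd) *
      exp(-(tt - b$at)^2 / (2 * (b$width_s / 4)^2))
  }
  env
}

# flat speed trace with a running bout
speed_with_bout <- function(dur_s = 60, bout = c(20, 30), fs = 10,
                            seed = 1) {
  withr::with_seed(seed, {
    times <- seq(0, dur_s - 1 / fs, by = 1 / fs)
    v <- 0.5 + rnorm(length(times), 0, 0.05)
    v[times >= bout[1] & times < bout[2]] <- 30
    ripplemapr::speed_trace(times, v)
  })
}

`%||%` <- rlang::`%||%`
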