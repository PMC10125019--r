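mk_qc_units <- function(n = 4, rate = 5) {
  tibble::tibble(
    cluster_id = sprintf("u%03d", seq_len(n)),
    probe_id = "probe01", area = "CA1", ml = seq(1000, 2000, length.out = n),
    peak_trough_ratio = 2, isi_violations = 0.1, amplitude_cutoff = 0.05,
    presence_ratio = 0.9, firing_rate = rate,
    spike_times = purrr::map(seq_len(n), ~ numeric(0)))
}

# deterministic spike trains: k spikes per window per ripple
regular_unit <- function(starts, n_base, n_rip, window = c(0, 0.12)) {
  spikes <- c()
  for (s in starts) {
    if (n_base > 0)
      spikes <- c(spikes, s - 0.12 + (seq_len(n_base) - 0.5) * 0.12 / n_base)
    if (n_rip > 0)
      spikes <- c(spikes, s + window[1] +
                    (seq_len(n_rip) - 0.5) * diff(window) / n_rip)
  }
  sort(spikes)
}

test_that("QC filter applies the five unit-selection criteria", {
  u <- mk_qc_units(6)
  u$isi_violations[1] <- 0.6
  u$peak_trough_ratio[2] <- 5.5
  u$amplitude_cutoff[3] <- 0.15
  u$presence_ratio[4] <- 0.05
  u$firing_rate[5] <- 0.05
  out <- qc_filter(u)
  expect_equal(out$cluster_id, "u006")
  counts <- attr(out, "qc_counts")
  expect_equal(unname(counts[c("isi_violations", "firing_rate")]), c(1L, 1L))
  # all-passing set is the identity
  clean <- mk_qc_units(5)
  expect_equal(qc_filter(clean)$cluster_id, clean$cluster_id)
})

test_that("modulation index is (ripple - baseline) / baseline", {
  starts <- seq(10, 200, by = 1)
  rip <- tibble::tibble(start_s = starts,
                        seed_section = rep(c("medial", "lateral"),
                                           length.out = length(starts)))
  u <- mk_qc_units(2)
  # baseline 6 spikes / 120 ms = 50 Hz; cluster 1 fires 9 spikes per ripple
  # window (75 Hz, a 50% increase), cluster 2 stays at baseline
  u$spike_times <- list(
    regular_unit(starts, n_base = 6, n_rip = 9),
    regular_unit(starts, n_base = 6, n_rip = 6))
  rec <- modulation_index(u, rip)
  full <- rec[rec$window == "full", ]
  expect_equal(full$modulation[full$cluster_id == "u001"], c(0.5, 0.5))
  expect_equal(full$modulation[full$cluster_id == "u002"], c(0, 0))
  expect_equal(unique(full$baseline_hz), 50)  # 6 spikes / 0.12 s
  # zero baseline flagged
  u0 <- mk_qc_units(1)
  u0$spike_times <- list(regular_unit(starts, n_base = 0, n_rip = 2))
  expect_warning(rec0 <- modulation_index(u0, rip), "zero baseline")
  expect_true(all(is.na(rec0$modulation)))
})

test_that("modulation index is invariant under uniform time rescaling", {
  withr::with_seed(51, {
    starts <- sort(runif(300, 10, 1990))
    rip <- tibble::tibble(start_s = starts, seed_section = "medial")
    u <- mk_qc_units(1)
    u$spike_times <- list(sort(runif(6000, 0, 2000)))
    a <- modulation_index(u, rip)
    k <- 3
    u2 <- u; u2$spike_times <- list(u$spike_times[[1]] * k)
    rip2 <- tibble::tibble(start_s = starts * k, seed_section = "medial")
    b <- modulation_index(u2, rip2,
                          windows = lapply(modulation_windows(), `*`, k),
                          baseline_window = c(-0.12, 0) * k)
    expect_equal(a$modulation, b$modulation)
  })
})

test_that("Poisson gain is recovered as index g - 1", {
  withr::with_seed(52, {
    g <- 1.5; lam <- 5; n_rip <- 1500
    starts <- seq(5, 5 + (n_rip - 1) * 0.6, by = 0.6)
    L <- max(starts) + 5
    rip <- tibble::tibble(start_s = starts, seed_section = "medial")
    u <- mk_qc_units(30, rate = lam)
    u$spike_times <- purrr::map(seq_len(nrow(u)), function(i) {
      base <- runif(rpois(1, lam * L), 0, L)
      extra <- unlist(lapply(starts, function(s) {
        s + runif(rpois(1, (g - 1) * lam * 0.12), 0, 0.12)
      }))
      sort(c(base, extra))
    })
    rec <- modulation_index(u, rip)
    est <- mean(rec$modulation[rec$window == "full"])
    expect_equal(est, g - 1, tolerance = 0.03)
  })
})

test_that("modulated flag uses an inclusive 50% threshold on either seed type", {
  rec <- tibble::tibble(
    cluster_id = rep(sprintf("u%d", 1:3), each = 2),
    area = "CA1", ml = 1, window = "full",
    seed_type = rep(c("medial", "lateral"), 3),
    rate_hz = 1, baseline_hz = 1,
    modulation = c(0.6, 0.1, 0.4, 0.4, 0.5, 0.2))
  out <- classify_modulated(rec)
  expect_equal(out$is_modulated[match(sprintf("u%d", 1:3), out$cluster_id)],
               c(TRUE, FALSE, TRUE))  # 0.5 exactly counts ("at least")
})

test_that("preference classes follow the twofold rule with sign guard", {
  mk <- function(m_med, m_lat) {
    tibble::tibble(cluster_id = "u1", area = "CA1", ml = 1, window = "full",
                   seed_type = c("medial", "lateral"), rate_hz = 1,
                   baseline_hz = 1, modulation = c(m_med, m_lat))
  }
  expect_equal(as.character(classify_preference(mk(0.8, 0.2))$preference),
               "medial")
  expect_equal(as.character(classify_preference(mk(0.8, 0.6))$preference),
               "none")
  # sign guard: non-positive comparison modulation satisfies the ratio
  expect_equal(as.character(classify_preference(mk(0.6, -0.1))$preference),
               "medial")
  expect_equal(as.character(classify_preference(mk(-0.2, 0.7))$preference),
               "lateral")
  expect_equal(as.character(classify_preference(mk(0.4, -0.5))$preference),
               "none")  # below the absolute floor
  # fractions over clusters sum to 1
  rec <- dplyr::bind_rows(mk(0.8, 0.2), mk(0.1, 0.9), mk(0.3, 0.3))
  rec$cluster_id <- rep(c("a", "b", "c"), each = 2)
  fr <- attr(classify_preference(rec), "fractions")
  expect_equal(sum(fr), 1)
})

test_that("M-L variance explained matches the planted construction", {
  withr::with_seed(53, {
    n <- 400
    ml <- runif(n, 1000, 4000)
    mk_rec <- function(contrast) {
      tibble::tibble(
        cluster_id = rep(sprintf("u%03d", 1:n), each = 2),
        area = "CA1", ml = rep(ml, each = 2), window = "early",
        seed_type = rep(c("medial", "lateral"), n),
        rate_hz = 1, baseline_hz = 1,
        modulation = as.vector(rbind(contrast, rep(0, n))))
    }
    suppressWarnings(  # lm flags the deliberately perfect fit
      exact <- ml_variance_explained(mk_rec(0.0003 * ml), window = "early"))
    expect_equal(exact$r_squared, 1, tolerance = 1e-9)
    flat <- ml_variance_explained(mk_rec(rnorm(n, 0, 0.1)), window = "early")
    expect_lt(flat$r_squared, 0.05)
    # planted slope + noise: R^2 ~ a^2 Var(ml) / (a^2 Var(ml) + sigma^2)
    a <- 3e-4; sig <- 0.2
    got <- ml_variance_explained(mk_rec(a * ml + rnorm(n, 0, sig)),
                                 window = "early")
    expected <- a^2 * var(ml) / (a^2 * var(ml) + sig^2)
    expect_lt(abs(got$r_squared - expected), 0.05)
  })
})

test_that("baseline-vs-ripple rates average over seed types", {
  rec <- tibble::tibble(
    cluster_id = rep("u1", 2), area = "CA1", ml = 1, window = "full",
    seed_type = c("medial", "lateral"),
    rate_hz = c(4, 6), baseline_hz = c(2, 2), modulation = c(1, 2))
  out <- baseline_ripple_rates(rec)
  expect_equal(out$ripple_hz, 5)
  expect_equal(out$baseline_hz, 2)
})
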