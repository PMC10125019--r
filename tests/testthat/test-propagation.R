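three_sections <- function() {
  assign_sections(tibble::tibble(probe_id = sprintf("probe%02d", 1:6),
                                 ml = seq(1000, 3500, length.out = 6)))
}

mk_events <- function(probe, starts, strength = NULL, dur = 0.08) {
  tibble::tibble(probe_id = probe, start_s = starts,
                 strength = strength %||% rep(1, length(starts)),
                 duration_s = dur)
}

test_that("clusters keep the first event per probe inside the window", {
  ref <- tibble::tibble(start_s = 10, strength = 1, duration_s = 0.08,
                        is_strong = FALSE)
  evs <- dplyr::bind_rows(
    mk_events("probe01", 10),
    mk_events("probe02", 10.010),
    mk_events("probe03", c(10.005, 10.030)),  # second event ignored
    mk_events("probe04", 10.070))             # outside +/-60 ms
  mem <- build_clusters(ref, evs)
  expect_equal(nrow(mem), 3)
  expect_equal(mem$lag_ms[mem$probe_id == "probe03"], 5)
  expect_equal(sort(mem$lag_ms), c(0, 5, 10))
})

test_that("cluster membership equals an exhaustive window scan", {
  withr::with_seed(13, {
    probes <- sprintf("probe%02d", 1:5)
    evs <- purrr::map(probes, function(p) {
      mk_events(p, sort(runif(60, 0, 300)), strength = rlnorm(60))
    }) |> purrr::list_rbind()
    ref <- evs[evs$probe_id == "probe01", ]
    ref$is_strong <- FALSE
    mem <- build_clusters(ref, evs)
    # brute-force oracle
    for (ci in seq_len(nrow(ref))) {
      for (p in probes) {
        cand <- evs$start_s[evs$probe_id == p]
        cand <- cand[cand >= ref$start_s[ci] - 0.06 &
                       cand <= ref$start_s[ci] + 0.06]
        got <- mem$start_s[mem$cluster_id == ci & mem$probe_id == p]
        if (length(cand) == 0) {
          expect_equal(length(got), 0)
        } else {
          expect_equal(got, min(cand))
        }
      }
    }
  })
})

test_that("seed is the earliest member, ties resolve medially", {
  sec <- three_sections()
  mem <- build_clusters(
    tibble::tibble(start_s = 5, strength = 1, duration_s = 0.08,
                   is_strong = FALSE),
    dplyr::bind_rows(mk_events("probe05", 5),
                     mk_events("probe01", 5.012),
                     mk_events("probe03", 5.006)))
  seed <- identify_seeds(mem, sec)
  expect_equal(seed$seed_probe, "probe05")
  expect_equal(as.character(seed$seed_section), "lateral")
  # exact tie cases: enumerate pairs with simultaneous starts
  for (pair in list(c("probe02", "probe04"), c("probe01", "probe06"),
                    c("probe03", "probe05"))) {
    memt <- build_clusters(
      tibble::tibble(start_s = 1, strength = 1, duration_s = 0.08,
                     is_strong = FALSE),
      dplyr::bind_rows(mk_events(pair[1], 1), mk_events(pair[2], 1)))
    st <- identify_seeds(memt, sec)
    expect_equal(st$seed_probe, pair[1])  # the more medial probe
  }
})

test_that("SCI counts sections above their top-decile strength", {
  sec <- three_sections()
  evs <- purrr::map(sprintf("probe%02d", 1:6), function(p) {
    mk_events(p, 1:100, strength = 1:100)
  }) |> purrr::list_rbind()
  thr <- section_strength_thresholds(evs, sec)
  expect_equal(nrow(thr), 3)
  expect_equal(thr$threshold, rep(quantile(1:100, 0.9, names = FALSE), 3))
  ref <- mk_events("probe01", c(1, 2, 3))
  ref$is_strong <- c(TRUE, FALSE, FALSE)
  # cluster 1: all members above threshold -> SCI 1; cluster 2: none -> 0;
  # cluster 3: only the medial member above -> 1/3
  evs2 <- dplyr::bind_rows(
    mk_events("probe01", c(1, 2, 3), strength = c(99, 1, 95)),
    mk_events("probe03", c(1.01, 2.01, 3.01), strength = c(95, 2, 3)),
    mk_events("probe05", c(1.02, 2.02, 3.02), strength = c(92, 3, 4)))
  mem <- build_clusters(ref, evs2)
  cl <- summarize_clusters(mem, sec, thresholds = thr,
                           detecting_probes = sprintf("probe%02d", 1:6))
  expect_equal(cl$sci, c(1, 0, 1 / 3))
  expect_equal(cl$spatial_engagement, rep(3 / 6, 3))
})

test_that("propagation speed matches closed-form OLS and guards degenerate lags", {
  sec <- three_sections()
  ref <- mk_events("probe01", 1); ref$is_strong <- FALSE
  ml <- seq(1000, 3500, length.out = 6)
  lags <- (ml - ml[1]) / 170  # ms
  evs <- purrr::map(1:6, function(i) {
    mk_events(sprintf("probe%02d", i), 1 + lags[i] / 1000)
  }) |> purrr::list_rbind()
  mem <- build_clusters(ref, evs)
  cl <- summarize_clusters(mem, sec)
  expect_equal(cl$speed_um_per_ms, 170, tolerance = 0.02)
  # oracle on 3 collinear points
  x <- c(0, 4, 10); y <- c(1000, 1680, 2700)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  mem3 <- build_clusters(ref, purrr::map(1:3, function(i) {
    mk_events(sprintf("probe%02d", i * 2 - 1), 1 + x[i] / 1000)
  }) |> purrr::list_rbind())
  # place members at those ml positions via a custom section table
  sec3 <- assign_sections(tibble::tibble(
    probe_id = sprintf("probe%02d", c(1, 3, 5)), ml = y))
  cl3 <- summarize_clusters(mem3, sec3)
  expect_equal(cl3$speed_um_per_ms, slope, tolerance = 1e-6)
  # all-equal lags: undefined speed
  sim <- build_clusters(ref, purrr::map(1:6, function(i) {
    mk_events(sprintf("probe%02d", i), 1.005)
  }) |> purrr::list_rbind())
  expect_true(is.na(summarize_clusters(sim, sec)$speed_um_per_ms))
})

test_that("seed-section frequencies are a distribution per reference", {
  withr::with_seed(17, {
    sec <- three_sections()
    probes <- sprintf("probe%02d", 1:6)
    evs <- purrr::map(probes, function(p) {
      mk_events(p, sort(runif(200, 0, 2000)), strength = rlnorm(200))
    }) |> purrr::list_rbind()
    ref <- evs[evs$probe_id == "probe03", ]
    ref$is_strong <- FALSE
    cl <- summarize_clusters(build_clusters(ref, evs), sec)
    freq <- prop.table(table(cl$seed_section))
    expect_equal(sum(freq), 1)
    expect_true(all(freq >= 0))
  })
})

test_that("propagation map is linear when lag is exactly distance over speed", {
  sec <- three_sections()
  ml <- sec$ml[order(sec$probe_id)]
  speed <- 200
  ref <- mk_events("probe01", 1:50); ref$is_strong <- rep(c(TRUE, FALSE), 25)
  evs <- purrr::map(1:6, function(i) {
    mk_events(sprintf("probe%02d", i), 1:50 + (ml[i] - ml[1]) / speed / 1000)
  }) |> purrr::list_rbind()
  mem <- build_clusters(ref, evs)
  map_df <- propagation_map(mem, sec)
  fit <- lm(mean_lag_ms ~ ml, data = map_df)
  expect_equal(unname(coef(fit)[2]), 1 / speed, tolerance = 1e-6)
  # interpolation: midpoint of a two-probe ramp is the mean of the endpoints
  two <- tibble::tibble(ml = c(0, 100), v = c(1, 3))
  grid <- interpolate_ml(two, "v", grid = c(0, 50, 100))
  expect_equal(grid$v, c(1, 2, 3))
})

test_that("partial correlation matches the residual-regression definition", {
  withr::with_seed(23, {
    n <- 200
    ml <- runif(n, 1000, 4000)
    ap <- runif(n, 7000, 9000)
    lag <- 0.01 * ml + rnorm(n, 0, 3)
    out <- axis_partial_correlation(tibble::tibble(lag_ms = lag, ml = ml,
                                                   ap = ap))
    expect_gt(out$r_squared[out$axis == "ml"], 0.8)
    expect_lt(out$r_squared[out$axis == "ap"], 0.05)
    # oracle: correlate residuals after regressing out the other axis
    res_lag_ap <- resid(lm(lag ~ ap))
    res_ml_ap <- resid(lm(ml ~ ap))
    expect_equal(out$r_partial[out$axis == "ml"],
                 cor(res_lag_ap, res_ml_ap), tolerance = 1e-10)
    res_lag_ml <- resid(lm(lag ~ ml))
    res_ap_ml <- resid(lm(ap ~ ml))
    expect_equal(out$r_partial[out$axis == "ap"],
                 cor(res_lag_ml, res_ap_ml), tolerance = 1e-10)
    # pure noise: both small
    noise <- axis_partial_correlation(
      tibble::tibble(lag_ms = rnorm(n), ml = ml, ap = ap))
    expect_true(all(noise$r_squared < 0.05))
    expect_error(axis_partial_correlation(
      tibble::tibble(lag_ms = rnorm(10), ml = 1:10, ap = 2 * (1:10))),
      "collinear")
  })
})
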