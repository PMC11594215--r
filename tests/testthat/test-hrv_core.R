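test_that("time-domain metrics match hand-computed values", {
  expect_equal(rmssd(c(800, 800, 800)), 0)
  expect_equal(rmssd(c(800, 810, 800, 810, 800)), 10)
  expect_equal(sdnn(rep(750, 10)), 0)
  expect_equal(sdnn(c(800, 820)), sqrt(200))  # n - 1 convention: 14.142...
  expect_equal(avnn(800), 800)
  expect_equal(avnn(c(750, 850)), 800)
  expect_error(rmssd(800), "at least 2")
  expect_error(sdnn(800), "at least 2")
  expect_error(avnn(numeric(0)), "at least 1")
})

test_that("estimators recover the analytic values for i.i.d. Gaussian intervals", {
  # For i.i.d. noise with sd 30 ms, SDNN estimates 30 and RMSSD 30 * sqrt(2)
  set.seed(1)
  nn <- 1000 + rnorm(10000, 0, 30)
  expect_equal(sdnn(nn), 30, tolerance = 0.02)
  expect_equal(rmssd(nn), 30 * sqrt(2), tolerance = 0.02)
})

test_that("metrics are shift-invariant, scale-equivariant and obey the successive-difference bound", {
  set.seed(2)
  for (i in 1:20) {
    nn <- 800 + rnorm(50, 0, 25)
    expect_equal(rmssd(nn + 123), rmssd(nn))
    expect_equal(sdnn(nn + 123), sdnn(nn))
    expect_equal(rmssd(nn * 2.5), 2.5 * rmssd(nn))
    expect_equal(sdnn(nn * 2.5), 2.5 * sdnn(nn))
    n <- length(nn)
    expect_lte(rmssd(nn), 2 * sdnn(nn) * sqrt(n / (n - 1)) + 1e-12)
  }
})

test_that("windows tile the walk and a 20-min walk yields 20 windows", {
  s <- three_phase_series(1000, walk_s = 1200)
  win <- window_metrics(slice_phase(s, "walk"))
  expect_equal(nrow(win), 20L)
  expect_equal(win$start_s, seq(0, 1140, by = 60))
  expect_true(all(win$rmssd_ms == 0))
  expect_true(all(win$sdnn_ms == 0))
  expect_true(all(win$avnn_ms == 1000))
})

test_that("a 21.5-min walk yields 21 full windows plus a retained partial tail", {
  s <- ibi_series(rep(1000, 1290), phases = data.frame(
    phase = "walk", start_s = 0, end_s = 1290), walk_duration_bounds = NULL)
  win <- window_metrics(slice_phase(s, "walk"))
  expect_equal(nrow(win), 22L)
  expect_equal(win$end_s[22], 1290)
  expect_equal(win$end_s[22] - win$start_s[22], 30)
  # a partial tail too short to hold min_beats is dropped outright
  s2 <- ibi_series(rep(1000, 1205), phases = data.frame(
    phase = "walk", start_s = 0, end_s = 1205), walk_duration_bounds = NULL)
  expect_equal(nrow(window_metrics(slice_phase(s2, "walk"))), 20L)
  expect_error(window_metrics(slice_phase(s, "walk"), window_s = 0),
               "positive")
})

test_that("sparse windows are emitted with missing metrics", {
  # beats only in the second minute: window 0 exists but has no usable data
  nn <- rep(1000, 180)
  cum <- c(seq(0.5, 5, by = 0.5), seq(60.5, 120, length.out = 170))
  s <- ibi_series(nn[seq_along(cum)], cum_time_s = cum,
                  phases = data.frame(phase = "walk", start_s = 0, end_s = 120),
                  walk_duration_bounds = NULL)
  win <- window_metrics(slice_phase(s, "walk"), min_beats = 15L)
  expect_equal(nrow(win), 2L)
  expect_true(is.na(win$rmssd_ms[1]))
  expect_false(is.na(win$rmssd_ms[2]))
})

test_that("windowed metrics equal direct per-window computation (oracle)", {
  set.seed(4)
  s <- simulate_nn_series(850, 60, 45, 600)
  s$phases <- data.frame(phase = "walk", start_s = 0, end_s = 600)
  walk <- slice_phase(s, "walk")
  win <- window_metrics(walk, window_s = 60, min_beats = 10L)
  for (k in win$index) {
    sel <- walk$cum_time_s >= k * 60 &
      (walk$cum_time_s < (k + 1) * 60 | ((k + 1) * 60 == 600 &
                                           walk$cum_time_s == 600))
    row <- win[win$index == k, ]
    expect_equal(row$n_beats, sum(sel))
    expect_equal(row$rmssd_ms, rmssd(walk$intervals[sel]))
    expect_equal(row$sdnn_ms, sdnn(walk$intervals[sel]))
    expect_equal(row$avnn_ms, avnn(walk$intervals[sel]))
  }
})

test_that("baseline metrics use the whole rest phase and need 60 s of data", {
  s <- three_phase_series(1000, pre_s = 300, walk_s = 1200)
  b <- baseline_metrics(slice_phase(s, "pre_rest"))
  expect_equal(b$rmssd_ms, 0)
  expect_equal(b$sdnn_ms, 0)
  expect_equal(b$avnn_ms, 1000)
  expect_equal(b$n_beats, 299L)

  short <- ibi_series(rep(1000, 30))
  expect_error(baseline_metrics(short), "60 s")
})

test_that("baseline estimates recover configured generator targets", {
  set.seed(6)
  s <- simulate_nn_series(850, 65, 40, 300)
  expect_equal(sdnn(s$intervals), 65, tolerance = 0.1)
  expect_equal(rmssd(s$intervals), 40, tolerance = 0.1)
})
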