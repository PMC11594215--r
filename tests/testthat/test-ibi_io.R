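test_that("read_ibi parses intervals and rebuilds the cumulative beat clock", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("800", "820", "790"), f)
  s <- read_ibi(f)
  expect_equal(s$intervals, c(800, 820, 790))
  expect_equal(s$cum_time_s, c(0.8, 1.62, 2.41))

  # a header row is tolerated
  writeLines(c("interval_ms", "800", "820"), f)
  expect_equal(read_ibi(f)$intervals, c(800, 820))
})

test_that("read_ibi rejects empty files and names the offending line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(read_ibi(f), "empty")
  writeLines(c("800", "oops", "790"), f)
  expect_error(read_ibi(f), "line 2")
  expect_error(read_ibi(file.path(tempdir(), "no-such-file.csv")),
               "not found")
})

test_that("a sidecar phase file attaches three phases spanning the recording", {
  f <- withr::local_tempfile(fileext = ".csv")
  pf <- withr::local_tempfile(fileext = ".csv")
  writeLines(as.character(rep(1000, 1800)), f)
  writeLines(c("phase,start_s,end_s", "pre_rest,0,300", "walk,300,1500",
               "post_rest,1500,1800"), pf)
  s <- read_ibi(f, phase_file = pf)
  expect_equal(nrow(s$phases), 3L)
  expect_equal(s$duration_s, 1800)
  walk <- slice_phase(s, "walk")
  expect_equal(length(walk$intervals), 1200L)
  expect_equal(walk$duration_s, 1200)
})

test_that("read -> write -> read round-trips intervals and phases bit-identically", {
  set.seed(3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  pf <- withr::local_tempfile(fileext = ".csv")
  nn <- 850 + rnorm(2100, 0, 40)
  orig <- ibi_series(nn, phases = data.frame(
    phase = c("pre_rest", "walk", "post_rest"),
    start_s = c(0, 300, 1500.25), end_s = c(300, 1500.25, 1800)),
    walk_duration_bounds = NULL)
  write_ibi(orig, f1, phase_file = pf)
  r1 <- read_ibi(f1, phase_file = pf, walk_duration_bounds = NULL)
  write_ibi(r1, f2)
  r2 <- read_ibi(f2, phase_file = pf, walk_duration_bounds = NULL)
  expect_identical(r1$intervals, orig$intervals)
  expect_identical(r2$intervals, r1$intervals)
  expect_identical(r1$phases, orig$phases)
})

test_that("per-beat phase labels reconstruct phase spans that tile the recording", {
  f <- withr::local_tempfile(fileext = ".csv")
  s <- three_phase_series(1000, pre_s = 120, walk_s = 300, post_s = 120)
  write_ibi(s, f)
  r <- read_ibi(f, walk_duration_bounds = NULL)
  expect_equal(r$phases$phase, c("pre_rest", "walk", "post_rest"))
  expect_equal(r$phases$start_s[-1], r$phases$end_s[-3])
})

test_that("series invariants are enforced", {
  expect_error(ibi_series(numeric(0)), "at least one")
  expect_error(ibi_series(c(800, -5)), "positive")
  expect_error(ibi_series(c(800, 800), cum_time_s = c(1, 1)),
               "strictly increasing")
  expect_error(
    ibi_series(rep(1000, 100), phases = data.frame(
      phase = c("walk", "pre_rest"), start_s = c(0, 40), end_s = c(50, 90))),
    "non-overlapping")
  # a 10-minute walk violates the default admissible walk duration
  expect_error(
    ibi_series(rep(1000, 700), phases = data.frame(
      phase = "walk", start_s = 0, end_s = 600)),
    "walk duration")
})

test_that("clean_nn removes bound and jump artifacts and keeps the raw clock", {
  s <- ibi_series(c(800, 3000, 810))
  out <- clean_nn(s)
  expect_equal(out$series$intervals, c(800, 810))
  expect_equal(out$qc$n_removed, 1L)
  expect_equal(unname(out$qc$removal_reasons[["out_of_range"]]), 1L)
  # retained beats keep their original cumulative times
  expect_equal(out$series$cum_time_s, c(0.8, 4.61))

  const <- ibi_series(rep(800, 100))
  expect_equal(clean_nn(const)$qc$n_removed, 0L)

  # a 50% in-range jump is removed by the successive-difference rule
  j <- clean_nn(ibi_series(c(800, 1200, 820)))
  expect_equal(j$series$intervals, c(800, 820))
  expect_equal(unname(j$qc$removal_reasons[["jump"]]), 1L)
})

test_that("clean_nn is idempotent and flags heavily corrupted recordings", {
  set.seed(8)
  nn <- 850 + rnorm(500, 0, 30)
  spike_at <- sort(sample(500, 150))  # 30% injected artifacts
  nn[spike_at] <- nn[spike_at] * 3
  out <- clean_nn(ibi_series(nn))
  expect_gte(out$qc$n_removed, length(spike_at))
  expect_false(out$qc$usable)
  again <- clean_nn(out$series)
  expect_equal(again$qc$n_removed, 0L)
  expect_identical(again$series$intervals, out$series$intervals)
})

test_that("slice_phase uses half-open spans and partitions retained beats", {
  s <- three_phase_series(1000, pre_s = 120, walk_s = 300, post_s = 120)
  pre <- slice_phase(s, "pre_rest")
  walk <- slice_phase(s, "walk")
  post <- slice_phase(s, "post_rest")
  # the beat ending exactly at 120 s belongs to the walk, not the pre-rest
  expect_length(pre$intervals, 119L)
  expect_equal(walk$cum_time_s[1], 0)  # re-zeroed to phase start
  # concatenating the slices recovers every beat exactly once
  expect_equal(length(pre$intervals) + length(walk$intervals) +
                 length(post$intervals), length(s$intervals))
  expect_equal(c(pre$cum_time_s, walk$cum_time_s + 120,
                 post$cum_time_s + 420), s$cum_time_s)

  no_post <- ibi_series(rep(1000, 100), phases = data.frame(
    phase = "pre_rest", start_s = 0, end_s = 100))
  expect_error(slice_phase(no_post, "post_rest"), "not present")
})

test_that("side data requires cortisol as concentrations or percent change", {
  df <- data.frame(subject_id = c("a", "a"), condition = c("green", "urban"),
                   walk_order = c("first", "second"),
                   cortisol_pre = c(10, 8), cortisol_post = c(5, 6))
  v <- greenwalk:::validate_side_data(df)
  expect_equal(v$cortisol_pct_change, c(-50, -25))
  df2 <- df
  df2$cortisol_post <- NA_real_
  expect_error(greenwalk:::validate_side_data(df2), "percent change")
  df3 <- df
  df3$walk_order <- c("first", "first")
  expect_error(greenwalk:::validate_side_data(df3), "'first' and one 'second'")
})
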