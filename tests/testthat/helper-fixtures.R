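# Shared in-code fixtures for the test suite.

# A windowed-HRV table with prescribed per-window values (both metrics equal),
# bypassing beat-level computation so the spline stage can be tested on exact
# inputs.
mock_windows <- function(values, window_s = 60) {
  n <- length(values)
  structure(
    data.frame(index = seq_len(n) - 1L,
               start_s = (seq_len(n) - 1L) * window_s,
               end_s = seq_len(n) * window_s,
               n_beats = 60L,
               rmssd_ms = values, sdnn_ms = values, avnn_ms = 850),
    window_s = window_s, duration_s = n * window_s,
    class = c("hrv_windows", "data.frame")
  )
}

# A constant-interval recording with the standard three-phase layout.
three_phase_series <- function(interval_ms = 1000, pre_s = 300,
                               walk_s = 1200, post_s = 300, ...) {
  total <- pre_s + walk_s + post_s
  n <- floor(total / (interval_ms / 1000))
  ibi_series(rep(interval_ms, n),
             phases = data.frame(
               phase = c("pre_rest", "walk", "post_rest"),
               start_s = c(0, pre_s, pre_s + walk_s),
               end_s = c(pre_s, pre_s + walk_s, total)),
             walk_duration_bounds = NULL, ...)
}

# A small, fast cohort configuration (short phases) for end-to-end tests;
# overrides win over the speed defaults.
fast_config <- function(...) {
  args <- list(n_subjects = 3L, group_proportions = c(1, 1, 1) / 3,
               seed = 11L, pre_rest_s = 120, post_rest_s = 120,
               urban_walk_s = 600, green_walk_range_s = c(600, 660))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# Closed-form first-order partial correlation from a correlation matrix.
partial_r_closed_form <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}
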