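#' Time-domain HRV metrics
#'
#' `rmssd()` is the root mean square of successive NN-interval differences
#' (short-term, parasympathetically dominated variability); `sdnn()` is the
#' sample standard deviation of the intervals (total variability, `n - 1`
#' denominator); `avnn()` is the mean NN interval. All take and return
#' milliseconds.
#'
#' @param nn numeric vector of NN intervals in ms.
#' @return A single value in ms.
#' @examples
#' rmssd(c(800, 810, 800, 810, 800))  # every successive difference is 10 ms
#' sdnn(c(800, 820))
#' @export
rmssd <- function(nn) {
  nn <- as.numeric(nn)
  if (length(nn) < 2L) {
    stop("rmssd needs at least 2 intervals", call. = FALSE)
  }
  sqrt(mean(diff(nn)^2))
}

#' @rdname rmssd
#' @export
sdnn <- function(nn) {
  nn <- as.numeric(nn)
  if (length(nn) < 2L) {
    stop("sdnn needs at least 2 intervals", call. = FALSE)
  }
  sd(nn)
}

#' @rdname rmssd
#' @export
avnn <- function(nn) {
  nn <- as.numeric(nn)
  if (length(nn) < 1L) {
    stop("avnn needs at least 1 interval", call. = FALSE)
  }
  mean(nn)
}

#' Windowed time-domain HRV over a walk
#'
#' Tiles the phase span `[0, duration)` with consecutive half-open windows
#' `[k w, (k+1) w)` aligned to the phase start and computes RMSSD, SDNN and
#' AVNN per window from the beats whose end times fall inside it. There are
#' `floor(duration / w)` full windows; a final partial window is retained
#' only if it holds at least `min_beats` beats. Full windows with fewer than
#' `min_beats` beats are emitted with their metrics set to `NA` (they are
#' bridged later by the smoothing spline rather than imputed here).
#'
#' @param walk an [ibi_series()], normally the output of [slice_phase()]
#'   (times re-zeroed to the phase start).
#' @param window_s window length in seconds (default 60).
#' @param min_beats minimum beats for a window's metrics to be computed.
#'
#' @return A `data.frame` of class `hrv_windows` with columns `index`
#'   (0-based), `start_s`, `end_s`, `n_beats`, `rmssd_ms`, `sdnn_ms`,
#'   `avnn_ms`, and attributes `window_s` and `duration_s`.
#' @export
window_metrics <- function(walk, window_s = 60, min_beats = 10L) {
  stopifnot(inherits(walk, "ibi_series"))
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  if (length(walk$intervals) == 0L) stop("empty walk series", call. = FALSE)
  duration <- walk$duration_s
  n_full <- floor(duration / window_s)
  has_partial <- duration > n_full * window_s
  n_win <- n_full + as.integer(has_partial)
  idx <- pmin(floor(walk$cum_time_s / window_s), n_win - 1L)
  rows <- lapply(seq_len(n_win) - 1L, function(k) {
    beats <- walk$intervals[idx == k]
    n <- length(beats)
    ok <- n >= min_beats
    data.frame(
      index = k,
      start_s = k * window_s,
      end_s = min((k + 1) * window_s, duration),
      n_beats = n,
      rmssd_ms = if (ok && n >= 2L) rmssd(beats) else NA_real_,
      sdnn_ms = if (ok && n >= 2L) sdnn(beats) else NA_real_,
      avnn_ms = if (ok && n >= 1L) avnn(beats) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  # a short partial tail window is dropped outright
  if (has_partial && out$n_beats[n_win] < min_beats) {
    out <- out[-n_win, , drop = FALSE]
  }
  structure(out, window_s = window_s, duration_s = duration,
            class = c("hrv_windows", "data.frame"))
}

#' Whole-phase (baseline) HRV metrics
#'
#' Computes RMSSD, SDNN and AVNN over an entire rest phase as a single
#' unwindowed segment, as used for the seated pre-walk (and post-walk)
#' baseline recordings.
#'
#' @param rest an [ibi_series()] covering a rest phase, at least 60 s long.
#' @return A list with `rmssd_ms`, `sdnn_ms`, `avnn_ms`, `n_beats`,
#'   `duration_s`.
#' @export
baseline_metrics <- function(rest) {
  stopifnot(inherits(rest, "ibi_series"))
  if (rest$duration_s < 60) {
    stop("baseline metrics need at least 60 s of data", call. = FALSE)
  }
  list(rmssd_ms = rmssd(rest$intervals),
       sdnn_ms = sdnn(rest$intervals),
       avnn_ms = avnn(rest$intervals),
       n_beats = length(rest$intervals),
       duration_s = rest$duration_s)
}
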