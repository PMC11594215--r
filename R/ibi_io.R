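#' Construct an IBI (NN-interval) series
#'
#' An `ibi_series` holds one subject-session of NN intervals (milliseconds)
#' together with the cumulative beat clock and optional phase annotations
#' (`pre_rest`, `walk`, `post_rest`). The cumulative time of beat k is the sum
#' of the first k intervals, i.e. the time at which the beat *ends*, with the
#' clock origin at the start of the recording.
#'
#' @param intervals numeric vector of NN intervals in ms, all > 0.
#' @param subject_id subject label.
#' @param condition session condition, `"green"` or `"urban"` (or `NA`).
#' @param phases optional `data.frame` with columns `phase`, `start_s`,
#'   `end_s`; phases must be non-overlapping, ordered
#'   `pre_rest < walk < post_rest`, with half-open spans `[start_s, end_s)`.
#' @param cum_time_s optional cumulative beat-end times in seconds. Defaults
#'   to `cumsum(intervals) / 1000`. Supplied explicitly by [clean_nn()] so the
#'   original recording clock survives artifact removal.
#' @param walk_duration_bounds length-2 numeric, admissible walk-phase
#'   duration in seconds (default 15-25 min); `NULL` disables the check.
#'
#' @return An object of class `ibi_series`: a list with elements
#'   `subject_id`, `condition`, `intervals`, `cum_time_s`, `phases` and
#'   `duration_s` (phase-span end if phases are present, otherwise the last
#'   beat time).
#' @seealso [read_ibi()], [clean_nn()], [slice_phase()]
#' @export
ibi_series <- function(intervals, subject_id = NA_character_,
                       condition = NA_character_, phases = NULL,
                       cum_time_s = NULL,
                       walk_duration_bounds = c(900, 1500)) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) {
    stop("an NN-interval series must contain at least one beat", call. = FALSE)
  }
  if (anyNA(intervals) || any(intervals <= 0)) {
    stop("all NN intervals must be positive and non-missing", call. = FALSE)
  }
  if (is.null(cum_time_s)) {
    cum_time_s <- cumsum(intervals) / 1000
  } else {
    cum_time_s <- as.numeric(cum_time_s)
    if (length(cum_time_s) != length(intervals)) {
      stop("cum_time_s must have one entry per interval", call. = FALSE)
    }
    if (any(diff(cum_time_s) <= 0)) {
      stop("cum_time_s must be strictly increasing", call. = FALSE)
    }
  }
  if (!is.na(condition) && !condition %in% c("green", "urban")) {
    stop("condition must be 'green' or 'urban'", call. = FALSE)
  }
  duration_s <- cum_time_s[length(cum_time_s)]
  if (!is.null(phases)) {
    phases <- validate_phases(phases, walk_duration_bounds)
    duration_s <- max(duration_s, phases$end_s[nrow(phases)])
  }
  structure(
    list(subject_id = subject_id, condition = condition,
         intervals = intervals, cum_time_s = cum_time_s,
         phases = phases, duration_s = duration_s),
    class = "ibi_series"
  )
}

phase_levels <- c("pre_rest", "walk", "post_rest")

validate_phases <- function(phases, walk_duration_bounds = c(900, 1500)) {
  stopifnot(is.data.frame(phases))
  need <- c("phase", "start_s", "end_s")
  if (!all(need %in% names(phases))) {
    stop("phases need columns phase, start_s, end_s", call. = FALSE)
  }
  phases <- phases[, need]
  phases$phase <- as.character(phases$phase)
  if (!all(phases$phase %in% phase_levels)) {
    stop("phase labels must be one of: ", paste(phase_levels, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(phases$phase)) {
    stop("each phase may appear at most once", call. = FALSE)
  }
  phases <- phases[order(match(phases$phase, phase_levels)), , drop = FALSE]
  if (any(phases$end_s <= phases$start_s)) {
    stop("each phase must satisfy start_s < end_s", call. = FALSE)
  }
  if (nrow(phases) > 1L &&
      any(phases$start_s[-1L] < phases$end_s[-nrow(phases)])) {
    stop("phases must be non-overlapping and ordered pre_rest < walk < post_rest",
         call. = FALSE)
  }
  if (!is.null(walk_duration_bounds) && "walk" %in% phases$phase) {
    w <- phases[phases$phase == "walk", ]
    dur <- w$end_s - w$start_s
    if (dur < walk_duration_bounds[1] || dur > walk_duration_bounds[2]) {
      stop(sprintf("walk duration %.1f s outside admissible bounds [%g, %g] s",
                   dur, walk_duration_bounds[1], walk_duration_bounds[2]),
           call. = FALSE)
    }
  }
  rownames(phases) <- NULL
  phases
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> subject %s, condition %s: %d beats over %.1f s\n",
              x$subject_id, x$condition, length(x$intervals), x$duration_s))
  if (!is.null(x$phases)) {
    cat(sprintf("  phases: %s\n",
                paste(sprintf("%s [%g, %g)", x$phases$phase, x$phases$start_s,
                              x$phases$end_s), collapse = ", ")))
  }
  invisible(x)
}

#' Read an NN-interval recording from delimited text
#'
#' Reads a plain-text recording with one NN interval (ms) per row and an
#' optional second column of per-beat phase labels. An optional sidecar phase
#' file (`phase,start_s,end_s`) may be given instead of a phase column; it
#' takes precedence when both are present.
#'
#' @param path path to the recording.
#' @param phase_file optional path to a sidecar phase file.
#' @param subject_id,condition series annotations (see [ibi_series()]).
#' @param sep field separator; `""` (default) splits on commas or whitespace.
#' @param max_bad_rows number of non-numeric data rows tolerated (dropped
#'   with a warning) before parsing fails; the error names the first bad line.
#' @param walk_duration_bounds passed to [ibi_series()].
#'
#' @return An [ibi_series()].
#' @export
read_ibi <- function(path, phase_file = NULL, subject_id = NA_character_,
                     condition = NA_character_, sep = "",
                     max_bad_rows = 0L, walk_duration_bounds = c(900, 1500)) {
  if (!file.exists(path)) {
    stop("IBI file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("IBI file is empty: ", path, call. = FALSE)
  }
  split_re <- if (identical(sep, "")) "[,;[:space:]]+" else sep
  fields <- strsplit(trimws(lines), split_re)
  first_line <- 1L
  first_val <- suppressWarnings(as.numeric(fields[[1L]][1L]))
  if (is.na(first_val)) {
    first_line <- 2L  # header row
    if (length(lines) < 2L) {
      stop("IBI file contains a header but no data: ", path, call. = FALSE)
    }
  }
  body <- fields[first_line:length(fields)]
  raw_ms <- suppressWarnings(vapply(body, function(f) as.numeric(f[1L]),
                                    numeric(1)))
  bad <- which(is.na(raw_ms))
  if (length(bad) > max_bad_rows) {
    stop(sprintf("non-numeric interval at line %d of %s",
                 bad[1L] + first_line - 1L, path), call. = FALSE)
  }
  phase_col <- vapply(body, function(f)
    if (length(f) >= 2L) f[2L] else NA_character_, character(1))
  if (length(bad)) {
    warning(sprintf("dropped %d non-numeric row(s) from %s",
                    length(bad), path))
    raw_ms <- raw_ms[-bad]
    phase_col <- phase_col[-bad]
  }
  phases <- NULL
  if (!is.null(phase_file)) {
    if (!file.exists(phase_file)) {
      stop("phase file not found: ", phase_file, call. = FALSE)
    }
    phases <- read.csv(phase_file, stringsAsFactors = FALSE)
  } else if (any(!is.na(phase_col))) {
    phases <- phases_from_labels(phase_col, cumsum(raw_ms) / 1000)
  }
  ibi_series(raw_ms, subject_id = subject_id, condition = condition,
             phases = phases, walk_duration_bounds = walk_duration_bounds)
}

# Reconstruct phase spans from per-beat labels: each run of equal labels
# spans from the previous beat's end time (0 for the first) to the run's
# last beat end, so the spans tile the recording.
phases_from_labels <- function(labels, cum_time_s) {
  if (anyNA(labels)) {
    stop("per-beat phase labels must be present on every row", call. = FALSE)
  }
  runs <- rle(labels)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, ends_idx[-length(ends_idx)] + 1L)
  data.frame(
    phase = runs$values,
    start_s = c(0, cum_time_s[ends_idx[-length(ends_idx)]]),
    end_s = cum_time_s[ends_idx],
    stringsAsFactors = FALSE
  )
}

#' Write an NN-interval recording as delimited text
#'
#' Inverse of [read_ibi()]: writes `interval_ms[,phase]` rows, the per-beat
#' phase being the phase whose half-open span contains the beat's end time.
#' When `phase_file` is given the exact phase spans are also written as a
#' sidecar (`phase,start_s,end_s`), which round-trips phase marks
#' bit-identically.
#'
#' @param series an [ibi_series()].
#' @param path output file.
#' @param phase_file optional sidecar phase file path.
#' @return `path`, invisibly.
#' @export
write_ibi <- function(series, path, phase_file = NULL) {
  stopifnot(inherits(series, "ibi_series"))
  # %.17g guarantees doubles survive the text round trip bit-identically
  df <- data.frame(interval_ms = sprintf("%.17g", series$intervals))
  if (!is.null(series$phases)) {
    df$phase <- phase_of_beat(series$cum_time_s, series$phases)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(phase_file) && !is.null(series$phases)) {
    ph <- data.frame(phase = series$phases$phase,
                     start_s = sprintf("%.17g", series$phases$start_s),
                     end_s = sprintf("%.17g", series$phases$end_s))
    write.csv(ph, phase_file, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Phase containing each beat's end time under the half-open [start, end)
# convention; NA for beats outside every phase.
phase_of_beat <- function(cum_time_s, phases) {
  out <- rep(NA_character_, length(cum_time_s))
  last_end <- max(phases$end_s)
  for (i in seq_len(nrow(phases))) {
    inside <- cum_time_s >= phases$start_s[i] &
      (cum_time_s < phases$end_s[i] |
         (phases$end_s[i] == last_end & cum_time_s == phases$end_s[i]))
    out[inside] <- phases$phase[i]
  }
  out
}

#' Artifact-filter an NN-interval series
#'
#' Removes physiologically implausible beats: intervals outside
#' `[lower_ms, upper_ms]`, and intervals differing from the previously
#' *retained* interval by more than a relative fraction `max_rel_jump`
#' (successive-relative-difference filter). The cumulative clock of retained
#' beats is preserved from the raw recording so that downstream window
#' boundaries stay on the original time base.
#'
#' The defaults (300-2000 ms bounds, 20\% jump) are standard time-domain HRV
#' practice; the rule is sequential and therefore idempotent. A recording
#' losing more than `max_removed_frac` of its beats is flagged unusable.
#'
#' @param series an [ibi_series()].
#' @param lower_ms,upper_ms physiological bounds in ms.
#' @param max_rel_jump maximal relative difference vs the previous retained
#'   interval, in (0, 1].
#' @param max_removed_frac removal fraction above which `usable` is `FALSE`.
#'
#' @return A list with elements `series` (the cleaned [ibi_series()]) and
#'   `qc`, a `qc_report` list: `n_raw`, `n_removed`, `removal_reasons`
#'   (tally by rule), `removed_frac`, `usable`.
#' @export
clean_nn <- function(series, lower_ms = 300, upper_ms = 2000,
                     max_rel_jump = 0.2, max_removed_frac = 0.2) {
  stopifnot(inherits(series, "ibi_series"))
  if (!(lower_ms < upper_ms)) stop("lower_ms must be < upper_ms", call. = FALSE)
  if (!(max_rel_jump > 0 && max_rel_jump <= 1)) {
    stop("max_rel_jump must lie in (0, 1]", call. = FALSE)
  }
  x <- series$intervals
  keep <- logical(length(x))
  reason <- character(length(x))
  prev <- NA_real_
  for (i in seq_along(x)) {
    if (x[i] < lower_ms || x[i] > upper_ms) {
      reason[i] <- "out_of_range"
    } else if (!is.na(prev) && abs(x[i] - prev) / prev > max_rel_jump) {
      reason[i] <- "jump"
    } else {
      keep[i] <- TRUE
      prev <- x[i]
    }
  }
  n_raw <- length(x)
  n_removed <- sum(!keep)
  if (all(!keep)) {
    stop("recording unusable: no beats survive artifact filtering",
         call. = FALSE)
  }
  qc <- structure(
    list(n_raw = n_raw, n_removed = n_removed,
         removal_reasons = table(factor(reason[!keep],
                                        levels = c("out_of_range", "jump"))),
         removed_frac = n_removed / n_raw,
         usable = n_removed / n_raw <= max_removed_frac),
    class = "qc_report"
  )
  cleaned <- ibi_series(x[keep], subject_id = series$subject_id,
                        condition = series$condition, phases = series$phases,
                        cum_time_s = series$cum_time_s[keep],
                        walk_duration_bounds = NULL)
  cleaned$duration_s <- series$duration_s
  list(series = cleaned, qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d beats removed (%.1f%%); usable: %s\n",
              x$n_removed, x$n_raw, 100 * x$removed_frac, x$usable))
  invisible(x)
}

#' Extract one phase of an NN-interval series
#'
#' Returns the sub-series whose beat end times fall in the half-open span
#' `[start_s, end_s)` of the requested phase, with times re-zeroed to the
#' phase start. The returned series records the phase span length as its
#' `duration_s` (used by [window_metrics()] to tile windows), and carries a
#' single re-zeroed phase mark.
#'
#' @param series an [ibi_series()] with phase annotations.
#' @param phase one of `"pre_rest"`, `"walk"`, `"post_rest"`.
#' @return An [ibi_series()].
#' @export
slice_phase <- function(series, phase = c("pre_rest", "walk", "post_rest")) {
  stopifnot(inherits(series, "ibi_series"))
  phase <- match.arg(phase)
  if (is.null(series$phases) || !phase %in% series$phases$phase) {
    stop("phase '", phase, "' not present in this series", call. = FALSE)
  }
  p <- series$phases[series$phases$phase == phase, ]
  # half-open [start, end), except the recording's final boundary, which is
  # inclusive so that slicing all phases partitions the retained beats
  is_last <- p$end_s == max(series$phases$end_s)
  inside <- series$cum_time_s >= p$start_s &
    (series$cum_time_s < p$end_s |
       (is_last & series$cum_time_s == p$end_s))
  if (!any(inside)) {
    stop("phase '", phase, "' contains no beats", call. = FALSE)
  }
  out <- ibi_series(series$intervals[inside],
                    subject_id = series$subject_id,
                    condition = series$condition,
                    cum_time_s = series$cum_time_s[inside] - p$start_s,
                    phases = data.frame(phase = phase, start_s = 0,
                                        end_s = p$end_s - p$start_s,
                                        stringsAsFactors = FALSE),
                    walk_duration_bounds = NULL)
  out$duration_s <- p$end_s - p$start_s
  out
}

#' Read per-session side data (cortisol, mood scales, walk order)
#'
#' Expects one CSV row per subject-session with columns `subject_id`,
#' `condition`, `walk_order` (`first`/`second`), optional `cortisol_pre` /
#' `cortisol_post` (ng/mL) or `cortisol_pct_change` (percent), and the scale
#' scores `vigor_pre`, `vigor_post`, `tmd_pre`, `tmd_post`,
#' `mindfulness_pre`, `mindfulness_post`. `cortisol_pct_change` is derived
#' from the concentrations when both are present.
#'
#' @param path CSV path.
#' @return A validated `data.frame`.
#' @export
read_side_data <- function(path) {
  if (!file.exists(path)) stop("side-data file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_side_data(df)
}

validate_side_data <- function(df) {
  need <- c("subject_id", "condition", "walk_order")
  if (!all(need %in% names(df))) {
    stop("side data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$condition %in% c("green", "urban"))) {
    stop("condition must be 'green' or 'urban'", call. = FALSE)
  }
  if (!all(df$walk_order %in% c("first", "second"))) {
    stop("walk_order must be 'first' or 'second'", call. = FALSE)
  }
  for (col in c("cortisol_pre", "cortisol_post", "cortisol_pct_change"))
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  has_conc <- !is.na(df$cortisol_pre) & !is.na(df$cortisol_post)
  if (any(!has_conc & is.na(df$cortisol_pct_change))) {
    stop("each session needs cortisol pre & post concentrations or a percent change",
         call. = FALSE)
  }
  if (any(df$cortisol_pre[has_conc] <= 0)) {
    stop("cortisol_pre must be > 0", call. = FALSE)
  }
  df$cortisol_pct_change[has_conc] <-
    cortisol_pct_change(df$cortisol_pre[has_conc], df$cortisol_post[has_conc])
  for (sid in unique(df$subject_id)) {
    orders <- sort(df$walk_order[df$subject_id == sid])
    if (length(orders) == 2L && !identical(orders, c("first", "second"))) {
      stop("subject ", sid, " must have one 'first' and one 'second' session",
           call. = FALSE)
    }
  }
  df
}
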