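#' Mean of raw windowed HRV values during a walk
#'
#' Arithmetic mean (with sd and range) of the raw 60 s window values of one
#' metric across a walk. Per-subject contrasts and the published-style
#' per-subject table are built from these raw-window means, not from the
#' spline-resampled points (which feed the paired tests and plots).
#'
#' @param windows an `hrv_windows` table from [window_metrics()].
#' @param metric `"rmssd"` or `"sdnn"`.
#' @return A list with `mean`, `sd`, `min`, `max`, `n` (usable windows).
#' @export
walk_mean <- function(windows, metric = c("rmssd", "sdnn")) {
  stopifnot(inherits(windows, "hrv_windows"))
  metric <- match.arg(metric)
  v <- windows[[paste0(metric, "_ms")]]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("no usable windows for metric ", metric, call. = FALSE)
  }
  list(mean = mean(v),
       sd = if (length(v) >= 2L) sd(v) else NA_real_,
       min = min(v), max = max(v), n = length(v))
}

#' Assign a physiological response group from paired HRV deltas
#'
#' Classifies a subject by the signs of the green-minus-urban changes in the
#' two HRV metrics: both positive (higher HRV on the green walk, i.e. a
#' reduced physiological stress response) gives group 1; both negative gives
#' group 2; opposite signs give group 3 (mixed/inconclusive). A delta of
#' exactly 0 on either metric is treated as inconclusive and also yields
#' group 3.
#'
#' @param delta_rmssd,delta_sdnn green-minus-urban differences in mean
#'   walk RMSSD / SDNN (ms). Vectorised.
#' @return Integer vector of group labels in `{1, 2, 3}`.
#' @examples
#' assign_group(83, 57)    # both up -> 1
#' assign_group(-52, -34)  # both down -> 2
#' assign_group(3, -2)     # mixed -> 3
#' @export
assign_group <- function(delta_rmssd, delta_sdnn) {
  if (length(delta_rmssd) != length(delta_sdnn)) {
    stop("delta vectors must have equal length", call. = FALSE)
  }
  if (anyNA(delta_rmssd) || anyNA(delta_sdnn) ||
      any(!is.finite(delta_rmssd)) || any(!is.finite(delta_sdnn))) {
    stop("HRV deltas must be finite and non-missing", call. = FALSE)
  }
  ifelse(delta_rmssd > 0 & delta_sdnn > 0, 1L,
         ifelse(delta_rmssd < 0 & delta_sdnn < 0, 2L, 3L))
}

#' Stratify a cohort of subject contrasts into response groups
#'
#' Applies [assign_group()] to each subject's HRV deltas (unless a `group`
#' column is already present) and tabulates group sizes and percentages.
#'
#' @param contrasts a `data.frame` with columns `delta_rmssd` and
#'   `delta_sdnn` (and optionally `subject_id`, `group`).
#' @return A list of class `cohort_strata`: `assignments` (the input with a
#'   `group` column) and `table` (`data.frame` of `group`, `n`, `pct`).
#' @export
stratify_cohort <- function(contrasts) {
  stopifnot(is.data.frame(contrasts), nrow(contrasts) >= 1L)
  if (!"group" %in% names(contrasts)) {
    contrasts$group <- assign_group(contrasts$delta_rmssd,
                                    contrasts$delta_sdnn)
  }
  counts <- table(factor(contrasts$group, levels = 1:3))
  structure(
    list(assignments = contrasts,
         table = data.frame(group = 1:3,
                            n = as.integer(counts),
                            pct = 100 * as.integer(counts) / nrow(contrasts))),
    class = "cohort_strata"
  )
}

#' @export
print.cohort_strata <- function(x, ...) {
  cat("<cohort_strata>", nrow(x$assignments), "subjects\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Build a per-subject green-vs-urban contrast
#'
#' Combines the two sessions of one subject into the row of the
#' published-style per-subject table: raw-window means per arm, the
#' green-minus-urban deltas, a paired t-test on the position-matched
#' spline trajectories with its significance code, the response group, and
#' the per-arm cortisol percent changes.
#'
#' @param green_windows,urban_windows `hrv_windows` tables for the two walks.
#' @param green_traj_rmssd,urban_traj_rmssd,green_traj_sdnn,urban_traj_sdnn
#'   `walk_trajectory` tables from [resample_trajectory()].
#' @param subject_id subject label.
#' @param cortisol_pct_green,cortisol_pct_urban per-arm cortisol percent
#'   changes (negative = decrease), optional.
#' @return A one-row `data.frame` with the contrast fields.
#' @export
subject_contrast <- function(subject_id, green_windows, urban_windows,
                             green_traj_rmssd, urban_traj_rmssd,
                             green_traj_sdnn, urban_traj_sdnn,
                             cortisol_pct_green = NA_real_,
                             cortisol_pct_urban = NA_real_) {
  mg_r <- walk_mean(green_windows, "rmssd")
  mu_r <- walk_mean(urban_windows, "rmssd")
  mg_s <- walk_mean(green_windows, "sdnn")
  mu_s <- walk_mean(urban_windows, "sdnn")
  t_r <- paired_walk_test(green_traj_rmssd$value_ms, urban_traj_rmssd$value_ms)
  t_s <- paired_walk_test(green_traj_sdnn$value_ms, urban_traj_sdnn$value_ms)
  delta_r <- mg_r$mean - mu_r$mean
  delta_s <- mg_s$mean - mu_s$mean
  data.frame(
    subject_id = subject_id,
    mean_rmssd_green = mg_r$mean, sd_rmssd_green = mg_r$sd,
    min_rmssd_green = mg_r$min, max_rmssd_green = mg_r$max,
    mean_rmssd_urban = mu_r$mean, sd_rmssd_urban = mu_r$sd,
    min_rmssd_urban = mu_r$min, max_rmssd_urban = mu_r$max,
    mean_sdnn_green = mg_s$mean, sd_sdnn_green = mg_s$sd,
    min_sdnn_green = mg_s$min, max_sdnn_green = mg_s$max,
    mean_sdnn_urban = mu_s$mean, sd_sdnn_urban = mu_s$sd,
    min_sdnn_urban = mu_s$min, max_sdnn_urban = mu_s$max,
    delta_rmssd = delta_r, delta_sdnn = delta_s,
    t_p_rmssd = t_r$p, t_p_sdnn = t_s$p,
    sig_rmssd = t_r$code, sig_sdnn = t_s$code,
    group = assign_group(delta_r, delta_s),
    cortisol_pct_green = cortisol_pct_green,
    cortisol_pct_urban = cortisol_pct_urban,
    stringsAsFactors = FALSE
  )
}
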