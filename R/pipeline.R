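#' Pipeline configuration
#'
#' Collects the tunable analysis parameters: 60 s non-overlapping HRV
#' windows, 20 spline-resampled trajectory points per walk, smoothing factor
#' 0.4, artifact-filter bounds, the minimum beats per window, and the
#' significance thresholds (p < 0.01 strong, p < 0.1 weak).
#'
#' @param window_s HRV window length (s).
#' @param n_trajectory_points resampled points per walk.
#' @param smoothing_factor spline smoothing factor (see
#'   [fit_smoothing_spline()]).
#' @param lower_ms,upper_ms,max_rel_jump,max_removed_frac artifact-filter
#'   parameters (see [clean_nn()]).
#' @param min_beats minimum beats per window (see [window_metrics()]).
#' @param sig_thresholds strong/weak significance thresholds.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 60, n_trajectory_points = 20L,
                            smoothing_factor = 0.4,
                            lower_ms = 300, upper_ms = 2000,
                            max_rel_jump = 0.2, max_removed_frac = 0.2,
                            min_beats = 10L,
                            sig_thresholds = c(0.01, 0.1)) {
  stopifnot(window_s > 0, n_trajectory_points >= 2L, smoothing_factor >= 0,
            lower_ms > 0, lower_ms < upper_ms, max_rel_jump > 0,
            min_beats >= 2L, length(sig_thresholds) == 2L,
            sig_thresholds[1] < sig_thresholds[2])
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates, per subject and session: artifact filtering, phase slicing,
#' baseline (pre-rest) and post-rest HRV, windowed walk HRV, smoothing-spline
#' trajectory resampling; then, per subject: raw-window walk means, deltas,
#' paired trajectory tests, group assignment and cortisol changes; and, at
#' cohort level: stratification, group summaries, overall and order-split
#' cortisol means, and the mood-scale vs HRV partial-correlation grid.
#' A subject whose recording fails quality control (or any per-subject
#' error) is excluded and logged rather than aborting the cohort, mirroring
#' how corrupted recordings are handled in practice.
#'
#' @param cohort a `gw_cohort` (from [simulate_cohort()] or [read_cohort()])
#'   or a directory path readable by [read_cohort()].
#' @param config a [pipeline_config()].
#' @return A list of class `gw_report` with elements `contrasts` (per-subject
#'   table), `strata`, `group_summaries` (one row per group, including the
#'   significant-subset HRV columns as `*_sig`), `cortisol_overall`,
#'   `order_effect`, `partial_correlations`, `sessions`, `qc`, `exclusions`
#'   and `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "gw_cohort"), inherits(config, "pipeline_config"))
  contrasts <- list(); session_rows <- list(); qc_rows <- list()
  exclusions <- list()
  for (subj in cohort$subjects) {
    res <- tryCatch(
      analyse_subject(subj, config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      exclusions[[subj$subject_id]] <- conditionMessage(res)
      next
    }
    contrasts[[subj$subject_id]] <- res$contrast
    session_rows[[subj$subject_id]] <- res$sessions
    qc_rows[[subj$subject_id]] <- res$qc
  }
  if (length(contrasts) == 0L) {
    stop("no usable subjects in cohort; exclusions: ",
         paste(names(exclusions), unlist(exclusions),
               sep = ": ", collapse = "; "), call. = FALSE)
  }
  contrasts <- do.call(rbind, contrasts)
  rownames(contrasts) <- NULL
  sessions <- do.call(rbind, session_rows)
  rownames(sessions) <- NULL
  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL
  strata <- stratify_cohort(contrasts)
  summaries <- lapply(sort(unique(contrasts$group)), function(g) {
    sub <- contrasts[contrasts$group == g, , drop = FALSE]
    all_conv <- group_aggregate(sub, hrv_subset = "all")
    sig_conv <- group_aggregate(sub, hrv_subset = "significant")
    hrv_cols <- c("n_hrv", "mu_delta_rmssd", "sigma_delta_rmssd",
                  "pct_delta_rmssd", "mean_subject_pct_rmssd",
                  "mu_delta_sdnn", "sigma_delta_sdnn", "pct_delta_sdnn",
                  "mean_subject_pct_sdnn")
    sig_part <- sig_conv[hrv_cols]
    names(sig_part) <- paste0(hrv_cols, "_sig")
    cbind(as.data.frame(all_conv), sig_part)
  })
  group_summaries <- do.call(rbind, summaries)
  oe <- if (!anyNA(contrasts$green_order)) order_effect(contrasts) else NULL
  structure(
    list(contrasts = contrasts,
         strata = strata,
         group_summaries = group_summaries,
         cortisol_overall = overall_cortisol_means(contrasts),
         order_effect = oe,
         partial_correlations = mood_hrv_partial_correlations(sessions),
         sessions = sessions,
         qc = qc,
         exclusions = exclusions,
         config = config),
    class = "gw_report"
  )
}

# One subject: QC, phase metrics, trajectories, contrast row.
analyse_subject <- function(subj, config) {
  per_cond <- list(); qc_rows <- list(); ses_rows <- list()
  for (cond in c("green", "urban")) {
    ses <- subj$sessions[[cond]]
    if (is.null(ses)) stop("missing ", cond, " session")
    cleaned <- clean_nn(ses, lower_ms = config$lower_ms,
                        upper_ms = config$upper_ms,
                        max_rel_jump = config$max_rel_jump,
                        max_removed_frac = config$max_removed_frac)
    qc_rows[[cond]] <- data.frame(
      subject_id = subj$subject_id, condition = cond,
      n_raw = cleaned$qc$n_raw, n_removed = cleaned$qc$n_removed,
      removed_frac = cleaned$qc$removed_frac, usable = cleaned$qc$usable,
      stringsAsFactors = FALSE
    )
    if (!cleaned$qc$usable) {
      stop(sprintf("%s session failed QC (%.1f%% of beats removed)",
                   cond, 100 * cleaned$qc$removed_frac))
    }
    s <- cleaned$series
    pre <- baseline_metrics(slice_phase(s, "pre_rest"))
    post <- baseline_metrics(slice_phase(s, "post_rest"))
    walk <- slice_phase(s, "walk")
    win <- window_metrics(walk, window_s = config$window_s,
                          min_beats = config$min_beats)
    traj <- lapply(c(rmssd = "rmssd", sdnn = "sdnn"), function(m) {
      resample_trajectory(
        fit_smoothing_spline(win, metric = m, s = config$smoothing_factor),
        n = config$n_trajectory_points
      )
    })
    per_cond[[cond]] <- list(windows = win, traj = traj)
    side <- subj$side[subj$side$condition == cond, , drop = FALSE]
    ses_rows[[cond]] <- data.frame(
      subject_id = subj$subject_id, condition = cond,
      walk_order = side$walk_order,
      baseline_rmssd = pre$rmssd_ms, baseline_sdnn = pre$sdnn_ms,
      during_rmssd = walk_mean(win, "rmssd")$mean,
      during_sdnn = walk_mean(win, "sdnn")$mean,
      post_rmssd = post$rmssd_ms, post_sdnn = post$sdnn_ms,
      cortisol_pct_change = side$cortisol_pct_change,
      vigor_pre = side$vigor_pre, vigor_post = side$vigor_post,
      tmd_pre = side$tmd_pre, tmd_post = side$tmd_post,
      mindfulness_pre = side$mindfulness_pre,
      mindfulness_post = side$mindfulness_post,
      stringsAsFactors = FALSE
    )
  }
  contrast <- subject_contrast(
    subj$subject_id,
    green_windows = per_cond$green$windows,
    urban_windows = per_cond$urban$windows,
    green_traj_rmssd = per_cond$green$traj$rmssd,
    urban_traj_rmssd = per_cond$urban$traj$rmssd,
    green_traj_sdnn = per_cond$green$traj$sdnn,
    urban_traj_sdnn = per_cond$urban$traj$sdnn,
    cortisol_pct_green = ses_rows$green$cortisol_pct_change,
    cortisol_pct_urban = ses_rows$urban$cortisol_pct_change
  )
  contrast$green_order <- ses_rows$green$walk_order
  list(contrast = contrast,
       sessions = do.call(rbind, ses_rows),
       qc = do.call(rbind, qc_rows))
}

#' @export
print.gw_report <- function(x, ...) {
  cat(sprintf("<gw_report> %d subjects analysed, %d excluded\n",
              nrow(x$contrasts), length(x$exclusions)))
  print(x$strata$table, row.names = FALSE)
  co <- x$cortisol_overall
  cat(sprintf("cortisol change: green %.1f%%, urban %.1f%%\n",
              co$green, co$urban))
  invisible(x)
}

#' Load the published per-subject summary table
#'
#' Returns the embedded 17-subject summary (per-arm walk RMSSD/SDNN
#' mean/sd/range, green-minus-urban deltas with significance codes, per-arm
#' cortisol percent changes, and the published group label) as typed data,
#' for regression-testing the stratification and aggregation stages against
#' printed values.
#'
#' @return A `data.frame` with one row per subject.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "greenwalk")
  if (path == "") {  # package not installed: running from source tree
    path <- file.path("inst", "extdata", "table1.csv")
  }
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = list(sig_rmssd = "character",
                                   sig_sdnn = "character"))
  df$sig_rmssd[is.na(df$sig_rmssd)] <- ""
  df$sig_sdnn[is.na(df$sig_sdnn)] <- ""
  df
}

#' Published table reshaped as subject contrasts
#'
#' Maps the fixture of [load_table1_fixture()] onto the
#' [subject_contrast()] column schema so the aggregation operations can be
#' applied to the printed values directly.
#'
#' @return A `data.frame` of subject contrasts with the published `group`
#'   column retained as `group_published`.
#' @export
table1_contrasts <- function() {
  t1 <- load_table1_fixture()
  data.frame(
    subject_id = t1$id,
    mean_rmssd_green = t1$rmssd_green_mean, mean_rmssd_urban = t1$rmssd_urban_mean,
    mean_sdnn_green = t1$sdnn_green_mean, mean_sdnn_urban = t1$sdnn_urban_mean,
    delta_rmssd = t1$delta_rmssd, delta_sdnn = t1$delta_sdnn,
    sig_rmssd = t1$sig_rmssd, sig_sdnn = t1$sig_sdnn,
    group = assign_group(t1$delta_rmssd, t1$delta_sdnn),
    group_published = t1$group,
    cortisol_pct_green = t1$cortisol_pct_green,
    cortisol_pct_urban = t1$cortisol_pct_urban,
    stringsAsFactors = FALSE
  )
}

#' Round half away from zero
#'
#' Report-table rounding convention: ties round away from zero (2.5 -> 3,
#' -2.5 -> -3), unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write report tables to CSV and JSON
#'
#' Emits the per-subject table, group-summary table and partial-correlation
#' grid as CSV rounded to printed precision (integers for percent summaries,
#' one decimal for means, half away from zero) alongside a `report.json`
#' carrying all values unrounded.
#'
#' @param report a `gw_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gw_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t1 <- report$contrasts
  num <- vapply(t1, is.numeric, logical(1))
  t1[num] <- lapply(t1[num], round_half_away, digits = 1)
  write.csv(t1, file.path(dir, "table1.csv"), row.names = FALSE)
  t2 <- report$group_summaries
  pct_cols <- grep("^pct_|^mean_subject_pct_", names(t2))
  t2[pct_cols] <- lapply(t2[pct_cols], round_half_away, digits = 0)
  other <- setdiff(which(vapply(t2, is.numeric, logical(1))), pct_cols)
  t2[other] <- lapply(t2[other], round_half_away, digits = 1)
  write.csv(t2, file.path(dir, "table2.csv"), row.names = FALSE)
  t3 <- report$partial_correlations
  t3$r <- round_half_away(t3$r, 2)
  write.csv(t3, file.path(dir, "table3.csv"), row.names = FALSE)
  unrounded <- list(
    contrasts = report$contrasts,
    group_summaries = report$group_summaries,
    strata = report$strata$table,
    cortisol_overall = report$cortisol_overall,
    order_effect = unclass(report$order_effect),
    partial_correlations = report$partial_correlations,
    qc = report$qc,
    exclusions = report$exclusions
  )
  jsonlite::write_json(unrounded, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}
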