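#' Paired t-test on position-matched walk trajectories
#'
#' Two-sided paired t-test on the position-matched spline trajectory points
#' of the two walks. The fixed-length resampled trajectories are the only
#' construct guaranteeing an equal-length pairing of walks of unequal
#' duration, which is why the test is run on them rather than on the raw
#' windows.
#'
#' @param green_points,urban_points numeric vectors of equal length (>= 2),
#'   normally the `value_ms` columns of two [resample_trajectory()] outputs.
#' @return A list with `t`, `df`, `p` and the significance `code`.
#' @export
paired_walk_test <- function(green_points, urban_points) {
  if (length(green_points) != length(urban_points)) {
    stop("paired test needs equal-length point vectors", call. = FALSE)
  }
  if (length(green_points) < 2L) {
    stop("paired test needs at least 2 point pairs", call. = FALSE)
  }
  d <- green_points - urban_points
  if (sd(d) == 0) {
    stop("degenerate paired test: all pairwise differences identical",
         call. = FALSE)
  }
  ht <- t.test(green_points, urban_points, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, code = significance_code(ht$p.value))
}

#' Significance code for a p-value
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.1, `""` otherwise; a boundary value
#' belongs to the weaker code (p = 0.01 gives `"*"`).
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param thresholds strong and weak thresholds, default `c(0.01, 0.1)`.
#' @return Character vector of codes.
#' @export
significance_code <- function(p, thresholds = c(0.01, 0.1)) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < thresholds[1], "**", ifelse(p < thresholds[2], "*", ""))
}

#' Cortisol percent change across a walk
#'
#' `(post - pre) * 100 / pre`; negative values are decreases.
#'
#' @param pre,post salivary cortisol concentrations in ng/mL, `pre > 0`.
#'   Vectorised.
#' @return Percent change.
#' @export
cortisol_pct_change <- function(pre, post) {
  if (anyNA(pre) || any(pre <= 0)) {
    stop("pre-walk cortisol must be > 0", call. = FALSE)
  }
  (post - pre) * 100 / pre
}

#' Per-group summary of HRV deltas and cortisol changes
#'
#' Aggregates one response group of subject contrasts into the row of the
#' published-style group table. For each HRV metric it reports the mean and
#' sample sd of the per-subject (green - urban) deltas and two percent-change
#' conventions:
#' \describe{
#'   \item{`pct_delta_*`}{the ratio-of-means formula
#'     `(mu_green - mu_urban) * 100 / mu_urban` applied to the group-level
#'     arm means;}
#'   \item{`mean_subject_pct_*`}{the mean of per-subject percent changes
#'     `delta / urban * 100`, which is the convention that reproduces the
#'     published group percentages.}
#' }
#' For cortisol, the mean/sd of per-subject differences in percent change is
#' reported, and `pct_delta_cortisol` applies the ratio-of-means formula to
#' the mean per-arm *magnitudes of decrease* (the published sign convention:
#' the mean difference is negative while the relative-change column is
#' positive).
#'
#' `hrv_subset = "significant"` restricts the HRV aggregates (only) to
#' subjects whose paired test reached a significance code on at least one
#' metric, falling back to the whole group when none did; this mirrors how
#' the published group-1 HRV row was evidently computed. Cortisol aggregates
#' always use the whole group.
#'
#' @param contrasts `data.frame` of subject contrasts (see
#'   [subject_contrast()]) belonging to one group.
#' @param hrv_subset `"all"` (default) or `"significant"`.
#' @return A one-row `data.frame` of class `group_summary`.
#' @export
group_aggregate <- function(contrasts, hrv_subset = c("all", "significant")) {
  stopifnot(is.data.frame(contrasts), nrow(contrasts) >= 1L)
  hrv_subset <- match.arg(hrv_subset)
  grp <- unique(contrasts$group)
  if (length(grp) != 1L) {
    stop("group_aggregate expects contrasts from a single group", call. = FALSE)
  }
  h <- contrasts
  if (hrv_subset == "significant" &&
      all(c("sig_rmssd", "sig_sdnn") %in% names(contrasts))) {
    sig <- nzchar(contrasts$sig_rmssd) | nzchar(contrasts$sig_sdnn)
    if (any(sig)) h <- contrasts[sig, , drop = FALSE]
  }
  sd_or_na <- function(x) if (length(x) >= 2L) sd(x) else NA_real_
  ratio_pct <- function(mg, mu) (mg - mu) * 100 / mu
  d_cort <- contrasts$cortisol_pct_green - contrasts$cortisol_pct_urban
  out <- data.frame(
    group = grp,
    n = nrow(contrasts),
    n_hrv = nrow(h),
    mu_delta_rmssd = mean(h$delta_rmssd),
    sigma_delta_rmssd = sd_or_na(h$delta_rmssd),
    pct_delta_rmssd = ratio_pct(mean(h$mean_rmssd_green),
                                mean(h$mean_rmssd_urban)),
    mean_subject_pct_rmssd = mean(h$delta_rmssd / h$mean_rmssd_urban * 100),
    mu_delta_sdnn = mean(h$delta_sdnn),
    sigma_delta_sdnn = sd_or_na(h$delta_sdnn),
    pct_delta_sdnn = ratio_pct(mean(h$mean_sdnn_green),
                               mean(h$mean_sdnn_urban)),
    mean_subject_pct_sdnn = mean(h$delta_sdnn / h$mean_sdnn_urban * 100),
    mu_delta_cortisol = mean(d_cort),
    sigma_delta_cortisol = sd_or_na(d_cort),
    pct_delta_cortisol = ratio_pct(mean(-contrasts$cortisol_pct_green),
                                   mean(-contrasts$cortisol_pct_urban))
  )
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Cohort-level mean cortisol percent change per arm
#'
#' Per-arm mean of the per-subject cortisol percent changes over all
#' subjects with both sessions.
#'
#' @param contrasts `data.frame` with `cortisol_pct_green` and
#'   `cortisol_pct_urban`.
#' @return A list with `green` and `urban` mean percent changes and `n`.
#' @export
overall_cortisol_means <- function(contrasts) {
  ok <- !is.na(contrasts$cortisol_pct_green) &
    !is.na(contrasts$cortisol_pct_urban)
  if (!any(ok)) stop("no subject has cortisol for both arms", call. = FALSE)
  list(green = mean(contrasts$cortisol_pct_green[ok]),
       urban = mean(contrasts$cortisol_pct_urban[ok]),
       n = sum(ok))
}

#' Cortisol order effect: second-day walks split by condition
#'
#' In a crossover design the response to the second walk may be modulated by
#' the first (anticipation/attenuation). This summarises the cortisol
#' percent change of each subject's *second* walk, stratified by which
#' condition came second. An empty stratum (all subjects walked the same
#' order) is reported as `NA` with its size 0.
#'
#' @param contrasts `data.frame` with `cortisol_pct_green`,
#'   `cortisol_pct_urban` and `green_order` (`"first"`/`"second"` position of
#'   the green walk).
#' @return A list of class `order_effect` with
#'   `mean_pct_change_green_when_second`, `mean_pct_change_urban_when_second`
#'   and the stratum sizes `n_green_second`, `n_urban_second`.
#' @export
order_effect <- function(contrasts) {
  if (!"green_order" %in% names(contrasts) || anyNA(contrasts$green_order)) {
    stop("order_effect needs a complete green_order column", call. = FALSE)
  }
  if (!all(contrasts$green_order %in% c("first", "second"))) {
    stop("green_order must be 'first' or 'second'", call. = FALSE)
  }
  green_second <- contrasts$green_order == "second"
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  structure(
    list(mean_pct_change_green_when_second =
           mean_or_na(contrasts$cortisol_pct_green[green_second]),
         mean_pct_change_urban_when_second =
           mean_or_na(contrasts$cortisol_pct_urban[!green_second]),
         n_green_second = sum(green_second),
         n_urban_second = sum(!green_second)),
    class = "order_effect"
  )
}

#' @export
print.order_effect <- function(x, ...) {
  cat(sprintf(
    "<order_effect> second-walk cortisol change: green %.1f%% (n=%d), urban %.1f%% (n=%d)\n",
    x$mean_pct_change_green_when_second, x$n_green_second,
    x$mean_pct_change_urban_when_second, x$n_urban_second))
  invisible(x)
}

#' Partial correlation by residualisation
#'
#' Pearson correlation between `y` and `x` after removing the linear effect
#' of the covariates (plus an intercept) from both by least squares. This is
#' mathematically equivalent to the recursive partial-correlation formula on
#' the joint correlation matrix, and is the adjustment used to relate
#' post-walk mood-scale scores to HRV while controlling for pre-walk scores
#' and baseline HRV.
#'
#' @param y,x numeric vectors.
#' @param covariates numeric vector, matrix or `data.frame` of covariates
#'   (one column each).
#' @return A list of class `partial_corr` with `r`, `n`, `k` (number of
#'   covariates).
#' @export
partial_correlation <- function(y, x, covariates) {
  z <- as.matrix(covariates)
  n <- length(y)
  if (length(x) != n || nrow(z) != n) {
    stop("y, x and covariates must have matching lengths", call. = FALSE)
  }
  if (anyNA(y) || anyNA(x) || anyNA(z)) {
    stop("partial_correlation does not accept missing values", call. = FALSE)
  }
  k <- ncol(z)
  if (n < k + 3L) {
    stop(sprintf("need n >= k + 3 observations (n = %d, k = %d)", n, k),
         call. = FALSE)
  }
  if (qr(cbind(1, z))$rank < k + 1L) {
    stop("covariates are collinear", call. = FALSE)
  }
  ry <- resid(lm(y ~ z))
  rx <- resid(lm(x ~ z))
  # residuals of a variable spanned by the covariates are zero up to
  # round-off; compare to the variable's own scale
  if (sd(ry) <= 1e-10 * max(sd(y), .Machine$double.eps) ||
      sd(rx) <= 1e-10 * max(sd(x), .Machine$double.eps)) {
    stop("undefined partial correlation: zero residual variance", call. = FALSE)
  }
  structure(list(r = cor(ry, rx), n = n, k = k), class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("<partial_corr> r = %.3f (n = %d, %d covariate%s)\n",
              x$r, x$n, x$k, if (x$k == 1L) "" else "s"))
  invisible(x)
}

#' Grid of mood-scale vs HRV partial correlations
#'
#' For every combination of scale (vigor, total mood disturbance,
#' mindfulness), HRV metric (RMSSD, SDNN), HRV phase (during-walk mean or
#' post-walk rest) and condition, correlates the post-walk scale score with
#' the HRV measure, adjusting for the pre-walk scale score and the pre-walk
#' (baseline) value of the same HRV metric on the same day.
#'
#' @param sessions `data.frame` with one row per subject-session and columns
#'   `subject_id`, `condition`, `vigor_pre`, `vigor_post`, `tmd_pre`,
#'   `tmd_post`, `mindfulness_pre`, `mindfulness_post`, `baseline_rmssd`,
#'   `baseline_sdnn`, `during_rmssd`, `during_sdnn`, `post_rmssd`,
#'   `post_sdnn`.
#' @return A `data.frame` with columns `scale`, `metric`, `phase`,
#'   `condition`, `r`, `n`.
#' @export
mood_hrv_partial_correlations <- function(sessions) {
  scales <- c(vigor = "vigor", total_mood_disturbance = "tmd",
              mindfulness = "mindfulness")
  grid <- expand.grid(scale = names(scales), metric = c("rmssd", "sdnn"),
                      phase = c("during", "post"),
                      condition = c("green", "urban"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    ses <- sessions[sessions$condition == g$condition, , drop = FALSE]
    stub <- scales[[g$scale]]
    y <- ses[[paste0(stub, "_post")]]
    x <- ses[[paste0(g$phase, "_", g$metric)]]
    covs <- cbind(ses[[paste0(stub, "_pre")]],
                  ses[[paste0("baseline_", g$metric)]])
    ok <- stats::complete.cases(y, x, covs)
    r <- tryCatch(partial_correlation(y[ok], x[ok], covs[ok, , drop = FALSE])$r,
                  error = function(e) NA_real_)
    data.frame(scale = g$scale, metric = g$metric, phase = g$phase,
               condition = g$condition, r = r, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
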