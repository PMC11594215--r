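#' Configuration for the synthetic crossover cohort
#'
#' Defines the study conditions the generator emulates: a two-session
#' (green/urban) crossover in which every session is a ~5 min seated
#' pre-rest, a 20 min (urban) or 20-22 min (green) walk, and a ~5 min
#' post-rest, recorded as NN intervals; pre/post salivary cortisol; mood
#' scales; and a randomised walk order.
#'
#' Defaults encode the cohort the analysis targets: baseline RMSSD 40 ms and
#' SDNN 65 ms around an 850 ms mean interval; green-walk HRV targets scaled
#' per response group (group 1 up on both metrics, group 2 down on both,
#' group 3 slightly mixed); mean cortisol drops of 53\% (green) and 37\%
#' (urban) with a crossover order interaction applied as a centred
#' `+/- order_interaction/2` shift on the second-day walk (centring keeps
#' the marginal arm means at the configured drops under a balanced order);
#' and post-walk vigor / mood-disturbance scores linearly coupled to the
#' during-walk RMSSD.
#'
#' @param n_subjects number of subjects.
#' @param group_proportions length-3 fractions summing to 1; subjects are
#'   allocated deterministically to the nearest integer split, then shuffled.
#' @param seed integer seed making the whole cohort reproducible.
#' @param rr_mean_ms mean NN interval (ms).
#' @param baseline_rmssd_ms,baseline_sdnn_ms rest-phase and urban-walk HRV
#'   targets (ms).
#' @param green_rmssd_multiplier,green_sdnn_multiplier named-by-group (1-3)
#'   multipliers applied to the green walk's HRV targets.
#' @param cortisol_meanlog,cortisol_sdlog log-normal parameters of pre-walk
#'   cortisol (ng/mL).
#' @param cortisol_drop_green,cortisol_drop_urban mean fractional cortisol
#'   drops per arm, in (0, 1).
#' @param cortisol_drop_sd between-session sd of the fractional drop.
#' @param order_interaction signed fraction: the second-day walk's drop is
#'   shifted by `+order_interaction/2` when green is second and
#'   `-order_interaction/2` when urban is second.
#' @param mood_effect coupling (vigor points per 10 ms of during-walk RMSSD
#'   above baseline) of HRV to post-walk mood; mood disturbance couples with
#'   the opposite sign.
#' @param artifact_rate per-beat probability of an injected artifact spike.
#' @param pre_rest_s,post_rest_s,urban_walk_s rest and urban-walk durations
#'   (s); the green walk is drawn uniformly from `green_walk_range_s`.
#' @param green_walk_range_s length-2 range (s) of green-walk durations.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 17L,
                          group_proportions = c(9, 6, 2) / 17,
                          seed = 1L,
                          rr_mean_ms = 850,
                          baseline_rmssd_ms = 40,
                          baseline_sdnn_ms = 65,
                          green_rmssd_multiplier = c(`1` = 2.0, `2` = 0.6,
                                                     `3` = 1.05),
                          green_sdnn_multiplier = c(`1` = 1.5, `2` = 0.7,
                                                    `3` = 0.95),
                          cortisol_meanlog = log(6),
                          cortisol_sdlog = 0.35,
                          cortisol_drop_green = 0.53,
                          cortisol_drop_urban = 0.37,
                          cortisol_drop_sd = 0.12,
                          order_interaction = 0.25,
                          mood_effect = 1.0,
                          artifact_rate = 0.02,
                          pre_rest_s = 300,
                          post_rest_s = 300,
                          urban_walk_s = 1200,
                          green_walk_range_s = c(1200, 1320)) {
  if (abs(sum(group_proportions) - 1) > 1e-8 || length(group_proportions) != 3L) {
    stop("group_proportions must be 3 fractions summing to 1", call. = FALSE)
  }
  if (any(green_rmssd_multiplier <= 0) || any(green_sdnn_multiplier <= 0)) {
    stop("group multipliers must be > 0", call. = FALSE)
  }
  for (d in c(cortisol_drop_green, cortisol_drop_urban)) {
    if (d <= 0 || d >= 1) stop("cortisol drops must lie in (0, 1)", call. = FALSE)
  }
  if (artifact_rate < 0 || artifact_rate >= 1) {
    stop("artifact_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate an NN-interval series with target SDNN and RMSSD
#'
#' Signal model: NN intervals are a constant mean plus a slow sinusoid
#' (default period 100 s, carrying long-range variability), a fast sinusoid
#' (default period 4 s, a respiratory-sinus-arrhythmia analogue carrying
#' beat-to-beat variability) and white noise. Beat phases are evaluated on
#' the nominal beat grid (multiples of the mean interval), which makes the
#' stationary expectations closed-form:
#' \deqn{SDNN^2 = a^2/2 + b^2/2 + c^2}
#' \deqn{RMSSD^2 = 2 a^2 \sin^2(\pi \Delta / P_s) + 2 b^2 \sin^2(\pi \Delta / P_f) + 2 c^2}
#' with `a`, `b` the sinusoid amplitudes, `c` the noise sd and `Delta` the
#' mean beat interval in seconds. Given the two targets the amplitudes are
#' solved from these identities (the white-noise sd is fixed at a small
#' device-noise floor), and an error naming the violated bound is raised
#' when no non-negative solution exists.
#'
#' @param mean_ms mean NN interval (ms).
#' @param target_sdnn_ms,target_rmssd_ms targets (ms); `(0, 0)` yields a
#'   constant series.
#' @param duration_s series duration (s), >= 60.
#' @param seed optional integer seed.
#' @param slow_period_s,fast_period_s sinusoid periods (s).
#' @param noise_sd_ms white-noise floor (ms); reduced automatically for very
#'   small RMSSD targets.
#' @param subject_id,condition,phases passed to [ibi_series()].
#' @return An [ibi_series()] whose beats span `[0, duration_s]`.
#' @export
simulate_nn_series <- function(mean_ms, target_sdnn_ms, target_rmssd_ms,
                               duration_s, seed = NULL,
                               slow_period_s = 100, fast_period_s = 4,
                               noise_sd_ms = 3,
                               subject_id = NA_character_,
                               condition = NA_character_, phases = NULL) {
  if (duration_s < 60) stop("duration_s must be >= 60 s", call. = FALSE)
  if (target_sdnn_ms < 0 || target_rmssd_ms < 0) {
    stop("HRV targets must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  amp <- solve_nn_amplitudes(mean_ms, target_sdnn_ms, target_rmssd_ms,
                             slow_period_s, fast_period_s, noise_sd_ms)
  delta_s <- mean_ms / 1000
  n <- ceiling(duration_s / delta_s) + 5L
  k <- seq_len(n)
  t_k <- k * delta_s
  phi <- runif(2, 0, 2 * pi)
  nn <- mean_ms +
    amp$a * sin(2 * pi * t_k / slow_period_s + phi[1]) +
    amp$b * sin(2 * pi * t_k / fast_period_s + phi[2]) +
    rnorm(n, 0, amp$c)
  nn <- pmax(nn, 250)  # physiological floor; unreachable under sane targets
  cum <- cumsum(nn) / 1000
  keep <- cum <= duration_s
  if (!any(keep)) stop("duration too short for the mean interval", call. = FALSE)
  ibi_series(nn[keep], subject_id = subject_id, condition = condition,
             phases = phases, walk_duration_bounds = NULL)
}

# Solve sinusoid amplitudes (a slow, b fast) and noise sd c so that the
# closed-form stationary SDNN/RMSSD match the targets.
solve_nn_amplitudes <- function(mean_ms, S, R, slow_period_s, fast_period_s,
                                noise_sd_ms) {
  if (S == 0 && R == 0) return(list(a = 0, b = 0, c = 0))
  delta_s <- mean_ms / 1000
  k_slow <- 2 * sin(pi * delta_s / slow_period_s)^2
  k_fast <- 2 * sin(pi * delta_s / fast_period_s)^2
  cc <- min(noise_sd_ms, R / 4, S / 4)
  b2 <- (R^2 - 2 * cc^2 - k_slow * 2 * (S^2 - cc^2)) / (k_fast - k_slow)
  a2 <- 2 * (S^2 - cc^2) - b2
  if (b2 < 0) {
    stop(sprintf(
      "infeasible HRV target pair: RMSSD %.3g ms too small for SDNN %.3g ms (needs RMSSD^2 >= %.3g ms^2 from the slow component alone)",
      R, S, 2 * cc^2 + k_slow * 2 * (S^2 - cc^2)), call. = FALSE)
  }
  if (a2 < 0) {
    stop(sprintf(
      "infeasible HRV target pair: RMSSD %.3g ms too large for SDNN %.3g ms (bound RMSSD <= %.3g ms at this mean interval)",
      R, S, sqrt(k_fast * 2 * (S^2 - cc^2) + 2 * cc^2)), call. = FALSE)
  }
  list(a = sqrt(a2), b = sqrt(b2), c = cc)
}

#' Simulate one subject's two crossover sessions
#'
#' Generates the green and urban sessions of one subject under a
#' [cohort_config()]: per-session NN recordings (pre-rest at baseline
#' targets, walk at arm targets, post-rest at baseline), artifact spikes,
#' pre/post cortisol with arm- and order-dependent drops, and mood scores
#' coupled to the during-walk RMSSD target. The urban walk runs at the
#' baseline HRV targets; the green walk's targets are the baseline scaled by
#' the subject's group multipliers.
#'
#' @param config a [cohort_config()].
#' @param subject_id subject label.
#' @param group response group 1, 2 or 3.
#' @param green_order `"first"` or `"second"`: position of the green walk.
#' @param seed optional integer seed.
#' @return A list of class `gw_subject`: `subject_id`, `group` (true label),
#'   `green_order`, `sessions` (named list of [ibi_series()]), `side`
#'   (two-row side-data `data.frame`) and `truth` (generating targets).
#' @export
simulate_subject <- function(config, subject_id, group, green_order,
                             seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), group %in% 1:3,
            green_order %in% c("first", "second"))
  if (!is.null(seed)) set.seed(seed)
  g <- as.character(group)
  targets <- list(
    urban = c(rmssd = config$baseline_rmssd_ms, sdnn = config$baseline_sdnn_ms),
    green = c(rmssd = config$baseline_rmssd_ms * config$green_rmssd_multiplier[[g]],
              sdnn = config$baseline_sdnn_ms * config$green_sdnn_multiplier[[g]])
  )
  walk_s <- list(urban = config$urban_walk_s,
                 green = runif(1, config$green_walk_range_s[1],
                               config$green_walk_range_s[2]))
  sessions <- list()
  side_rows <- list()
  for (cond in c("green", "urban")) {
    ws <- walk_s[[cond]]
    phases <- data.frame(
      phase = c("pre_rest", "walk", "post_rest"),
      start_s = c(0, config$pre_rest_s, config$pre_rest_s + ws),
      end_s = c(config$pre_rest_s, config$pre_rest_s + ws,
                config$pre_rest_s + ws + config$post_rest_s),
      stringsAsFactors = FALSE
    )
    seg <- function(dur, tgt) {
      simulate_nn_series(config$rr_mean_ms, tgt[["sdnn"]], tgt[["rmssd"]],
                         dur)$intervals
    }
    nn <- c(seg(config$pre_rest_s, targets$urban),
            seg(ws, targets[[cond]]),
            seg(config$post_rest_s, targets$urban))
    nn <- inject_artifacts(nn, config$artifact_rate)
    sessions[[cond]] <- ibi_series(nn, subject_id = subject_id,
                                   condition = cond, phases = phases,
                                   walk_duration_bounds = NULL)

    is_second <- (cond == "green") == (green_order == "second")
    drop0 <- if (cond == "green") config$cortisol_drop_green else
      config$cortisol_drop_urban
    oi <- config$order_interaction / 2 * (if (is_second) 1 else -1) *
      (if (cond == "green") 1 else -1)
    drop <- drop0 + oi + rnorm(1, 0, config$cortisol_drop_sd)
    drop <- min(max(drop, -0.5), 0.95)
    cort_pre <- rlnorm(1, config$cortisol_meanlog, config$cortisol_sdlog)
    cort_post <- cort_pre * (1 - drop)

    hrv_z <- (targets[[cond]][["rmssd"]] - config$baseline_rmssd_ms) / 10
    vigor_pre <- rnorm(1, 17, 4)
    tmd_pre <- rnorm(1, 12, 8)
    maas_pre <- rnorm(1, 4.3, 0.7)
    side_rows[[cond]] <- data.frame(
      subject_id = subject_id, condition = cond,
      walk_order = if (is_second) "second" else "first",
      cortisol_pre = cort_pre, cortisol_post = cort_post,
      cortisol_pct_change = NA_real_,
      vigor_pre = vigor_pre,
      vigor_post = 7 + 0.6 * vigor_pre + config$mood_effect * hrv_z +
        rnorm(1, 0, 1.5),
      tmd_pre = tmd_pre,
      tmd_post = 2 + 0.7 * tmd_pre - 1.5 * config$mood_effect * hrv_z +
        rnorm(1, 0, 3),
      mindfulness_pre = maas_pre,
      mindfulness_post = 0.5 + 0.85 * maas_pre + rnorm(1, 0, 0.4),
      stringsAsFactors = FALSE
    )
  }
  side <- validate_side_data(do.call(rbind, side_rows))
  structure(
    list(subject_id = subject_id, group = group, green_order = green_order,
         sessions = sessions, side = side,
         truth = list(group = group, targets = targets,
                      walk_s = walk_s, green_order = green_order)),
    class = "gw_subject"
  )
}

# Artifact model mimicking beat-detection failures while preserving the
# recording's total time: a false detection splits one interval into two
# uneven halves, a missed beat merges two adjacent intervals into one long
# interval. Both kinds violate the successive-relative-difference filter and
# so are removable downstream.
inject_artifacts <- function(nn, rate) {
  if (rate <= 0 || length(nn) < 3L) return(nn)
  hit <- which(runif(length(nn)) < rate)
  hit <- hit[hit < length(nn)]
  if (!length(hit)) return(nn)
  split_kind <- runif(length(hit)) < 0.5
  out <- vector("list", length(nn))
  skip <- FALSE
  for (i in seq_along(nn)) {
    if (skip) { skip <- FALSE; next }
    j <- match(i, hit)
    if (!is.na(j) && split_kind[j]) {
      u <- runif(1, 0.3, 0.45)
      out[[i]] <- c(u, 1 - u) * nn[i]
    } else if (!is.na(j) && i < length(nn)) {
      out[[i]] <- nn[i] + nn[i + 1]
      skip <- TRUE
    } else {
      out[[i]] <- nn[i]
    }
  }
  unlist(out)
}

#' Simulate a complete synthetic cohort
#'
#' Allocates subjects to response groups (deterministic nearest-integer
#' split of the configured proportions, order shuffled), randomises the walk
#' order 50/50 per subject, and simulates every subject with
#' [simulate_subject()]. Optionally writes the dataset in the same
#' plain-text formats [read_ibi()] and [read_side_data()] consume.
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory; when given, writes one
#'   `<subject>_<condition>.csv` recording per session (with a per-beat
#'   phase column), a combined `sidedata.csv`, and `truth.json`.
#' @return A list of class `gw_cohort`: `subjects` (list of `gw_subject`),
#'   `config`, and `truth` (`data.frame` of true group and order per
#'   subject).
#' @export
simulate_cohort <- function(config = cohort_config(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  counts <- diff(c(0, round(cumsum(config$group_proportions) * n)))
  groups <- sample(rep(1:3, times = counts))
  orders <- ifelse(rbinom(n, 1, 0.5) == 1, "second", "first")
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- simulate_subject(
      config, subject_id = sprintf("S%02d", i),
      group = groups[i], green_order = orders[i]
    )
  }
  truth <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    group = if (n) groups else integer(0),
    green_order = if (n) orders else character(0),
    stringsAsFactors = FALSE
  )
  cohort <- structure(list(subjects = subjects, config = config,
                           truth = truth), class = "gw_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a synthetic cohort to plain-text files
#'
#' @param cohort a `gw_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gw_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  side_all <- list()
  for (subj in cohort$subjects) {
    for (cond in names(subj$sessions)) {
      stem <- sprintf("%s_%s", subj$subject_id, cond)
      write_ibi(subj$sessions[[cond]], file.path(dir, paste0(stem, ".csv")),
                phase_file = file.path(dir, paste0(stem, "_phases.csv")))
    }
    side_all[[subj$subject_id]] <- subj$side
  }
  if (length(side_all)) {
    write.csv(do.call(rbind, side_all), file.path(dir, "sidedata.csv"),
              row.names = FALSE, quote = FALSE)
  } else {
    write.csv(data.frame(subject_id = character(0), condition = character(0),
                         walk_order = character(0)),
              file.path(dir, "sidedata.csv"), row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `<subject>_<condition>.csv`
#'   recordings and `sidedata.csv`.
#' @return A list of class `gw_cohort` (without truth unless `truth.json`
#'   is present).
#' @export
read_cohort <- function(dir) {
  side <- read_side_data(file.path(dir, "sidedata.csv"))
  subjects <- list()
  for (sid in unique(side$subject_id)) {
    sessions <- list()
    for (cond in side$condition[side$subject_id == sid]) {
      path <- file.path(dir, sprintf("%s_%s.csv", sid, cond))
      pf <- file.path(dir, sprintf("%s_%s_phases.csv", sid, cond))
      sessions[[cond]] <- read_ibi(path,
                                   phase_file = if (file.exists(pf)) pf,
                                   subject_id = sid, condition = cond,
                                   walk_duration_bounds = NULL)
    }
    row <- side[side$subject_id == sid & side$condition == "green", ]
    subjects[[sid]] <- structure(
      list(subject_id = sid, group = NA_integer_,
           green_order = if (nrow(row)) row$walk_order else NA_character_,
           sessions = sessions,
           side = side[side$subject_id == sid, , drop = FALSE],
           truth = NULL),
      class = "gw_subject"
    )
  }
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    truth <- as.data.frame(jsonlite::read_json(tj, simplifyVector = TRUE))
  }
  structure(list(subjects = subjects, config = NULL, truth = truth),
            class = "gw_cohort")
}
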