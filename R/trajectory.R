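#' Fit a smoothing spline to windowed HRV values
#'
#' Fits a cubic smoothing spline to one metric of a windowed HRV table, with
#' window *midpoints* (normalised to the walk span, so time runs over
#' `[0, 1]`) as abscissae. Windows whose metrics are missing are simply
#' absent from the fit; the spline itself provides the interpolation across
#' them.
#'
#' The smoothing factor `s` is a normalised penalty weight on `[0, 1)`:
#' internally it is mapped to the classical penalised-least-squares parameter
#' via `lambda = s / (1 - s)` on the normalised time axis, so `s = 0` gives
#' the natural interpolating cubic spline, increasing `s` trades fidelity for
#' smoothness monotonically, and `s -> 1` collapses the fit onto the
#' least-squares straight line (values of `s >= 1` are treated as that
#' linear limit). This scale is a property of this implementation; smoothing
#' factors quoted for other spline libraries are not directly comparable.
#'
#' @param windows an `hrv_windows` table from [window_metrics()].
#' @param metric `"rmssd"` or `"sdnn"`.
#' @param s smoothing factor (default 0.4).
#'
#' @return An object of class `walk_spline`: list with `metric`, `s`,
#'   `lambda`, `x`/`y` (fitted abscissae and values), `fitted`, `mse`
#'   (mean squared residual at the window midpoints, ms^2) and `duration_s`.
#' @seealso [resample_trajectory()], [spline_mse()]
#' @export
fit_smoothing_spline <- function(windows, metric = c("rmssd", "sdnn"),
                                 s = 0.4) {
  stopifnot(inherits(windows, "hrv_windows"))
  metric <- match.arg(metric)
  if (s < 0) stop("smoothing factor s must be >= 0", call. = FALSE)
  duration <- attr(windows, "duration_s")
  col <- paste0(metric, "_ms")
  ok <- !is.na(windows[[col]])
  if (sum(ok) < 4L) {
    stop("need at least 4 usable windows to fit a cubic smoothing spline",
         call. = FALSE)
  }
  x <- (windows$start_s[ok] + windows$end_s[ok]) / 2 / duration
  y <- windows[[col]][ok]
  if (s == 0) {
    # exact natural interpolating spline: the lambda -> 0 limit
    fun <- splinefun(x, y, method = "natural")
    lambda <- 0
  } else {
    # cap lambda where the penalised system is still well conditioned; at
    # 1e4 the fit already matches the least-squares line to ~1e-5 ms
    lambda <- if (s >= 1) 1e4 else min(s / (1 - s), 1e4)
    fit <- smooth.spline(x, y, lambda = lambda, all.knots = TRUE,
                         keep.data = FALSE)
    fun <- function(t) predict(fit, t)$y
  }
  fitted_y <- fun(x)
  structure(
    list(metric = metric, s = s, lambda = lambda, x = x, y = y,
         fitted = fitted_y, mse = mean((y - fitted_y)^2),
         predict = fun, duration_s = duration),
    class = "walk_spline"
  )
}

#' Mean squared fit error of a walk spline
#'
#' Mean of squared residuals between the spline and the raw windowed HRV
#' values at the window midpoints, in ms^2.
#'
#' @param model a `walk_spline` from [fit_smoothing_spline()].
#' @return MSE in ms^2.
#' @export
spline_mse <- function(model) {
  stopifnot(inherits(model, "walk_spline"))
  model$mse
}

#' @export
predict.walk_spline <- function(object, time_frac, ...) {
  object$predict(time_frac)
}

#' Resample a walk spline to a fixed number of trajectory points
#'
#' Evaluates the fitted spline at `n` equally spaced time fractions spanning
#' the walk (0 to 1 inclusive). Because time is normalised, walks of unequal
#' duration (e.g. 20 vs 22 min) yield trajectories of identical length that
#' can be compared point-by-point across conditions. Negative evaluations
#' (possible for a smoothing spline near sparse data) are clamped to 0 ms and
#' flagged.
#'
#' @param model a `walk_spline` from [fit_smoothing_spline()].
#' @param n number of points (default 20).
#' @return A `data.frame` of class `walk_trajectory` with columns
#'   `point_index` (1-based), `time_frac`, `value_ms`, `clamped`, and
#'   attributes `metric`, `smoothing_factor`, `spline_mse`.
#' @export
resample_trajectory <- function(model, n = 20L) {
  stopifnot(inherits(model, "walk_spline"))
  if (n < 2L) stop("need at least 2 trajectory points", call. = FALSE)
  tf <- seq(0, 1, length.out = n)
  v <- model$predict(tf)
  clamped <- v < 0
  v[clamped] <- 0
  structure(
    data.frame(point_index = seq_len(n), time_frac = tf, value_ms = v,
               clamped = clamped),
    metric = model$metric, smoothing_factor = model$s,
    spline_mse = model$mse,
    class = c("walk_trajectory", "data.frame")
  )
}

#' Plot a walk spline over its raw windowed values
#'
#' Raw window midpoints as points, the fitted spline as a line, and the
#' resampled trajectory points as crosses.
#'
#' @param x a `walk_spline`.
#' @param n number of resampled points to overlay.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.walk_spline <- function(x, n = 20L, ...) {
  grid <- seq(0, 1, length.out = 200)
  plot(x$x, x$y, xlab = "walk time fraction",
       ylab = sprintf("%s (ms)", toupper(x$metric)),
       main = sprintf("smoothing spline (s = %g)", x$s), ...)
  graphics::lines(grid, x$predict(grid))
  traj <- resample_trajectory(x, n)
  graphics::points(traj$time_frac, traj$value_ms, pch = 4)
  invisible(x)
}
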