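#' Serial-dilution calibration concentrations
#'
#' Concentrations of an `n`-point serial dilution starting at `top` with the
#' given dilution factor: `top, top/factor, ..., top/factor^(n-1)`. The
#' default 9-point 2x series from 50 ng/mL spans the endogenous salivary
#' cortisol range down to ~0.195 ng/mL.
#'
#' @param top top standard concentration in ng/mL.
#' @param n number of standards.
#' @param factor dilution factor (> 1).
#' @return Numeric vector of concentrations, highest first.
#' @export
serial_dilution_series <- function(top = 50, n = 9L, factor = 2) {
  if (top <= 0 || n < 1L || factor <= 1) {
    stop("need top > 0, n >= 1 and factor > 1", call. = FALSE)
  }
  top / factor^(seq_len(n) - 1)
}

#' Fit a through-origin 1/x^2-weighted calibration curve
#'
#' Weighted least-squares line through the origin relating instrument
#' response (internal-standard-normalised peak area, or raw area -- the
#' mathematics is identical) to analyte concentration, with weights
#' `1/x^2` as is standard for bioanalytical calibration. With these weights
#' the through-origin slope reduces to the mean of the per-standard response
#' ratios `y/x`.
#'
#' Because the coefficient of determination of a through-origin fit is
#' convention-dependent, both a weighted and an unweighted R^2 are reported:
#' each is `1 - RSS/TSS` with the total sum of squares taken about the
#' (weighted or unweighted) mean response.
#'
#' @param concs standard concentrations in ng/mL, all > 0.
#' @param responses instrument responses, same length.
#' @return An object of class `calibration_curve`: list with `slope`,
#'   `intercept` (fixed 0), `r_squared` (weighted), `r_squared_unweighted`,
#'   `weighting` (`"1/x^2"`), `range_ng_ml`, `valid` (slope > 0), `n`.
#' @export
fit_calibration <- function(concs, responses) {
  x <- as.numeric(concs)
  y <- as.numeric(responses)
  if (length(x) != length(y)) {
    stop("concs and responses must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 standards", call. = FALSE)
  if (anyNA(x) || any(x <= 0)) {
    stop("all standard concentrations must be > 0 (1/x^2 weight undefined otherwise)",
         call. = FALSE)
  }
  w <- 1 / x^2
  fit <- lm(y ~ 0 + x, weights = w)
  slope <- unname(coef(fit)[1])
  rss_w <- sum(w * resid(fit)^2)
  ybar_w <- sum(w * y) / sum(w)
  tss_w <- sum(w * (y - ybar_w)^2)
  rss <- sum(resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(slope = slope, intercept = 0,
         r_squared = if (tss_w > 0) 1 - rss_w / tss_w else NA_real_,
         r_squared_unweighted = if (tss > 0) 1 - rss / tss else NA_real_,
         weighting = "1/x^2", range_ng_ml = range(x),
         valid = slope > 0, n = length(x)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> y = %.4g x (through origin, %s weights), R2 = %.4f, range %.3g-%.3g ng/mL%s\n",
    x$slope, x$weighting, x$r_squared, x$range_ng_ml[1], x$range_ng_ml[2],
    if (x$valid) "" else " [INVALID]"))
  invisible(x)
}

#' Quantify samples against a calibration curve
#'
#' Back-calculates sample concentrations as
#' `(response / slope) * dilution_factor`; the default dilution factor 5
#' corresponds to mixing 1 part saliva filtrate with 4 parts water. Samples
#' whose back-calculated (pre-dilution) concentration falls outside the
#' calibrated range are flagged via the `"in_range"` attribute and a
#' warning.
#'
#' @param response instrument response(s), >= 0.
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @param dilution_factor sample dilution factor (default 5).
#' @return Numeric vector of concentrations in ng/mL with attribute
#'   `in_range` (logical).
#' @export
quantify <- function(response, curve, dilution_factor = 5) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!curve$valid || curve$slope <= 0) {
    stop("calibration curve is invalid (slope <= 0)", call. = FALSE)
  }
  if (anyNA(response) || any(response < 0)) {
    stop("responses must be >= 0", call. = FALSE)
  }
  raw_conc <- response / curve$slope
  conc <- raw_conc * dilution_factor
  in_range <- raw_conc >= curve$range_ng_ml[1] & raw_conc <= curve$range_ng_ml[2]
  if (any(!in_range)) {
    warning(sum(!in_range), " sample(s) outside the calibrated range")
  }
  attr(conc, "in_range") <- in_range
  conc
}
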