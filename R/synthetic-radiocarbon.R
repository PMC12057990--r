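#' @include grid-utils.R
NULL

#' Build a synthetic calibration curve
#'
#' Utility for testing and simulation: a calendar-gridded curve with
#' radiocarbon age `mu = calBP + wiggleAmplitude * sin(2 pi calBP /
#' wigglePeriod)` and constant one-sigma `curveSd`. With
#' `wiggleAmplitude = 0` the curve is the identity, for which calibration
#' has a Gaussian closed form.
#'
#' @param calRange Numeric length-2, calendar span (cal BP).
#' @param step Grid step in years (default 1).
#' @param curveSd Curve SD in years (> 0; default 10).
#' @param wiggleAmplitude,wigglePeriod Sinusoidal wiggle (default none).
#' @param name Curve label.
#' @return A [CalibrationCurve-class].
#' @export
#' @examples
#' syntheticCalCurve(c(2500, 3500))
syntheticCalCurve <- function(calRange, step = 1, curveSd = 10,
                              wiggleAmplitude = 0, wigglePeriod = 200,
                              name = "synthetic") {
  calBP <- seq(min(calRange), max(calRange), by = step)
  mu <- calBP + wiggleAmplitude * sin(2 * pi * calBP / wigglePeriod)
  methods::new("CalibrationCurve", calBP = calBP, mu = mu,
    sigma = rep(curveSd, length(calBP)), name = name)
}

#' Draw a radiocarbon dataset from a known uniform phase
#'
#' Ground-truth generator for the single-phase chronological model:
#' calendar dates are drawn uniformly within `[trueEndCalBP,
#' trueStartCalBP]` (cal BP decreases toward the present, so start >
#' end), converted through the calibration curve, and perturbed with
#' noise of SD `sqrt(curveSd^2 + labError^2)`. The reported measurement
#' sigma is the lab error.
#'
#' @param trueStartCalBP,trueEndCalBP Phase boundaries (cal BP), start >
#'   end.
#' @param nDates Number of dates.
#' @param curve A [CalibrationCurve-class] covering the phase.
#' @param labErrors Per-date lab one-sigma (years); recycled.
#' @param seed Integer seed.
#' @return data.frame(id, bp_age, sigma, true_calBP); `true_calBP` is the
#'   generating truth, not an observable.
#' @export
#' @examples
#' curve <- syntheticCalCurve(c(2700, 3300))
#' makeRadiocarbonDataset(3000, 2950, 8, curve, labErrors = 25, seed = 1)
makeRadiocarbonDataset <- function(trueStartCalBP, trueEndCalBP, nDates,
                                   curve, labErrors = 25, seed = 1L) {
  stopifnot(methods::is(curve, "CalibrationCurve"))
  if (trueStartCalBP <= trueEndCalBP)
    stop("trueStartCalBP must exceed trueEndCalBP (cal BP runs backward)")
  if (trueStartCalBP > max(curve@calBP) || trueEndCalBP < min(curve@calBP))
    stop("calibration curve does not cover the phase interval")
  labErrors <- rep_len(labErrors, nDates)
  withSeed(seed, {
    theta <- stats::runif(nDates, trueEndCalBP, trueStartCalBP)
    mu <- stats::approx(curve@calBP, curve@mu, xout = theta)$y
    sc <- stats::approx(curve@calBP, curve@sigma, xout = theta)$y
    if (anyNA(mu))
      stop("calibration curve has a gap over the phase interval")
    bp <- mu + stats::rnorm(nDates, 0, sqrt(sc^2 + labErrors^2))
    data.frame(id = sprintf("sim%02d", seq_len(nDates)),
               bp_age = bp, sigma = labErrors, true_calBP = theta)
  })
}
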