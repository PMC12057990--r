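#' @include AllClasses.R grid-utils.R
NULL

#' Forward model: diet carbon isotopes from elevation
#'
#' The linear calibration `d13C_diet = a * elevation + b` of the
#' elevation model; inverse of the chain in [enamelToElevation()].
#'
#' @param elevation Metres.
#' @param model An [ElevationModel-class].
#' @return d13C_diet in permil.
#' @export
dietFromElevation <- function(elevation, model = ElevationModel()) {
  model@slope * elevation + model@intercept
}

#' Invert enamel carbon isotopes to grazing elevation
#'
#' Full chain: archaeological enamel values are first shifted by the
#' Suess correction (modern calibration vs pre-industrial atmosphere),
#' then converted to diet by the diet-enamel fractionation, and the
#' linear diet-elevation calibration is inverted,
#' `elevation = (d13C_diet - b) / a`. Uncertainty is propagated by Monte
#' Carlo over Gaussian draws of the slope and intercept (their quoted
#' standard errors are too large for first-order propagation). Estimates
#' below the plausibility floor are flagged, never clipped: intra-tooth
#' variation is an indicator of altitudinal movement, not a survey
#' instrument.
#'
#' @param d13Cenamel Enamel d13C (permil V-PDB); vectorized.
#' @param model An [ElevationModel-class].
#' @param isArchaeological Apply the Suess shift? (default TRUE).
#' @param nMc Monte Carlo draws (default 10000). @param seed Seed.
#' @param level CI level (default 0.95).
#' @return data.frame(d13C_enamel, d13C_diet, elevation, sd, lower,
#'   upper, implausible).
#' @export
#' @examples
#' # diet -24.14 permil sits at the calibration intercept: elevation 0 m
#' enamelToElevation(-24.14 + 13.7, isArchaeological = FALSE, nMc = 100)
enamelToElevation <- function(d13Cenamel, model = ElevationModel(),
                              isArchaeological = TRUE, nMc = 10000,
                              seed = 1L, level = 0.95) {
  stopifnot(is.finite(d13Cenamel))
  diet <- d13Cenamel +
    (if (isArchaeological) model@suessShift else 0) +
    model@dietEnamelOffset
  elev <- (diet - model@intercept) / model@slope
  withSeed(seed, {
    a <- stats::rnorm(nMc, model@slope, model@slopeSe)
    b <- stats::rnorm(nMc, model@intercept, model@interceptSe)
    ## guard against sign flips of the slope in the far tail
    a[a >= -1e-6] <- -1e-6
    draws <- vapply(diet, function(d) {
      e <- (d - b) / a
      c(stats::sd(e), stats::quantile(e, c((1 - level) / 2,
                                           1 - (1 - level) / 2)))
    }, numeric(3))
  })
  data.frame(d13C_enamel = d13Cenamel, d13C_diet = diet,
             elevation = elev, sd = draws[1, ],
             lower = draws[2, ], upper = draws[3, ],
             implausible = elev < model@plausibleFloor)
}
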