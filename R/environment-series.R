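#' @include schedule.R grid-utils.R
NULL

#' Simulate the environmental isotope series under a movement schedule
#'
#' Produces the daily environmental input an animal experiences while its
#' herd follows `schedule` across `isoscape`: the bioavailable 87Sr/86Sr
#' of the occupied camp's cell, a sinusoidal annual d18O signal (summer
#' peak at `phaseDay + period/4`), and the elevation-driven d13C already
#' expressed in the enamel reference frame (diet d13C from the linear
#' elevation calibration, plus the diet-to-enamel fractionation). The
#' chain is deterministic: analytical noise belongs to [recordTooth()].
#'
#' @param schedule A [MovementSchedule-class]; camps must fall inside the
#'   isoscape extent.
#' @param isoscape An [SrIsoscape-class].
#' @param d18OParams List with `mean` (permil), `amplitude` (permil) and
#'   `phaseDay` (day of the ascending zero crossing). Defaults
#'   `list(mean = -12.8, amplitude = 2.45, phaseDay = 80)` give the
#'   typical continental-steppe annual cycle: a mean near -12.8 permil
#'   and a peak-to-trough range of 4.9 permil.
#' @param elevationModel An [ElevationModel-class] providing the forward
#'   d13C chain (default [ElevationModel()]).
#' @param timeStep Days between samples (default 1).
#' @return An [EnvironmentSeries-class] sampled at spell-interior points.
#' @export
simulateEnvironment <- function(schedule, isoscape,
                                d18OParams = list(mean = -12.8,
                                                  amplitude = 2.45,
                                                  phaseDay = 80),
                                elevationModel = ElevationModel(),
                                timeStep = 1) {
  stopifnot(methods::is(schedule, "MovementSchedule"),
            methods::is(isoscape, "SrIsoscape"))
  camps <- schedule@camps
  look <- lookupIsoscape(isoscape, camps[, "x"], camps[, "y"])
  if (anyNA(look$mean)) {
    bad <- which(is.na(look$mean))
    stop("camp(s) outside the isoscape extent: ",
         paste(bad, collapse = ", "))
  }
  occ <- schedule@occupancy
  t0 <- min(occ$start); t1 <- max(occ$end)
  time <- seq(t0 + timeStep / 2, t1, by = timeStep)
  time <- time[time < t1]
  spell <- findInterval(time, occ$start)
  camp <- occ$camp[spell]

  sr <- unname(look$mean[camp])
  d18O <- d18OParams$mean + d18OParams$amplitude *
    sin(2 * pi * (time - d18OParams$phaseDay) / schedule@yearLength)
  elev <- unname(camps[camp, "elevation"])
  diet <- elevationModel@slope * elev + elevationModel@intercept
  d13C <- diet - elevationModel@dietEnamelOffset

  methods::new("EnvironmentSeries", time = time, srRatio = sr,
    d18O = d18O, d13C = d13C, elevation = as.numeric(elev))
}

#' Convert an EnvironmentSeries to a data.frame
#'
#' @param x An [EnvironmentSeries-class].
#' @param ... Unused.
#' @return data.frame(time_day, sr_ratio, d18O, d13C, elevation).
#' @export
setMethod("as.data.frame", "EnvironmentSeries", function(x, ...) {
  data.frame(time_day = x@time, sr_ratio = x@srRatio, d18O = x@d18O,
             d13C = x@d13C, elevation = x@elevation)
})
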