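#' @include environment-series.R
NULL

DAYS_PER_MONTH <- 365 / 12

## Exact mean of the piecewise-linear interpolant of (time, value) over
## [t0, t0 + width]. Returns a closure; the cumulative integral of a
## piecewise-linear function is piecewise quadratic and evaluated exactly.
intervalMeanFun <- function(time, value) {
  n <- length(time)
  stopifnot(n >= 2, length(value) == n)
  dt <- diff(time)
  slope <- diff(value) / dt
  cum <- c(0, cumsum((value[-n] + value[-1]) / 2 * dt))
  C <- function(t) {
    t <- pmin(pmax(t, time[1]), time[n])
    i <- pmin(pmax(findInterval(t, time), 1L), n - 1L)
    h <- t - time[i]
    cum[i] + h * value[i] + 0.5 * slope[i] * h^2
  }
  function(t0, width) {
    if (width <= 0) return(stats::approx(time, value, xout = t0)$y)
    (C(t0 + width) - C(t0)) / width
  }
}

## Shared recording kernel: maps crown distance to time linearly
## (apex = start age, ERJ = end age) and averages the environmental series
## over the maturation window [t(d), t(d) + width]. Both recordTooth() and
## predictProfile() go through this one implementation.
recordKernel <- function(time, value, timing, maturationWindowDays,
                         nSamples) {
  tStart <- timing@startAgeMonths * DAYS_PER_MONTH
  tEnd <- timing@endAgeMonths * DAYS_PER_MONTH
  need <- c(tStart, tEnd + maturationWindowDays)
  if (min(time) > need[1] + 1e-9 || max(time) < need[2] - 1e-9)
    stop(sprintf(paste0(
      "environmental series must cover days [%.1f, %.1f] ",
      "(tooth formation plus maturation window); got [%.1f, %.1f]"),
      need[1], need[2], min(time), max(time)))
  d <- seq(0, timing@crownLengthMm, length.out = nSamples)
  tAtD <- tEnd - d / timing@crownLengthMm * (tEnd - tStart)
  m <- intervalMeanFun(time, value)
  val <- vapply(tAtD, function(t0) m(t0, maturationWindowDays), numeric(1))
  list(distance = d, value = val, time = tAtD)
}

#' Record an environmental series into intra-tooth isotope profiles
#'
#' Forward model of enamel formation: crown distance maps linearly from
#' the apex (mineralization start) to the ERJ (mineralization end), and
#' the value laid down at each position is the average of the
#' environmental input over the maturation window starting at deposition
#' (a rectangular moving-average kernel). Gaussian analytical noise is
#' added per sample. Distances are reported in mm from the ERJ, so age
#' decreases as distance increases.
#'
#' @param env An [EnvironmentSeries-class] covering the formation window
#'   (start age to end age + maturation window).
#' @param timing A [ToothTiming-class].
#' @param maturationWindowDays Rectangular kernel length in days (default
#'   180). The effective window of a real profile depends on which enamel
#'   layer is sampled; laser transects of inner enamel see much shorter
#'   effective averaging than bulk drilling.
#' @param nSamples Samples per profile (default 60).
#' @param noiseSd Analytical noise SD; a single number applied to all
#'   isotopes or a named vector like `c(Sr = 1e-4, d18O = 0.2, d13C = 0.1)`.
#' @param seed Integer seed for the noise draws.
#' @param isotopes Which systems to record (default all three).
#' @return Named list of [IsotopeProfile-class] objects, one per isotope.
#' @export
#' @examples
#' iso <- makeIsoscape(c(12, 12), nPatches = 0, backgroundAmplitude = 0,
#'                     backgroundRatio = 0.711, seed = 1)
#' camps <- data.frame(x = 5500, y = 5500, elevation = 2000)
#' sch <- makeSeasonalSchedule(camps, nYears = 6, switchesPerYear = 1)
#' env <- simulateEnvironment(sch, iso)
#' prof <- recordTooth(env, ToothTiming("M2"), noiseSd = 0, seed = 1)
#' stopifnot(all(abs(values(prof$Sr) - 0.711) < 1e-12))
recordTooth <- function(env, timing, maturationWindowDays = 180,
                        nSamples = 60, noiseSd = 0, seed = 1L,
                        isotopes = c("Sr", "d18O", "d13C")) {
  stopifnot(methods::is(env, "EnvironmentSeries"),
            methods::is(timing, "ToothTiming"))
  series <- list(Sr = env@srRatio, d18O = env@d18O, d13C = env@d13C)
  isotopes <- match.arg(isotopes, several.ok = TRUE)
  if (length(noiseSd) == 1L && is.null(names(noiseSd)))
    noiseSd <- stats::setNames(rep(noiseSd, length(isotopes)), isotopes)
  withSeed(seed, {
    out <- lapply(isotopes, function(iso) {
      rec <- recordKernel(env@time, series[[iso]], timing,
                          maturationWindowDays, nSamples)
      sdv <- unname(noiseSd[iso])
      if (is.na(sdv)) sdv <- 0
      val <- rec$value + if (sdv > 0) stats::rnorm(nSamples, 0, sdv) else 0
      IsotopeProfile(paste0("synthetic_", timing@label), iso,
        rec$distance, val, sd = rep(sdv, nSamples),
        metadata = list(toothLabel = timing@label,
                        maturationWindowDays = maturationWindowDays,
                        noiseSd = sdv, seed = seed,
                        ageDays = rec$time))
    })
    stats::setNames(out, isotopes)
  })
}
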