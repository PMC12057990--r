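#' @include AllGenerics.R
NULL

## ---- georeferenced grids ---------------------------------------------------

#' Virtual parent for planar gridded fields
#'
#' Georeferencing is planar metric: `origin` is the (x, y) of the lower-left
#' corner of cell (1, 1) in metres and `cellSize` the square cell edge in
#' metres. Matrix rows index y (south to north), columns index x (west to
#' east). Cell membership is half-open: a point with `x in [x0, x0 + d)`
#' falls in column 1.
#'
#' @slot cellSize Numeric scalar, cell edge length in metres.
#' @slot origin Numeric length-2, (x, y) of the grid's lower-left corner.
#' @keywords internal
#' @export
setClass("GriddedField", representation("VIRTUAL",
  cellSize = "numeric", origin = "numeric"))

setValidity("GriddedField", function(object) {
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    return("cellSize must be a single positive number (metres)")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    return("origin must be a finite (x, y) pair")
  TRUE
})

#' Bioavailable strontium isoscape
#'
#' A paired mean/SD grid of bioavailable 87Sr/86Sr. `meanGrid` holds the
#' predicted ratio per cell, `sdGrid` its one-sigma spatial uncertainty.
#' Produced either synthetically by [makeIsoscape()] or by the
#' quantile-random-forest fit in [fitIsoscape()].
#'
#' @slot meanGrid,sdGrid Numeric matrices of identical shape; `sdGrid > 0`
#'   everywhere (NA cells allowed in both, marking no-data).
#' @slot metadata List: provenance (predictors used, CV scores, seed, ...).
#' @export
setClass("SrIsoscape", contains = "GriddedField",
  representation(meanGrid = "matrix", sdGrid = "matrix", metadata = "list"))

setValidity("SrIsoscape", function(object) {
  if (!identical(dim(object@meanGrid), dim(object@sdGrid)))
    return("meanGrid and sdGrid must have identical shape")
  sdv <- object@sdGrid[!is.na(object@sdGrid)]
  if (any(sdv <= 0))
    return("all sdGrid values must be > 0")
  if (any(is.na(object@meanGrid) != is.na(object@sdGrid)))
    return("meanGrid and sdGrid must share the same NA (no-data) cells")
  TRUE
})

#' Stack of gridded covariates
#'
#' Named covariate layers sharing one georeferencing, used as predictor
#' rasters for isoscape fitting.
#'
#' @slot layers Named list of numeric matrices, all the same shape.
#' @export
setClass("CovariateStack", contains = "GriddedField",
  representation(layers = "list"))

setValidity("CovariateStack", function(object) {
  if (length(object@layers) == 0L) return("at least one layer required")
  nm <- names(object@layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    return("layers must have unique non-empty names")
  dims <- lapply(object@layers, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    return("all layers must share one shape")
  TRUE
})

## ---- intra-tooth profiles --------------------------------------------------

#' Intra-tooth isotope profile
#'
#' An ordered series of measurements along a tooth crown for one isotope
#' system. Positions are millimetres from the enamel-root junction (ERJ);
#' distance increases toward the occlusal surface, so age *decreases* with
#' distance (the crown top is the oldest enamel).
#'
#' @slot toothId Character, e.g. `"ST63_M2"`.
#' @slot isotope One of `"Sr"`, `"d13C"`, `"d18O"`.
#' @slot distance Strictly monotonic positions (mm from ERJ).
#' @slot value Measured values (ratio for Sr, permil V-PDB for deltas).
#' @slot sd Per-sample SD (may be all NA when unknown).
#' @slot metadata List (individual, tooth label, reduction provenance).
#' @export
setClass("IsotopeProfile", representation(
  toothId = "character", isotope = "character",
  distance = "numeric", value = "numeric", sd = "numeric",
  metadata = "list"))

setValidity("IsotopeProfile", function(object) {
  n <- length(object@distance)
  if (length(object@value) != n || length(object@sd) != n)
    return("distance, value and sd must have equal length")
  if (n >= 2) {
    d <- diff(object@distance)
    if (!(all(d > 0) || all(d < 0)))
      return("distances must be strictly monotonic")
  }
  if (!object@isotope %in% c("Sr", "d13C", "d18O"))
    return("isotope must be one of 'Sr', 'd13C', 'd18O'")
  if (any(!is.na(object@sd) & object@sd < 0))
    return("sd must be non-negative")
  TRUE
})

#' Laser-ablation MC-ICP-MS strontium transect
#'
#' Raw per-point ion-beam intensities for masses 88..83 (volts) along an
#' enamel transect, plus the bracketing-standard measurements interleaved
#' in the analytical sequence.
#'
#' @slot position Per-point position along the transect (mm).
#' @slot intensity Matrix with columns named `"88","87","86","85","84","83"`.
#' @slot standards data.frame with columns `position` (sequence position on
#'   the same axis as `position`, standards sit before/after the transect
#'   or between blocks) and `ratio` (measured 87Sr/86Sr of the standard).
#' @export
setClass("LaserTransect", representation(
  position = "numeric", intensity = "matrix", standards = "data.frame"))

setValidity("LaserTransect", function(object) {
  need <- c("88", "87", "86", "85", "84", "83")
  if (!all(need %in% colnames(object@intensity)))
    return("intensity must have columns named 88, 87, 86, 85, 84, 83")
  if (nrow(object@intensity) != length(object@position))
    return("one intensity row per position required")
  if (any(object@intensity < 0, na.rm = TRUE))
    return("intensities must be >= 0")
  if (!all(c("position", "ratio") %in% names(object@standards)))
    return("standards needs columns 'position' and 'ratio'")
  if (nrow(object@standards) < 2L)
    return("at least 2 bracketing standards required")
  TRUE
})

## ---- movement and recording ------------------------------------------------

#' Seasonal camp-to-camp movement schedule
#'
#' Timestamped occupancy of a set of camps over a simulated period; the
#' driver of the forward tooth-recording model.
#'
#' @slot camps Matrix with columns `x`, `y` (metres) and `elevation` (m),
#'   one row per camp.
#' @slot occupancy data.frame with columns `camp` (row index into `camps`),
#'   `start` and `end` (days); intervals are contiguous (each `start`
#'   equals the previous `end`), non-overlapping, and cover the period.
#' @slot yearLength Days per year (365).
#' @export
setClass("MovementSchedule", representation(
  camps = "matrix", occupancy = "data.frame", yearLength = "numeric"))

setValidity("MovementSchedule", function(object) {
  if (!all(c("x", "y", "elevation") %in% colnames(object@camps)))
    return("camps needs columns x, y, elevation")
  occ <- object@occupancy
  if (!all(c("camp", "start", "end") %in% names(occ)))
    return("occupancy needs columns camp, start, end")
  if (any(occ$camp < 1 | occ$camp > nrow(object@camps)))
    return("occupancy camp index out of range")
  if (any(occ$end <= occ$start))
    return("occupancy intervals must have end > start")
  if (nrow(occ) >= 2 &&
      any(abs(occ$start[-1] - occ$end[-nrow(occ)]) > 1e-9))
    return("occupancy intervals must be contiguous and non-overlapping")
  if (length(object@yearLength) != 1L || object@yearLength <= 0)
    return("yearLength must be a positive scalar")
  TRUE
})

#' Molar mineralization timing
#'
#' Start and end age of enamel mineralization for one molar, with the
#' reported uncertainties, and the crown length over which the record is
#' laid down. Defaults for M1/M2/M3 follow the equid literature:
#' M1 0.5 (+/-1) to 23 (+/-3) months, M2 7 (+/-1.5) to 37 (+/-3) months,
#' M3 21 (+/-3) to 55 (+/-2) months, i.e. average integration spans of
#' about 1.9, 2.5 and 2.8 years.
#'
#' @slot label One of `"M1"`, `"M2"`, `"M3"`.
#' @slot startAgeMonths,startSdMonths,endAgeMonths,endSdMonths Numeric.
#' @slot crownLengthMm Crown length sampled (mm).
#' @export
setClass("ToothTiming", representation(
  label = "character",
  startAgeMonths = "numeric", startSdMonths = "numeric",
  endAgeMonths = "numeric", endSdMonths = "numeric",
  crownLengthMm = "numeric"))

setValidity("ToothTiming", function(object) {
  if (object@endAgeMonths <= object@startAgeMonths)
    return("end age must exceed start age")
  if (object@crownLengthMm <= 0)
    return("crown length must be positive")
  TRUE
})

#' Environmental isotope time series experienced by one animal
#'
#' Daily (or finer) series of the environmental values an animal is exposed
#' to under a movement schedule: bioavailable 87Sr/86Sr at the occupied
#' camp, the seasonal d18O signal, the elevation-driven d13C (already in
#' enamel reference frame, pre-noise) and the camp elevation itself.
#'
#' @slot time Days, strictly increasing.
#' @slot srRatio,d18O,d13C,elevation Numeric, same length as `time`.
#' @export
setClass("EnvironmentSeries", representation(
  time = "numeric", srRatio = "numeric", d18O = "numeric",
  d13C = "numeric", elevation = "numeric"))

setValidity("EnvironmentSeries", function(object) {
  n <- length(object@time)
  if (any(c(length(object@srRatio), length(object@d18O),
            length(object@d13C), length(object@elevation)) != n))
    return("all series must have the length of time")
  if (n >= 2 && any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  TRUE
})

## ---- assignment ------------------------------------------------------------

#' Posterior geographic-assignment surface
#'
#' Normalized posterior probability of origin over a square assignment box
#' clipped to the isoscape, plus the top-area mask (the fraction of valid
#' cells with the highest posterior).
#'
#' @slot posterior Matrix; non-negative, sums to 1 over non-NA cells.
#' @slot topMask Logical matrix, same shape; NA outside valid cells.
#' @slot scaleKm Box side length (km) as requested.
#' @slot sampleRef List describing the assigned feature (profile id,
#'   distance mm, observed mean and SD).
#' @export
setClass("AssignmentSurface", contains = "GriddedField",
  representation(posterior = "matrix", topMask = "matrix",
    scaleKm = "numeric", sampleRef = "list"))

setValidity("AssignmentSurface", function(object) {
  if (!identical(dim(object@posterior), dim(object@topMask)))
    return("posterior and topMask must share one shape")
  p <- object@posterior[!is.na(object@posterior)]
  if (length(p) == 0L) return("no valid cells in posterior")
  if (any(p < 0)) return("posterior must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    return("posterior must sum to 1 over valid cells")
  TRUE
})

## ---- seasonality / elevation ----------------------------------------------

#' Calibration from diet carbon isotopes to grazing elevation
#'
#' Linear calibration of diet d13C against elevation in mountain steppe,
#' d13C_diet = a * elevation + b, together with the constants of the
#' enamel-to-diet chain: the Suess-effect shift applied to archaeological
#' enamel measured against a modern calibration (-2 permil) and the
#' diet-to-enamel fractionation for horses (-13.7 permil, applied
#' enamel -> diet by adding the negative offset). Elevations below
#' `plausibleFloor` (default 1500 m) are flagged implausible for the
#' region, not clipped.
#'
#' @slot slope,slopeSe Slope a (permil per metre) and its SE; a < 0.
#' @slot intercept,interceptSe Intercept b (permil) and its SE.
#' @slot suessShift Permil shift for archaeological enamel (-2).
#' @slot dietEnamelOffset Diet minus enamel (-13.7 permil).
#' @slot plausibleFloor Metres; below this the estimate is flagged.
#' @export
setClass("ElevationModel", representation(
  slope = "numeric", slopeSe = "numeric",
  intercept = "numeric", interceptSe = "numeric",
  suessShift = "numeric", dietEnamelOffset = "numeric",
  plausibleFloor = "numeric"))

setValidity("ElevationModel", function(object) {
  if (object@slope >= 0) return("slope must be negative (d13C falls with elevation)")
  if (object@slopeSe < 0 || object@interceptSe < 0)
    return("standard errors must be non-negative")
  TRUE
})

#' Fitted seasonal anchor of a d18O profile
#'
#' Sinusoid fitted to an intra-tooth d18O series, providing the temporal
#' scale of the crown: one period = one year of growth. Degenerate fits
#' (amplitude indistinguishable from noise) carry `degenerate = TRUE` and
#' no usable anchor.
#'
#' @slot amplitude Permil, >= 0. @slot periodMm Crown mm per year.
#' @slot phaseMm Phase offset (mm). @slot meanValue Permil.
#' @slot peaksMm,troughsMm Positions of fitted summer peaks / winter troughs.
#' @slot nYears Full periods covered by the sampled crown range.
#' @slot residualSd Residual SD of the fit.
#' @slot degenerate Logical flag.
#' @export
setClass("SeasonalAnchor", representation(
  amplitude = "numeric", periodMm = "numeric", phaseMm = "numeric",
  meanValue = "numeric", peaksMm = "numeric", troughsMm = "numeric",
  nYears = "numeric", residualSd = "numeric", degenerate = "logical"))

## ---- chronology ------------------------------------------------------------

#' Radiocarbon calibration curve
#'
#' Calendar-gridded calibration curve in the IntCal convention: for each
#' calendar age (cal BP) the conventional radiocarbon age (BP) and its
#' one-sigma uncertainty.
#'
#' @slot calBP Strictly monotonic calendar grid (cal BP).
#' @slot mu Curve radiocarbon age (BP). @slot sigma Curve SD (> 0).
#' @slot name Curve label.
#' @export
setClass("CalibrationCurve", representation(
  calBP = "numeric", mu = "numeric", sigma = "numeric", name = "character"))

setValidity("CalibrationCurve", function(object) {
  n <- length(object@calBP)
  if (length(object@mu) != n || length(object@sigma) != n)
    return("calBP, mu, sigma must have equal length")
  if (n >= 2) {
    d <- diff(object@calBP)
    if (!(all(d > 0) || all(d < 0)))
      return("calBP grid must be strictly monotonic")
  }
  if (any(object@sigma <= 0)) return("curve sigma must be > 0")
  TRUE
})

#' Single-phase Bayesian radiocarbon model
#'
#' Posterior draws for the phase start (alpha, cal BP), end (beta) and the
#' latent calendar dates, under a uniform-phase prior with the standard
#' 1/(alpha - beta) span correction.
#'
#' @slot alpha,beta Posterior draws (cal BP), pooled over chains after
#'   burn-in; `alpha >= beta` draw-wise so span >= 0.
#' @slot theta Matrix of latent calendar-date draws (draws x samples).
#' @slot summary data.frame with medians and 95.4% HPD for start, end, span.
#' @slot hpd List of HPD interval matrices per parameter.
#' @slot rhat Named split-R-hat for alpha and beta.
#' @slot calibrated List of per-sample calibrated densities (for plotting).
#' @export
setClass("PhaseModel", representation(
  alpha = "numeric", beta = "numeric", theta = "matrix",
  summary = "data.frame", hpd = "list", rhat = "numeric",
  calibrated = "list"))

setValidity("PhaseModel", function(object) {
  if (length(object@alpha) != length(object@beta))
    return("alpha and beta draws must align")
  if (any(object@alpha - object@beta < 0))
    return("span must be >= 0 for every retained draw")
  TRUE
})

## ---- tracks ----------------------------------------------------------------

#' GPS track
#'
#' Timestamped planar positions of a collared animal, optionally with
#' elevations.
#'
#' @slot time Days, non-decreasing. @slot x,y Metres.
#' @slot elevation Metres (may be length 0 when absent).
#' @export
setClass("Track", representation(
  time = "numeric", x = "numeric", y = "numeric", elevation = "numeric"))

setValidity("Track", function(object) {
  n <- length(object@time)
  if (length(object@x) != n || length(object@y) != n)
    return("time, x, y must have equal length")
  if (length(object@elevation) > 0L && length(object@elevation) != n)
    return("elevation must be empty or match time")
  if (n >= 2 && any(diff(object@time) < 0))
    return("timestamps must be non-decreasing")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "SrIsoscape", function(object) {
  d <- dim(object@meanGrid)
  rng <- range(object@meanGrid, na.rm = TRUE)
  cat(sprintf("SrIsoscape: %d x %d cells of %.0f m\n", d[1], d[2], object@cellSize),
      sprintf("  87Sr/86Sr mean in [%.4f, %.4f]; median SD %.5f\n",
              rng[1], rng[2], stats::median(object@sdGrid, na.rm = TRUE)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "IsotopeProfile", function(object) {
  cat(sprintf("IsotopeProfile '%s' (%s): %d samples, %.1f-%.1f mm from ERJ\n",
              object@toothId, object@isotope, length(object@distance),
              min(object@distance), max(object@distance)))
})

setMethod("show", "MovementSchedule", function(object) {
  cat(sprintf("MovementSchedule: %d camps, %d occupancy spells over %.0f days\n",
              nrow(object@camps), nrow(object@occupancy),
              max(object@occupancy$end) - min(object@occupancy$start)))
})

setMethod("show", "AssignmentSurface", function(object) {
  nv <- sum(!is.na(object@posterior))
  cat(sprintf("AssignmentSurface: %.0f km box, %d valid cells, top area %d cells\n",
              object@scaleKm, nv, sum(object@topMask, na.rm = TRUE)))
})

setMethod("show", "PhaseModel", function(object) {
  cat("Single-phase radiocarbon model\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "SeasonalAnchor", function(object) {
  if (object@degenerate) {
    cat("SeasonalAnchor: degenerate (no resolvable seasonal cycle)\n")
  } else {
    cat(sprintf(
      "SeasonalAnchor: amplitude %.2f permil, period %.1f mm/yr, %.2f yr covered\n",
      object@amplitude, object@periodMm, object@nYears))
  }
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve '%s': %d knots, %.0f-%.0f cal BP\n",
              object@name, length(object@calBP),
              min(object@calBP), max(object@calBP)))
})

## ---- accessors -------------------------------------------------------------

#' @rdname accessors
setMethod("meanGrid", "SrIsoscape", function(x, ...) x@meanGrid)
#' @rdname accessors
setMethod("sdGrid", "SrIsoscape", function(x, ...) x@sdGrid)
#' @rdname accessors
setMethod("cellSize", "GriddedField", function(x, ...) x@cellSize)
#' @rdname accessors
setMethod("gridOrigin", "GriddedField", function(x, ...) x@origin)
#' @rdname accessors
setMethod("gridDim", "SrIsoscape", function(x, ...) dim(x@meanGrid))
#' @rdname accessors
setMethod("gridDim", "CovariateStack", function(x, ...) dim(x@layers[[1]]))
#' @rdname accessors
setMethod("gridDim", "AssignmentSurface", function(x, ...) dim(x@posterior))
#' @rdname accessors
setMethod("distances", "IsotopeProfile", function(x, ...) x@distance)
#' @rdname accessors
setMethod("values", "IsotopeProfile", function(x, ...) x@value)
#' @rdname accessors
setMethod("valueSds", "IsotopeProfile", function(x, ...) x@sd)
#' @rdname accessors
setMethod("isotope", "IsotopeProfile", function(x, ...) x@isotope)
#' @rdname accessors
setMethod("toothId", "IsotopeProfile", function(x, ...) x@toothId)
#' @rdname accessors
setMethod("posteriorGrid", "AssignmentSurface", function(x, ...) x@posterior)
#' @rdname accessors
setMethod("topMask", "AssignmentSurface", function(x, ...) x@topMask)
#' @rdname accessors
setMethod("layerNames", "CovariateStack", function(x, ...) names(x@layers))
#' @rdname accessors
setMethod("getLayer", "CovariateStack", function(x, name, ...) {
  if (!name %in% names(x@layers)) stop("no layer named '", name, "'")
  x@layers[[name]]
})
#' @rdname accessors
setMethod("nYears", "SeasonalAnchor", function(x, ...) x@nYears)
#' @rdname accessors
setMethod("isDegenerate", "SeasonalAnchor", function(x, ...) x@degenerate)
#' @rdname accessors
setMethod("phaseSummary", "PhaseModel", function(x, ...) x@summary)
#' @rdname accessors
setMethod("hpdIntervals", "PhaseModel", function(x, ...) x@hpd)

## ---- user-facing constructors ---------------------------------------------

#' Construct an IsotopeProfile
#'
#' @param toothId Identifier, e.g. `"ST63_M2"`.
#' @param isotope `"Sr"`, `"d13C"` or `"d18O"`.
#' @param distance Positions in mm from the ERJ (strictly monotonic).
#' @param value Measured values.
#' @param sd Optional per-sample SD (recycled NA when missing).
#' @param metadata Optional list.
#' @return An [IsotopeProfile-class] object.
#' @export
#' @examples
#' IsotopeProfile("demo", "d18O", 1:5, c(-12, -11, -10, -11, -12))
IsotopeProfile <- function(toothId, isotope, distance, value,
                           sd = rep(NA_real_, length(distance)),
                           metadata = list()) {
  methods::new("IsotopeProfile", toothId = as.character(toothId),
    isotope = isotope, distance = as.numeric(distance),
    value = as.numeric(value), sd = as.numeric(sd), metadata = metadata)
}

#' Construct a MovementSchedule
#'
#' @param camps Matrix or data.frame with columns `x`, `y`, `elevation`.
#' @param occupancy data.frame with columns `camp`, `start`, `end` (days);
#'   must be contiguous and non-overlapping.
#' @param yearLength Days per year.
#' @return A [MovementSchedule-class] object.
#' @export
MovementSchedule <- function(camps, occupancy, yearLength = 365) {
  camps <- as.matrix(as.data.frame(camps)[, c("x", "y", "elevation"),
                                          drop = FALSE])
  methods::new("MovementSchedule", camps = camps,
    occupancy = as.data.frame(occupancy), yearLength = yearLength)
}

#' Construct a ToothTiming, with equid molar defaults
#'
#' Defaults encode the mineralization ages used for horse molars:
#' M1 0.5 (+/-1) to 23 (+/-3) months, M2 7 (+/-1.5) to 37 (+/-3),
#' M3 21 (+/-3) to 55 (+/-2).
#'
#' @param label `"M1"`, `"M2"` or `"M3"`; selects the default ages.
#' @param startAgeMonths,startSdMonths,endAgeMonths,endSdMonths Override
#'   the defaults.
#' @param crownLengthMm Crown length (mm), default 70.
#' @return A [ToothTiming-class] object.
#' @export
#' @examples
#' ToothTiming("M2")
ToothTiming <- function(label = c("M1", "M2", "M3"),
                        startAgeMonths = NULL, startSdMonths = NULL,
                        endAgeMonths = NULL, endSdMonths = NULL,
                        crownLengthMm = 70) {
  label <- match.arg(label)
  defaults <- list(
    M1 = c(start = 0.5, startSd = 1,   end = 23, endSd = 3),
    M2 = c(start = 7,   startSd = 1.5, end = 37, endSd = 3),
    M3 = c(start = 21,  startSd = 3,   end = 55, endSd = 2))[[label]]
  methods::new("ToothTiming", label = label,
    startAgeMonths = startAgeMonths %||% defaults[["start"]],
    startSdMonths = startSdMonths %||% defaults[["startSd"]],
    endAgeMonths = endAgeMonths %||% defaults[["end"]],
    endSdMonths = endSdMonths %||% defaults[["endSd"]],
    crownLengthMm = crownLengthMm)
}

#' Average environmental integration span of a tooth
#'
#' Years of environmental input averaged into a molar's enamel record,
#' (end - start) mineralization age. With the defaults this is about 1.9 y
#' for the M1, 2.5 y for the M2 and 2.8 y for the M3.
#'
#' @param timing A [ToothTiming-class] object.
#' @return Numeric scalar, years.
#' @export
#' @examples
#' integrationYears(ToothTiming("M1"))
integrationYears <- function(timing) {
  stopifnot(methods::is(timing, "ToothTiming"))
  (timing@endAgeMonths - timing@startAgeMonths) / 12
}

#' Construct an ElevationModel (Altai horse calibration defaults)
#'
#' Defaults are the published Altai calibration: slope -1.45e-3 (SE
#' 3.07e-4) permil per metre, intercept -24.14 (SE 0.71) permil, Suess
#' shift -2 permil, diet-enamel fractionation -13.7 permil, plausibility
#' floor 1500 m.
#'
#' @param slope,slopeSe,intercept,interceptSe Calibration coefficients.
#' @param suessShift,dietEnamelOffset,plausibleFloor Chain constants.
#' @return An [ElevationModel-class] object.
#' @export
ElevationModel <- function(slope = -1.45e-3, slopeSe = 3.07e-4,
                           intercept = -24.14, interceptSe = 0.71,
                           suessShift = -2.0, dietEnamelOffset = -13.7,
                           plausibleFloor = 1500) {
  methods::new("ElevationModel", slope = slope, slopeSe = slopeSe,
    intercept = intercept, interceptSe = interceptSe,
    suessShift = suessShift, dietEnamelOffset = dietEnamelOffset,
    plausibleFloor = plausibleFloor)
}

#' Construct a CovariateStack
#'
#' @param layers Named list of numeric matrices (same shape).
#' @param cellSize Cell edge (m). @param origin (x, y) lower-left corner.
#' @return A [CovariateStack-class] object.
#' @export
CovariateStack <- function(layers, cellSize, origin = c(0, 0)) {
  methods::new("CovariateStack", layers = layers, cellSize = cellSize,
    origin = origin)
}

#' Construct a LaserTransect
#'
#' @param position Per-point positions (mm).
#' @param intensity Matrix of beam intensities, columns `88`..`83` (V).
#' @param standards data.frame(position, ratio) of bracketing standards.
#' @return A [LaserTransect-class] object.
#' @export
LaserTransect <- function(position, intensity, standards) {
  methods::new("LaserTransect", position = as.numeric(position),
    intensity = as.matrix(intensity), standards = as.data.frame(standards))
}

#' Construct a Track
#'
#' @param time Days (non-decreasing). @param x,y Metres.
#' @param elevation Optional metres.
#' @return A [Track-class] object.
#' @export
Track <- function(time, x, y, elevation = numeric(0)) {
  methods::new("Track", time = as.numeric(time), x = as.numeric(x),
    y = as.numeric(y), elevation = as.numeric(elevation))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
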