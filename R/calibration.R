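#' @include AllClasses.R synthetic-radiocarbon.R
NULL

#' Read a calibration curve in the IntCal .14c dialect
#'
#' Comma-separated files with `#`-prefixed header lines and columns
#' cal BP, 14C age (BP), one-sigma error (further columns ignored), as
#' distributed for the IntCal family of curves.
#'
#' @param path File path.
#' @param name Curve label (default the file name).
#' @return A [CalibrationCurve-class].
#' @export
readCalCurve <- function(path, name = basename(path)) {
  dat <- utils::read.table(path, sep = ",", comment.char = "#",
                           strip.white = TRUE)
  if (ncol(dat) < 3) stop("curve file needs >= 3 comma-separated columns")
  ord <- order(dat[[1]])
  methods::new("CalibrationCurve", calBP = as.numeric(dat[[1]][ord]),
    mu = as.numeric(dat[[2]][ord]), sigma = as.numeric(dat[[3]][ord]),
    name = name)
}

#' Radiocarbon quality-control filter on collagen indicators
#'
#' Retains a sample when its atomic C/N ratio lies in the accepted
#' collagen-preservation band (3.1 to 3.3) OR its collagen extraction
#' yield is at least the threshold (5% m/m). Samples with both
#' indicators missing are flagged indeterminate and excluded.
#'
#' @param samples data.frame with columns `c_to_n` and/or
#'   `collagen_yield` (either may be NA), plus anything else (carried
#'   through).
#' @param cnRange Accepted C/N band (default `c(3.1, 3.3)`).
#' @param minYield Minimum yield in percent (default 5).
#' @return List: `retained` (data.frame), `report` (per-sample decision
#'   and reason).
#' @export
#' @examples
#' qcFilter(data.frame(id = c("a", "b"), c_to_n = c(3.2, 3.5),
#'                     collagen_yield = c(1, 4)))
qcFilter <- function(samples, cnRange = c(3.1, 3.3), minYield = 5) {
  cn <- if ("c_to_n" %in% names(samples)) samples$c_to_n
        else rep(NA_real_, nrow(samples))
  yd <- if ("collagen_yield" %in% names(samples)) samples$collagen_yield
        else rep(NA_real_, nrow(samples))
  cnOk <- !is.na(cn) & cn >= cnRange[1] & cn <= cnRange[2]
  ydOk <- !is.na(yd) & yd >= minYield
  indeterminate <- is.na(cn) & is.na(yd)
  keep <- (cnOk | ydOk) & !indeterminate
  reason <- ifelse(indeterminate, "indeterminate: both indicators missing",
            ifelse(keep,
                   ifelse(cnOk, "C/N in range", "yield >= threshold"),
                   "C/N out of range and yield below threshold"))
  list(retained = samples[keep, , drop = FALSE],
       report = data.frame(id = if ("id" %in% names(samples)) samples$id
                                else seq_len(nrow(samples)),
                           retained = keep, reason = reason))
}

## linear interpolation of curve mean and sd at calendar ages
curveAt <- function(curve, theta) {
  list(mu = stats::approx(curve@calBP, curve@mu, xout = theta)$y,
       sigma = stats::approx(curve@calBP, curve@sigma, xout = theta)$y)
}

## unnormalized calibration likelihood of one date on a calendar grid
calLikelihood <- function(bp, sigma, curve, grid) {
  cv <- curveAt(curve, grid)
  stats::dnorm(bp, mean = cv$mu, sd = sqrt(sigma^2 + cv$sigma^2))
}

#' Calibrate a radiocarbon date
#'
#' Posterior over calendar age for a conventional age `bp +/- sigma`:
#' `density(theta) ~ exp(-(bp - mu(theta))^2 / (2 (sigma^2 +
#' sigma_curve(theta)^2)))` on a 1-year calendar grid over the curve
#' support (curve linearly interpolated between knots), normalized by
#' trapezoidal integration. Errors out when noticeable posterior mass
#' sits at the grid boundary (curve range too narrow).
#'
#' @param bp Conventional radiocarbon age (BP). @param sigma Lab
#'   one-sigma (years).
#' @param curve A [CalibrationCurve-class].
#' @param step Calendar grid step (default 1 year).
#' @param hpdLevel HPD mass (default 0.954, the 2-sigma convention).
#' @return List: `grid` (cal BP), `density` (integrates to 1), `median`
#'   (cal BP), `hpd` (matrix of interval rows `lower`, `upper` in cal
#'   BP), `p` the HPD level.
#' @export
calibrate <- function(bp, sigma, curve, step = 1, hpdLevel = 0.954) {
  stopifnot(methods::is(curve, "CalibrationCurve"), sigma > 0)
  grid <- seq(min(curve@calBP), max(curve@calBP), by = step)
  dens <- calLikelihood(bp, sigma, curve, grid)
  total <- sum((dens[-1] + dens[-length(dens)]) / 2) * step
  if (total <= 0) stop("calibration curve does not cover the date")
  dens <- dens / total
  edge <- max(dens[1], dens[length(dens)]) * step
  if (edge > 1e-3)
    stop("curve range too narrow: posterior mass at the grid boundary")
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2) * step
  med <- grid[-1][which.min(abs(cdf - 0.5))]
  list(grid = grid, density = dens, median = med,
       hpd = densityHpd(grid, dens, hpdLevel), p = hpdLevel)
}

## HPD set of a gridded density: highest-density cells until `level` mass,
## returned as contiguous intervals
densityHpd <- function(grid, dens, level) {
  step <- grid[2] - grid[1]
  ord <- order(dens, decreasing = TRUE)
  mass <- cumsum(dens[ord]) * step
  k <- which(mass >= level)[1]
  if (is.na(k)) k <- length(ord)
  sel <- sort(ord[seq_len(k)])
  breaks <- which(diff(sel) > 1)
  starts <- c(sel[1], sel[breaks + 1])
  ends <- c(sel[breaks], sel[length(sel)])
  cbind(lower = grid[starts], upper = grid[ends])
}

## HPD interval of posterior draws (shortest interval containing `level`)
drawsHpd <- function(draws, level = 0.954) {
  x <- sort(draws)
  n <- length(x)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Convert calendar ages between cal BP and BCE/CE
#'
#' cal BP counts back from CE 1950; there is no year zero, so
#' `BCE = calBP - 1949` for dates before the common era (cal BP 2991 is
#' 1042 cal BCE).
#'
#' @param calBP Calendar ages (cal BP).
#' @return Numeric: years BCE (positive) for `calBP >= 1950`, negative
#'   values meaning CE years otherwise.
#' @export
#' @examples
#' calBPtoBCE(2991) # 1042
calBPtoBCE <- function(calBP) {
  ifelse(calBP >= 1950, calBP - 1949, -(1950 - calBP))
}
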