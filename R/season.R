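#' @include AllClasses.R
NULL

#' Fit the seasonal sinusoid of a d18O profile
#'
#' Anchors a tooth in seasonal time: a sinusoid
#' `mean + A * sin(2 pi (d - phase) / period)` is fitted to the
#' intra-tooth d18O series by nonlinear least squares, with the period
#' seeded from the dominant discrete-Fourier component and the fit
#' restarted over a small period grid. Summers sit at the fitted peaks,
#' winters at the troughs, and one period is one year of crown growth.
#' Fits whose amplitude is indistinguishable from noise (fitted
#' `A < 2 * residual SD`) are flagged degenerate and carry no anchor.
#'
#' @param profile An [IsotopeProfile-class] with >= 8 samples (d18O).
#' @return A [SeasonalAnchor-class].
#' @export
#' @examples
#' d <- seq(0, 60, length.out = 40)
#' p <- IsotopeProfile("demo", "d18O", d,
#'   -12.8 + 2.45 * sin(2 * pi * (d - 5) / 30))
#' fitSeasonalAnchor(p)
fitSeasonalAnchor <- function(profile) {
  stopifnot(methods::is(profile, "IsotopeProfile"))
  d <- profile@distance; y <- profile@value
  if (length(d) < 8) stop("need at least 8 samples to fit a seasonal anchor")
  span <- diff(range(d))
  yc <- y - mean(y)

  degenerateAnchor <- function(resSd) methods::new("SeasonalAnchor",
    amplitude = 0, periodMm = NA_real_, phaseMm = NA_real_,
    meanValue = mean(y), peaksMm = numeric(0), troughsMm = numeric(0),
    nYears = NA_real_, residualSd = resSd, degenerate = TRUE)

  if (stats::sd(y) == 0) return(degenerateAnchor(0))

  ## period seeds: dominant DFT component on a regular resample + grid
  ng <- 128L
  gd <- seq(min(d), max(d), length.out = ng)
  gy <- stats::approx(d, yc, xout = gd)$y
  sp <- Mod(stats::fft(gy - mean(gy)))[2:(ng %/% 2)]
  kStar <- which.max(sp)
  pSeeds <- unique(pmin(pmax(
    span / c(kStar, kStar + 1, max(kStar - 1, 1), kStar + 2, 2 * kStar),
    span / 20), 4 * span))

  best <- NULL
  for (p0 in pSeeds) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ m + A * sin(2 * pi * (d - phi) / P),
      start = list(m = mean(y), A = stats::sd(y) * sqrt(2),
                   phi = min(d), P = p0),
      lower = c(-Inf, 0, -Inf, span / 50),
      upper = c(Inf, Inf, Inf, 10 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(degenerateAnchor(stats::sd(y)))

  cf <- stats::coef(best$fit)
  A <- abs(cf[["A"]]); P <- cf[["P"]]; phi <- cf[["phi"]]; m <- cf[["m"]]
  resSd <- sqrt(best$rss / max(length(y) - 4, 1))
  if (A < 2 * resSd) return(degenerateAnchor(resSd))

  ## fitted peaks (phi + P/4 + kP) and troughs (phi + 3P/4 + kP) in range
  kk <- seq(floor((min(d) - phi) / P) - 1, ceiling((max(d) - phi) / P) + 1)
  peaks <- phi + P / 4 + kk * P
  troughs <- phi + 3 * P / 4 + kk * P
  inR <- function(v) sort(v[v >= min(d) & v <= max(d)])
  methods::new("SeasonalAnchor", amplitude = A, periodMm = P,
    phaseMm = phi %% P, meanValue = m, peaksMm = inR(peaks),
    troughsMm = inR(troughs), nYears = span / P, residualSd = resSd,
    degenerate = FALSE)
}

#' Observed amplitude of a profile
#'
#' Plain range (max minus min) of the series; order-invariant. The field
#' reports amplitudes of d18O on raw values and of Sr on the smoothed
#' profile.
#'
#' @param profile An [IsotopeProfile-class] (>= 2 samples) or numeric
#'   vector.
#' @return Numeric scalar, `max - min`.
#' @export
#' @examples
#' profileAmplitude(IsotopeProfile("x", "d18O", 1:3, c(-18, -10, -5.7)))
profileAmplitude <- function(profile) {
  v <- if (methods::is(profile, "IsotopeProfile")) profile@value
       else as.numeric(profile)
  if (length(v) < 2) stop("need at least 2 samples")
  max(v) - min(v)
}
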