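#' @include AllClasses.R season.R
NULL

#' Exact penalized change-point segmentation (PELT)
#'
#' Piecewise-constant least-squares segmentation: minimizes the summed
#' within-segment squared error plus `penalty` per change point, by the
#' pruned exact linear-time dynamic program. Segment cost is
#' `sum((x - mean)^2)` from cumulative sums; pruning uses the standard
#' condition for concatenation-subadditive costs.
#'
#' @param x Numeric series.
#' @param penalty Penalty per change point (> 0), in squared-data units.
#' @param minSegment Minimum segment length in samples (default 5).
#' @return List with `changepoints` (last index of each segment except
#'   the final one), `segments` data.frame(start, end, mean), and `cost`.
#' @export
#' @examples
#' x <- rep(c(0, 1, 0, 1, 0), each = 20)
#' peltSegment(x, penalty = 1)$changepoints
peltSegment <- function(x, penalty, minSegment = 5) {
  n <- length(x)
  if (n < 2 * minSegment)
    stop(sprintf("series of %d samples shorter than 2 x minimum segment length (%d)",
                 n, minSegment))
  stopifnot(penalty > 0)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  segCost <- function(i, j) { # cost of x[i..j]
    m <- j - i + 1
    cs2[j + 1] - cs2[i] - (cs[j + 1] - cs[i])^2 / m
  }
  F <- rep(Inf, n + 1)
  F[1] <- -penalty
  lastCp <- integer(n + 1)
  cand <- 0L # candidate previous change points (0-based positions)
  for (t in minSegment:n) {
    ok <- cand[t - cand >= minSegment]
    recent <- cand[t - cand < minSegment]
    if (length(ok) == 0L) next
    vals <- F[ok + 1L] + vapply(ok, function(s) segCost(s + 1L, t),
                                numeric(1)) + penalty
    best <- which.min(vals)
    F[t + 1L] <- vals[best]
    lastCp[t + 1L] <- ok[best]
    ## prune evaluated candidates that can never win again; keep the ones
    ## still too recent to evaluate, and admit t itself as a future split
    pruned <- ok[vals - penalty <= F[t + 1L]]
    cand <- unique(c(pruned, recent,
                     if (is.finite(F[t + 1L])) t else NULL))
  }
  ## backtrack
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- lastCp[t + 1L]
    if (s == 0L) break
    cps <- c(s, cps)
    t <- s
  }
  starts <- c(1L, cps + 1L)
  ends <- c(cps, n)
  means <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  list(changepoints = cps,
       segments = data.frame(start = starts, end = ends, mean = means),
       cost = F[n + 1L])
}

#' Count camp relocations from a smoothed strontium profile
#'
#' Segments the smoothed 87Sr/86Sr series into piecewise-constant
#' residence levels by exact penalized change-point search
#' ([peltSegment()]); each boundary is read as one relocation. When a
#' seasonal anchor is supplied, the rate per year uses the anchor's
#' period (crown mm per year); otherwise only the raw count is returned.
#'
#' The default penalty is built for kernel-smoothed enamel records, where
#' every real camp switch appears as a monotone ramp spanning roughly the
#' rolling-smoothing window plus the enamel maturation window: the
#' penalty is set just above the squared-error gain of splitting such a
#' ramp (`transitionSamples * gap^2 / 16`, `gap` the robust level
#' separation), with a noise floor of `2 * sigma^2 * log(n)`.
#'
#' @param profile Smoothed Sr [IsotopeProfile-class] (see
#'   [rollingSmooth()]) or numeric vector.
#' @param anchor Optional [SeasonalAnchor-class] for the per-year rate.
#' @param penalty Penalty per change point; NULL (default) for the
#'   automatic choice above.
#' @param minSegment Minimum residence length in samples (default 5).
#' @param transitionSamples Expected ramp length in samples for the
#'   automatic penalty; default twice the profile's smoothing window
#'   (70 when unrecorded).
#' @return List: `segments` data.frame(start_mm, end_mm, mean),
#'   `nRelocations`, `ratePerYear` (NA without a usable anchor),
#'   `penalty` used.
#' @export
countRelocations <- function(profile, anchor = NULL, penalty = NULL,
                             minSegment = 5, transitionSamples = NULL) {
  if (methods::is(profile, "IsotopeProfile")) {
    x <- profile@value
    d <- profile@distance
    win <- profile@metadata$windowN
  } else {
    x <- as.numeric(profile)
    d <- seq_along(x)
    win <- NULL
  }
  n <- length(x)
  if (is.null(transitionSamples))
    transitionSamples <- 2L * (win %||% 35L)
  if (is.null(penalty)) {
    gap <- diff(stats::quantile(x, c(0.1, 0.9), names = FALSE))
    sig <- stats::mad(diff(x)) / sqrt(2)
    penalty <- max(1.2 * transitionSamples * gap^2 / 16,
                   2 * sig^2 * log(n),
                   1e-12 * max(stats::var(x), 1e-20), 1e-20)
  }
  seg <- peltSegment(x, penalty, minSegment)
  segs <- data.frame(start_mm = d[seg$segments$start],
                     end_mm = d[seg$segments$end],
                     mean = seg$segments$mean)
  nRel <- length(seg$changepoints)
  rate <- NA_real_
  if (!is.null(anchor) && methods::is(anchor, "SeasonalAnchor") &&
      !anchor@degenerate && is.finite(anchor@periodMm)) {
    years <- diff(range(d)) / anchor@periodMm
    if (years > 0) rate <- nRel / years
  }
  list(segments = segs, nRelocations = nRel, ratePerYear = rate,
       penalty = penalty)
}
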