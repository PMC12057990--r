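#' @include tooth-recorder.R
NULL

#' Annotate a GPS track with isoscape values
#'
#' Nearest-cell (containing-cell, half-open convention) lookup of the
#' isoscape mean at each GPS fix. Fixes outside the extent are flagged
#' and excluded with a reported count; gaps between consecutive retained
#' fixes longer than `gapDays` are flagged.
#'
#' @param track A [Track-class].
#' @param isoscape An [SrIsoscape-class].
#' @param gapDays Gap-flag threshold in days (default 7).
#' @return data.frame(time, x, y, ratio, gapAfter) of retained fixes;
#'   attributes `excluded` (count) and `gaps` (data.frame of flagged
#'   gaps).
#' @export
annotateTrack <- function(track, isoscape, gapDays = 7) {
  stopifnot(methods::is(track, "Track"),
            methods::is(isoscape, "SrIsoscape"))
  ratio <- lookupCells(isoscape, isoscape@meanGrid, track@x, track@y)
  keep <- !is.na(ratio)
  nExcluded <- sum(!keep)
  if (nExcluded > 0)
    warning(nExcluded, " fix(es) outside the isoscape extent excluded")
  out <- data.frame(time = track@time[keep], x = track@x[keep],
                    y = track@y[keep], ratio = ratio[keep])
  gapAfter <- c(diff(out$time) > gapDays, FALSE)
  out$gapAfter <- gapAfter
  attr(out, "excluded") <- nExcluded
  attr(out, "gaps") <- out[which(gapAfter), c("time", "x", "y")]
  out
}

## time-weighted residence series from an annotated track: the animal is
## taken to reside at each fix until the next one (step function), so
## fix values are weighted by inter-fix duration, not fix count
trackToSeries <- function(annotated) {
  stopifnot(nrow(annotated) >= 2)
  t <- annotated$time; v <- annotated$ratio
  ## step series represented piecewise-linearly with near-vertical risers
  eps <- min(diff(t)) * 1e-6
  time <- as.vector(rbind(t, c(t[-1] - eps, t[length(t)] + eps)))
  value <- rep(v, each = 2)
  ok <- !duplicated(time)
  list(time = time[ok], value = value[ok])
}

#' Predict an intra-tooth profile from a GPS track
#'
#' Forward model for validating measured enamel profiles against known
#' movements: the annotated track becomes a time-weighted residence
#' series (each fix holds until the next), which is run through the same
#' recording kernel as the synthetic tooth recorder ([recordTooth()]) —
#' linear crown-distance/time mapping plus rectangular maturation
#' averaging — noise-free.
#'
#' @param trackSeries Annotated track from [annotateTrack()], or a
#'   list/data.frame with `time` (days) and `value` columns.
#' @param timing A [ToothTiming-class].
#' @param maturationWindowDays Kernel length (days, default 180).
#' @param nSamples Samples along the crown (default 60).
#' @return An [IsotopeProfile-class] (isotope `"Sr"`).
#' @export
predictProfile <- function(trackSeries, timing,
                           maturationWindowDays = 180, nSamples = 60) {
  stopifnot(methods::is(timing, "ToothTiming"))
  if (is.data.frame(trackSeries) && "ratio" %in% names(trackSeries))
    trackSeries <- trackToSeries(trackSeries)
  rec <- recordKernel(trackSeries$time, trackSeries$value, timing,
                      maturationWindowDays, nSamples)
  IsotopeProfile(paste0("predicted_", timing@label), "Sr",
    rec$distance, rec$value, sd = rep(0, nSamples),
    metadata = list(toothLabel = timing@label, forwardModel = TRUE,
                    maturationWindowDays = maturationWindowDays))
}

#' Compare a predicted and a measured profile
#'
#' Resamples both profiles onto the overlap of their distance ranges by
#' linear interpolation and reports RMSE, mean bias (measured minus
#' predicted) and Spearman rank correlation.
#'
#' @param predicted,measured [IsotopeProfile-class] objects.
#' @param nGrid Common-grid size (default 200).
#' @return List: `rmse`, `bias`, `spearman`, `nGrid`.
#' @export
compareProfiles <- function(predicted, measured, nGrid = 200) {
  dp <- range(predicted@distance); dm <- range(measured@distance)
  lo <- max(dp[1], dm[1]); hi <- min(dp[2], dm[2])
  if (lo >= hi) stop("profiles have non-overlapping distance ranges")
  g <- seq(lo, hi, length.out = nGrid)
  vp <- stats::approx(predicted@distance, predicted@value, xout = g)$y
  vm <- stats::approx(measured@distance, measured@value, xout = g)$y
  diffs <- vm - vp
  list(rmse = sqrt(mean(diffs^2)), bias = mean(diffs),
       spearman = suppressWarnings(stats::cor(vp, vm, method = "spearman")),
       nGrid = nGrid)
}
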