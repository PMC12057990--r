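#' @include grid-utils.R smoothing.R
NULL

#' Extract assignable features from a smoothed profile
#'
#' Automates the choice of profile positions worth assigning: local
#' extrema of the smoothed series whose prominence (absolute difference
#' from both neighbouring opposite extrema) exceeds `prominence`, labelled
#' `peak` or `trough`; long flat stretches are summarized by their
#' midpoint as `plateau` when no extremum qualifies. Each feature carries
#' the smoothed mean `m` and the rolling SD `s` at that position.
#'
#' @param profile A smoothed [IsotopeProfile-class] (see
#'   [rollingSmooth()]); the `sd` slot supplies `s`.
#' @param prominence Minimum prominence in ratio units (default 5e-4).
#' @return data.frame(distance, m, s, label), one row per feature; a
#'   single `plateau` row (profile midpoint) when no extremum qualifies.
#' @export
profileFeatures <- function(profile, prominence = 5e-4) {
  stopifnot(methods::is(profile, "IsotopeProfile"))
  v <- profile@value; d <- profile@distance; s <- profile@sd
  n <- length(v)
  rows <- list()
  if (n >= 3) {
    ## interior strict extrema with two-sided prominence
    for (i in 2:(n - 1)) {
      if (v[i] > v[i - 1] && v[i] >= v[i + 1]) {
        prom <- min(v[i] - min(v[1:(i - 1)]), v[i] - min(v[(i + 1):n]))
        if (prom >= prominence)
          rows[[length(rows) + 1L]] <-
            data.frame(distance = d[i], m = v[i], s = s[i], label = "peak")
      } else if (v[i] < v[i - 1] && v[i] <= v[i + 1]) {
        prom <- min(max(v[1:(i - 1)]) - v[i], max(v[(i + 1):n]) - v[i])
        if (prom >= prominence)
          rows[[length(rows) + 1L]] <-
            data.frame(distance = d[i], m = v[i], s = s[i], label = "trough")
      }
    }
  }
  if (length(rows) == 0L) {
    mid <- (n + 1L) %/% 2L
    return(data.frame(distance = d[mid], m = v[mid], s = s[mid],
                      label = "plateau"))
  }
  out <- do.call(rbind, rows)
  ## collapse runs of identical-value neighbours (flat-topped extrema)
  out[!duplicated(out[, c("m", "label")]), , drop = FALSE]
}

#' Bayesian posterior surface for one profile feature
#'
#' Continuous-surface geographic assignment: within a square box clipped
#' to the isoscape, the likelihood of cell i for an observed smoothed
#' ratio `m` with rolling SD `s` is the normal density of `m` at the cell
#' mean `mu_i` with variance `sigma_i^2 + s^2` (isoscape spatial
#' uncertainty and sample uncertainty in quadrature). With a uniform
#' prior over the box, the posterior is the likelihood normalized to sum
#' to 1 over valid cells.
#'
#' @param feature One-row data.frame (or list) with `m` and `s`
#'   (see [profileFeatures()]); `distance` carried into `sampleRef`.
#' @param isoscape An [SrIsoscape-class].
#' @param center (x, y) of the box centre (m).
#' @param scaleKm Box side (km).
#' @param fraction Top-area fraction for the mask (default 0.10).
#' @return An [AssignmentSurface-class] over the clipped box.
#' @export
posteriorSurface <- function(feature, isoscape, center, scaleKm,
                             fraction = 0.10) {
  stopifnot(methods::is(isoscape, "SrIsoscape"))
  m <- feature$m; s <- feature$s
  if (is.null(s) || is.na(s)) s <- 0
  idx <- boxIndices(isoscape, center[1], center[2], scaleKm * 1000)
  if (is.null(idx))
    stop(sprintf("assignment box (%.0f km) lies fully outside the isoscape",
                 scaleKm))
  mu <- isoscape@meanGrid[idx$rows, idx$cols, drop = FALSE]
  sg <- isoscape@sdGrid[idx$rows, idx$cols, drop = FALSE]
  tot <- sqrt(sg^2 + s^2)
  ## log-likelihood, shifted before exponentiation for numerical safety
  ll <- stats::dnorm(m, mean = mu, sd = tot, log = TRUE)
  valid <- !is.na(ll)
  if (!any(valid)) stop("no valid isoscape cells inside the assignment box")
  shift <- max(ll[valid])
  lik <- exp(ll - shift)
  lik[!valid] <- NA
  post <- lik / sum(lik[valid])
  newOrigin <- c(isoscape@origin[1] + (min(idx$cols) - 1) * isoscape@cellSize,
                 isoscape@origin[2] + (min(idx$rows) - 1) * isoscape@cellSize)
  mask <- topAreaMask(post, fraction)
  methods::new("AssignmentSurface", posterior = post, topMask = mask,
    cellSize = isoscape@cellSize, origin = newOrigin, scaleKm = scaleKm,
    sampleRef = list(m = m, s = s,
                     distance = feature$distance %||% NA_real_,
                     label = feature$label %||% NA_character_,
                     center = center, fraction = fraction))
}

## mask of the `fraction` of valid cells with the highest posterior;
## ties broken by cell (column-major) index order
topAreaMask <- function(posterior, fraction) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  p <- as.vector(posterior)
  valid <- which(!is.na(p))
  nTop <- ceiling(fraction * length(valid))
  ord <- valid[order(-p[valid], valid)]
  mask <- rep(NA, length(p))
  mask[valid] <- FALSE
  mask[ord[seq_len(nTop)]] <- TRUE
  matrix(mask, nrow(posterior), ncol(posterior))
}

#' Top probability area of an assignment surface
#'
#' Ranks valid cells by posterior (descending, ties broken by fixed
#' column-major cell index) and masks the smallest prefix reaching
#' `fraction` of the valid-cell count — an area threshold, not a
#' cumulative-probability threshold.
#'
#' @param surface An [AssignmentSurface-class] (or a posterior matrix).
#' @param fraction Fraction of valid cells to keep, in (0, 1); default
#'   0.10.
#' @return Logical matrix mask (NA outside valid cells); for an
#'   `AssignmentSurface` input, a copy of the surface with the mask
#'   replaced.
#' @export
topArea <- function(surface, fraction = 0.10) {
  if (methods::is(surface, "AssignmentSurface")) {
    surface@topMask <- topAreaMask(surface@posterior, fraction)
    surface@sampleRef$fraction <- fraction
    return(surface)
  }
  topAreaMask(surface, fraction)
}

#' Nested-scale assignment around a site
#'
#' Runs [posteriorSurface()] for the same feature in square boxes of
#' several side lengths centred on a site (the local, intermediate and
#' regional reading scales; defaults 100, 200 and 400 km). Scales whose
#' box misses the isoscape entirely are skipped with a warning.
#'
#' @param feature One-row feature (see [profileFeatures()]).
#' @param isoscape An [SrIsoscape-class].
#' @param siteXY (x, y) of the site (m); must be inside the isoscape.
#' @param scalesKm Box sides in km (default `c(100, 200, 400)`).
#' @param fraction Top-area fraction (default 0.10).
#' @return Named list of [AssignmentSurface-class], one per realized
#'   scale.
#' @export
nestedAssignment <- function(feature, isoscape, siteXY,
                             scalesKm = c(100, 200, 400),
                             fraction = 0.10) {
  inside <- cellIndex(isoscape, siteXY[1], siteXY[2])$inside
  if (!inside) stop("site lies outside the isoscape extent")
  out <- list()
  for (sc in scalesKm) {
    surf <- tryCatch(
      posteriorSurface(feature, isoscape, siteXY, sc, fraction),
      error = function(e) {
        warning(sprintf("scale %.0f km skipped: %s", sc, conditionMessage(e)))
        NULL
      })
    if (!is.null(surf)) out[[sprintf("%.0fkm", sc)]] <- surf
  }
  out
}

#' Classify an individual as local or non-local
#'
#' Envelope rule: the isoscape cells within `radiusKm` of the site define
#' a local range `[min(mu - 2 sigma), max(mu + 2 sigma)]`; an individual
#' is called non-local when any of its profile features falls outside
#' that envelope, otherwise local. This operationalizes the map-reading
#' practice of flagging values never seen near the site; the rationale
#' lists the offending features.
#'
#' @param features data.frame of features (see [profileFeatures()]),
#'   possibly pooled over teeth of one individual.
#' @param isoscape An [SrIsoscape-class].
#' @param siteXY (x, y) of the site (m).
#' @param radiusKm Radius defining "local" (default 50).
#' @param envelopeSd Multiplier on the cell SD (default 2).
#' @return List: `status` ("local"/"non-local"), `envelope` (length-2),
#'   `offending` (data.frame of out-of-envelope features) and `rationale`
#'   (character).
#' @export
classifyLocal <- function(features, isoscape, siteXY, radiusKm = 50,
                          envelopeSd = 2) {
  stopifnot(nrow(features) >= 1)
  dm <- gridDim(isoscape)
  ctr <- cellCenter(isoscape, matrix(rep(seq_len(dm[1]), dm[2]), dm[1]),
                    matrix(rep(seq_len(dm[2]), each = dm[1]), dm[1]))
  dist2 <- (ctr$x - siteXY[1])^2 + (ctr$y - siteXY[2])^2
  near <- dist2 <= (radiusKm * 1000)^2 & !is.na(isoscape@meanGrid)
  if (!any(near))
    stop(sprintf("no valid isoscape cells within %.0f km of the site",
                 radiusKm))
  lo <- min(isoscape@meanGrid[near] - envelopeSd * isoscape@sdGrid[near])
  hi <- max(isoscape@meanGrid[near] + envelopeSd * isoscape@sdGrid[near])
  out <- features$m < lo | features$m > hi
  offending <- features[out, , drop = FALSE]
  status <- if (any(out)) "non-local" else "local"
  rationale <- if (any(out)) {
    sprintf(paste0("%d feature(s) outside the local %.0f-km envelope ",
                   "[%.4f, %.4f]: %s"),
            nrow(offending), radiusKm, lo, hi,
            paste(sprintf("%.4f", offending$m), collapse = ", "))
  } else {
    sprintf("all %d feature(s) within the local %.0f-km envelope [%.4f, %.4f]",
            nrow(features), radiusKm, lo, hi)
  }
  list(status = status, envelope = c(lo, hi), offending = offending,
       rationale = rationale)
}
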