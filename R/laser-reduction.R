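#' @include AllClasses.R
NULL

#' Natural-abundance ratios used for interference stripping
#'
#' Configuration constants for the isobaric corrections: the 87Rb/85Rb
#' abundance ratio used to strip 87Rb from mass 87 via the interference-
#' free 85Rb beam, and the 86Kr/83Kr and 84Kr/83Kr ratios used to strip
#' plasma-gas krypton from masses 86 and 84 via 83Kr. Values are the
#' standard terrestrial abundances (Rb: 27.83/72.17; Kr: 11.500, 56.987,
#' 17.279 at masses 83, 84, 86).
#'
#' @param rb87_85 87Rb/85Rb (default 0.2783 / 0.7217).
#' @param kr86_83 86Kr/83Kr (default 17.279 / 11.500).
#' @param kr84_83 84Kr/83Kr (default 56.987 / 11.500).
#' @return Named list of the three ratios.
#' @export
naturalRatios <- function(rb87_85 = 0.2783 / 0.7217,
                          kr86_83 = 17.279 / 11.500,
                          kr84_83 = 56.987 / 11.500) {
  list(rb87_85 = rb87_85, kr86_83 = kr86_83, kr84_83 = kr84_83)
}

#' Strip Rb and Kr isobaric interferences from a laser transect
#'
#' Per point: the mass-87 beam is reduced by the 87Rb contribution
#' inferred from 85Rb (`I87 - I85 * rb87_85`), and the mass-86 and
#' mass-84 beams by the Kr contributions inferred from 83Kr. The raw
#' ratio is corrected87 / corrected86. Points whose corrected 86 beam is
#' non-positive are flagged invalid and must be excluded downstream.
#'
#' @param transect A [LaserTransect-class].
#' @param ratios Abundance constants from [naturalRatios()].
#' @return data.frame(position, ratio, valid); `ratio` is NA where
#'   invalid.
#' @export
correctInterferences <- function(transect, ratios = naturalRatios()) {
  stopifnot(methods::is(transect, "LaserTransect"))
  I <- transect@intensity
  i87 <- I[, "87"] - I[, "85"] * ratios$rb87_85
  i86 <- I[, "86"] - I[, "83"] * ratios$kr86_83
  valid <- is.finite(i86) & i86 > 0
  ratio <- ifelse(valid, i87 / i86, NA_real_)
  if (any(!valid))
    warning(sum(!valid), " point(s) with non-positive corrected 86 beam ",
            "flagged invalid")
  data.frame(position = transect@position, ratio = ratio, valid = valid)
}

#' Standard-sample-standard bracketing normalization
#'
#' Corrects raw 87Sr/86Sr values against interleaved measurements of a
#' certified standard. Each standard measurement yields a correction
#' factor `certified / measured`; the factor applied at a sample point is
#' the position-weighted linear interpolation of the factors of the
#' preceding and following bracketing standards (so a sample midway
#' between brackets gets the average of the two factors). Points outside
#' the flanked range fall back to the nearest standard, with a warning.
#'
#' @param rawRatios data.frame(position, ratio) (e.g. the output of
#'   [correctInterferences()]; invalid NA points pass through as NA).
#' @param standards data.frame(position, ratio) of standard measurements.
#' @param certifiedValue Certified ratio of the standard (default the
#'   TIMS value for sintered NIST SRM-1400 bone ash, 0.71308).
#' @return data.frame(position, ratio, factor) with corrected ratios.
#' @export
bracketNormalize <- function(rawRatios, standards,
                             certifiedValue = 0.71308) {
  stopifnot(all(c("position", "ratio") %in% names(rawRatios)),
            all(c("position", "ratio") %in% names(standards)))
  if (nrow(standards) < 2L)
    stop("at least 2 bracketing standards required")
  std <- standards[order(standards$position), ]
  pos <- rawRatios$position
  outside <- pos < min(std$position) | pos > max(std$position)
  if (any(outside))
    warning(sum(outside), " point(s) not flanked by standards; ",
            "nearest-standard fallback applied")
  fStd <- certifiedValue / std$ratio
  factor <- stats::approx(std$position, fStd, xout = pos, rule = 2)$y
  data.frame(position = pos, ratio = rawRatios$ratio * factor,
             factor = factor)
}
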