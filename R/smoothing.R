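#' @include AllClasses.R
NULL

## centered rolling mean / SD with truncated (shrinking) windows at the
## edges; half = (window - 1) / 2 with window forced odd
rollingStats <- function(x, windowN) {
  n <- length(x)
  if (n == 0L) stop("empty series")
  if (windowN %% 2 == 0) windowN <- windowN + 1L
  half <- (windowN - 1L) %/% 2L
  ## shift by x[1] so constant series come out exact (no cancellation)
  xc <- x - x[1]
  cs <- c(0, cumsum(xc))
  cs2 <- c(0, cumsum(xc^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  k <- hi - lo + 1L
  mc <- (cs[hi + 1L] - cs[lo]) / k
  ss <- cs2[hi + 1L] - cs2[lo] - k * mc^2
  s <- sqrt(pmax(ss, 0) / pmax(k - 1L, 1L))
  s[k < 2L] <- 0
  list(mean = mc + x[1], sd = s, n = k)
}

#' Rolling-window smoothing of an isotope profile
#'
#' Centered moving average and moving SD over `windowN` consecutive
#' measurements (default 35, roughly 2 mm of a laser transect), the
#' standard reduction applied to laser-ablation Sr profiles before
#' feature picking and assignment. Windows are truncated (shrunk) at the
#' profile ends rather than dropping edge points, so the output stays
#' aligned with the input positions; the rolling SD mirrors the mean's
#' truncation.
#'
#' @param profile An [IsotopeProfile-class].
#' @param windowN Window length in samples; forced odd (default 35).
#' @return An [IsotopeProfile-class] with smoothed values and the rolling
#'   SD in the `sd` slot; `metadata$windowN` records the window.
#' @export
#' @examples
#' p <- IsotopeProfile("demo", "Sr", 0:99, 0:99)
#' s <- rollingSmooth(p, 35)
#' values(s)[51]  # symmetric window on a linear ramp: equals the input
rollingSmooth <- function(profile, windowN = 35) {
  stopifnot(methods::is(profile, "IsotopeProfile"))
  if (length(profile@value) < 2L) stop("profile too short to smooth")
  st <- rollingStats(profile@value, windowN)
  IsotopeProfile(profile@toothId, profile@isotope, profile@distance,
    st$mean, sd = st$sd,
    metadata = c(profile@metadata,
                 list(windowN = if (windowN %% 2 == 0) windowN + 1L
                                else as.integer(windowN),
                      smoothed = TRUE)))
}
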