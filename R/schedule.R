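#' @include AllClasses.R
NULL

#' Build a cyclical seasonal movement schedule
#'
#' Constructs the camp-rotation regime of mobile pastoralism: a fixed set
#' of camps visited in a repeating annual cycle, `switchesPerYear` moves
#' per year (four to five is typical of mountain nomadism, alternating
#' low-elevation winter camps and high summer pastures). Spells are equal
#' length; the cycle repeats for `nYears`.
#'
#' @param camps Matrix/data.frame with columns `x`, `y`, `elevation`; the
#'   visit order is row order, recycled.
#' @param nYears Number of simulated years.
#' @param switchesPerYear Camp changes per year (default 4).
#' @param yearLength Days per year (365).
#' @param startDay Day the schedule starts (default 0).
#' @return A [MovementSchedule-class].
#' @export
#' @examples
#' camps <- data.frame(x = c(5e3, 2.5e4), y = c(5e3, 5e3),
#'                     elevation = c(1900, 2500))
#' makeSeasonalSchedule(camps, nYears = 3)
makeSeasonalSchedule <- function(camps, nYears, switchesPerYear = 4,
                                 yearLength = 365, startDay = 0) {
  camps <- as.matrix(as.data.frame(camps)[, c("x", "y", "elevation")])
  nSpells <- as.integer(ceiling(nYears * switchesPerYear))
  spell <- yearLength / switchesPerYear
  start <- startDay + (seq_len(nSpells) - 1) * spell
  occupancy <- data.frame(
    camp = rep_len(seq_len(nrow(camps)), nSpells),
    start = start, end = start + spell)
  MovementSchedule(camps, occupancy, yearLength = yearLength)
}
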