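#' @include AllClasses.R
NULL

## Shared planar-grid arithmetic. Convention (documented on GriddedField):
## origin = lower-left corner of cell (1,1); rows index y, columns x;
## half-open cells: x in [x0 + (j-1)*d, x0 + j*d) -> column j.

## evaluate expr under set.seed(seed), restoring the caller's RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

cellIndex <- function(grid, x, y) {
  d <- grid@cellSize
  j <- floor((x - grid@origin[1]) / d) + 1L
  i <- floor((y - grid@origin[2]) / d) + 1L
  dm <- gridDim(grid)
  inside <- i >= 1L & i <= dm[1] & j >= 1L & j <= dm[2]
  list(row = as.integer(i), col = as.integer(j), inside = inside)
}

cellCenter <- function(grid, row, col) {
  d <- grid@cellSize
  list(x = grid@origin[1] + (col - 0.5) * d,
       y = grid@origin[2] + (row - 0.5) * d)
}

## row/col index ranges of a square box (side in metres) centred on (cx, cy),
## clipped to the grid; NULL when the box misses the grid entirely
boxIndices <- function(grid, cx, cy, side) {
  d <- grid@cellSize
  dm <- gridDim(grid)
  half <- side / 2
  j1 <- floor((cx - half - grid@origin[1]) / d) + 1L
  j2 <- ceiling((cx + half - grid@origin[1]) / d)
  i1 <- floor((cy - half - grid@origin[2]) / d) + 1L
  i2 <- ceiling((cy + half - grid@origin[2]) / d)
  i1 <- max(1L, i1); j1 <- max(1L, j1)
  i2 <- min(dm[1], i2); j2 <- min(dm[2], j2)
  if (i1 > i2 || j1 > j2) return(NULL)
  list(rows = i1:i2, cols = j1:j2)
}

## value of a grid matrix at planar points, NA outside
lookupCells <- function(grid, mat, x, y) {
  idx <- cellIndex(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- idx$inside
  out[ok] <- mat[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Create an SrIsoscape from grids
#'
#' Low-level constructor pairing a mean and an SD grid with planar
#' georeferencing.
#'
#' @param meanGrid,sdGrid Numeric matrices of identical shape; `sdGrid > 0`.
#' @param cellSize Cell edge (m). @param origin (x, y) lower-left corner.
#' @param metadata Optional provenance list.
#' @return An [SrIsoscape-class] object.
#' @export
SrIsoscape <- function(meanGrid, sdGrid, cellSize, origin = c(0, 0),
                       metadata = list()) {
  methods::new("SrIsoscape", meanGrid = meanGrid, sdGrid = sdGrid,
    cellSize = cellSize, origin = origin, metadata = metadata)
}

#' Look up isoscape values at planar points
#'
#' Nearest-cell (containing-cell) lookup of the mean and SD grids; no
#' interpolation, the raster is the resolution authority.
#'
#' @param isoscape An [SrIsoscape-class].
#' @param x,y Point coordinates (m).
#' @return data.frame(x, y, mean, sd) with NA outside the extent.
#' @export
lookupIsoscape <- function(isoscape, x, y) {
  data.frame(x = x, y = y,
             mean = lookupCells(isoscape, isoscape@meanGrid, x, y),
             sd = lookupCells(isoscape, isoscape@sdGrid, x, y))
}
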