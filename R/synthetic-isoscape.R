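#' @include grid-utils.R
NULL

## bilinear upsampling of a coarse matrix onto an nr x nc grid
upsampleBilinear <- function(coarse, nr, nc) {
  kr <- nrow(coarse); kc <- ncol(coarse)
  if (kr == 1L && kc == 1L) return(matrix(coarse[1, 1], nr, nc))
  ry <- if (kr == 1L) rep(1, nr) else seq(1, kr, length.out = nr)
  rx <- if (kc == 1L) rep(1, nc) else seq(1, kc, length.out = nc)
  i0 <- pmin(floor(ry), kr - 1L); fi <- ry - i0
  j0 <- pmin(floor(rx), kc - 1L); fj <- rx - j0
  if (kr == 1L) { i0 <- rep(1L, nr); fi <- rep(0, nr) }
  if (kc == 1L) { j0 <- rep(1L, nc); fj <- rep(0, nc) }
  a <- coarse[i0, j0, drop = FALSE]
  b <- coarse[pmin(i0 + 1L, kr), j0, drop = FALSE]
  cc <- coarse[i0, pmin(j0 + 1L, kc), drop = FALSE]
  d <- coarse[pmin(i0 + 1L, kr), pmin(j0 + 1L, kc), drop = FALSE]
  FI <- matrix(fi, nr, nc); FJ <- matrix(fj, nr, nc, byrow = TRUE)
  a * (1 - FI) * (1 - FJ) + b * FI * (1 - FJ) + cc * (1 - FI) * FJ + d * FI * FJ
}

## grow one connected patch of target size by randomized breadth-first search
growPatch <- function(nr, nc, size) {
  start <- c(sample.int(nr, 1), sample.int(nc, 1))
  member <- matrix(FALSE, nr, nc)
  member[start[1], start[2]] <- TRUE
  frontier <- list(start)
  count <- 1L
  while (count < size && length(frontier) > 0) {
    pick <- sample.int(length(frontier), 1)
    cell <- frontier[[pick]]
    nbrs <- rbind(cell + c(1, 0), cell + c(-1, 0),
                  cell + c(0, 1), cell + c(0, -1))
    ok <- nbrs[, 1] >= 1 & nbrs[, 1] <= nr & nbrs[, 2] >= 1 & nbrs[, 2] <= nc
    nbrs <- nbrs[ok, , drop = FALSE]
    added <- FALSE
    if (nrow(nbrs) > 0) {
      for (k in sample.int(nrow(nbrs))) {
        if (!member[nbrs[k, 1], nbrs[k, 2]]) {
          member[nbrs[k, 1], nbrs[k, 2]] <- TRUE
          frontier[[length(frontier) + 1L]] <- nbrs[k, ]
          count <- count + 1L
          added <- TRUE
          break
        }
      }
    }
    if (!added) frontier[[pick]] <- NULL
  }
  member
}

#' Generate a synthetic bioavailable strontium isoscape
#'
#' Builds a patchy 87Sr/86Sr field of the kind real lithology produces: a
#' smooth regional background with discrete, connected lithological patches
#' of distinct ratio superimposed, plus a per-cell SD layer. All values are
#' clamped to `ratioRange`. Pure function of `seed`.
#'
#' @param shape Integer (nrow, ncol), each >= 8.
#' @param nPatches Number of lithological patches (>= 0).
#' @param backgroundSmoothness Number of coarse knots per axis controlling
#'   the correlation length of the background (smaller = smoother);
#'   default 4.
#' @param ratioRange Admissible ratio range, default `c(0.702, 0.725)`
#'   (generously spanning ratios observed in continental settings).
#' @param sdLevel Central per-cell SD of the uncertainty layer (> 0);
#'   default 0.001.
#' @param seed Integer seed.
#' @param backgroundRatio Background level; default the midpoint of
#'   `ratioRange`.
#' @param backgroundAmplitude SD of the smooth background fluctuation; 0
#'   gives a constant background. Default 15% of the range span.
#' @param cellSize Cell edge in metres (default 1000).
#' @param origin Lower-left corner (m), default `c(0, 0)`.
#' @return An [SrIsoscape-class]; `metadata$patchRatios` records the
#'   ground-truth patch means, `metadata$patchMask` the patch id per cell
#'   (0 = background).
#' @export
#' @examples
#' iso <- makeIsoscape(c(20, 20), nPatches = 2, seed = 1)
#' range(meanGrid(iso))
makeIsoscape <- function(shape, nPatches = 3, backgroundSmoothness = 4,
                         ratioRange = c(0.702, 0.725), sdLevel = 0.001,
                         seed = 1L, backgroundRatio = mean(ratioRange),
                         backgroundAmplitude = 0.15 * diff(ratioRange),
                         cellSize = 1000, origin = c(0, 0)) {
  if (any(shape < 8)) stop("shape must be at least (8, 8)")
  if (nPatches < 0) stop("nPatches must be >= 0")
  if (sdLevel <= 0) stop("sdLevel must be > 0")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  withSeed(seed, {

  if (backgroundAmplitude > 0) {
    k <- max(2L, as.integer(backgroundSmoothness))
    coarse <- matrix(stats::rnorm(k * k), k, k)
    bg <- upsampleBilinear(coarse, nr, nc)
    bg <- (bg - mean(bg)) / max(stats::sd(as.vector(bg)), 1e-12)
    mean_grid <- backgroundRatio + backgroundAmplitude * bg
  } else {
    mean_grid <- matrix(backgroundRatio, nr, nc)
  }

  patch_mask <- matrix(0L, nr, nc)
  patch_ratios <- numeric(0)
  if (nPatches > 0) {
    target <- max(4L, round(0.08 * nr * nc))
    for (p in seq_len(nPatches)) {
      member <- growPatch(nr, nc, target)
      ratio <- stats::runif(1, ratioRange[1], ratioRange[2])
      mean_grid[member] <- ratio
      patch_mask[member] <- p
      patch_ratios <- c(patch_ratios, ratio)
    }
  }
  mean_grid <- pmin(pmax(mean_grid, ratioRange[1]), ratioRange[2])

  sd_grid <- matrix(sdLevel * stats::runif(nr * nc, 0.8, 1.2), nr, nc)

  SrIsoscape(mean_grid, sd_grid, cellSize = cellSize, origin = origin,
    metadata = list(seed = seed, patchRatios = patch_ratios,
                    patchMask = patch_mask, ratioRange = ratioRange))
  })
}
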