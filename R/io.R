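#' @include grid-utils.R assignment.R
NULL

#' Read and write intra-tooth profiles as CSV
#'
#' Column dialect: `distance_mm_from_ERJ`, `value`, `sd` (optional),
#' plus `tooth_id` and `isotope` carried in columns so several profiles
#' can share a file. Ratios are written at full precision, delta values
#' in permil V-PDB.
#'
#' @param profile An [IsotopeProfile-class] (or list of them) to write.
#' @param path File path.
#' @return `readProfiles()` returns a named list of
#'   [IsotopeProfile-class]; `writeProfiles()` returns `path`
#'   invisibly.
#' @export
writeProfiles <- function(profile, path) {
  if (methods::is(profile, "IsotopeProfile")) profile <- list(profile)
  rows <- lapply(profile, function(p)
    data.frame(tooth_id = p@toothId, isotope = p@isotope,
               distance_mm_from_ERJ = p@distance, value = p@value,
               sd = p@sd))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path) {
  dat <- utils::read.csv(path)
  need <- c("tooth_id", "isotope", "distance_mm_from_ERJ", "value")
  if (!all(need %in% names(dat)))
    stop("profile CSV needs columns: ", paste(need, collapse = ", "))
  if (!"sd" %in% names(dat)) dat$sd <- NA_real_
  keys <- unique(dat[, c("tooth_id", "isotope")])
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- dat[dat$tooth_id == keys$tooth_id[k] &
               dat$isotope == keys$isotope[k], ]
    sub <- sub[order(sub$distance_mm_from_ERJ), ]
    IsotopeProfile(keys$tooth_id[k], keys$isotope[k],
                   sub$distance_mm_from_ERJ, sub$value, sub$sd)
  })
  stats::setNames(out, paste(keys$tooth_id, keys$isotope, sep = "."))
}

#' Write and read grids as ESRI ASCII rasters
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header then rows north to south); the
#' package's on-disk form for isoscape and posterior grids.
#'
#' @param mat Numeric matrix (rows = south to north, the package's
#'   in-memory convention).
#' @param path File path. @param cellSize Cell edge (m).
#' @param origin Lower-left corner.
#' @param nodata NODATA sentinel (default -9999).
#' @return `readAsciiGrid()` returns list(mat, cellSize, origin);
#'   writers return `path` invisibly.
#' @export
writeAsciiGrid <- function(mat, path, cellSize, origin = c(0, 0),
                           nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(mat)), sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.6f", origin[1]),
    sprintf("yllcorner %.6f", origin[2]),
    sprintf("cellsize %.6f", cellSize),
    sprintf("NODATA_value %s", format(nodata))), con)
  m <- mat[rev(seq_len(nrow(mat))), , drop = FALSE] # file runs N -> S
  m[is.na(m)] <- nodata
  utils::write.table(format(m, digits = 12, trim = TRUE, scientific = FALSE),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                          tolower(vapply(kv, `[`, character(1), 1)))
  dat <- as.matrix(utils::read.table(path, skip = 6))
  mat <- dat[rev(seq_len(nrow(dat))), , drop = FALSE] # back to S -> N rows
  mat[mat == vals[["nodata_value"]]] <- NA
  dimnames(mat) <- NULL
  list(mat = mat, cellSize = vals[["cellsize"]],
       origin = c(vals[["xllcorner"]], vals[["yllcorner"]]))
}

#' Write an isoscape as a pair of ASCII rasters
#'
#' @param isoscape An [SrIsoscape-class].
#' @param basePath Path stem; `<stem>_mean.asc` and `<stem>_sd.asc` are
#'   written.
#' @return The two paths, invisibly.
#' @export
writeIsoscape <- function(isoscape, basePath) {
  pm <- paste0(basePath, "_mean.asc")
  ps <- paste0(basePath, "_sd.asc")
  writeAsciiGrid(isoscape@meanGrid, pm, isoscape@cellSize, isoscape@origin)
  writeAsciiGrid(isoscape@sdGrid, ps, isoscape@cellSize, isoscape@origin)
  invisible(c(pm, ps))
}

#' Read an isoscape from a pair of ASCII rasters
#'
#' @param basePath Path stem as in [writeIsoscape()].
#' @return An [SrIsoscape-class].
#' @export
readIsoscape <- function(basePath) {
  m <- readAsciiGrid(paste0(basePath, "_mean.asc"))
  s <- readAsciiGrid(paste0(basePath, "_sd.asc"))
  SrIsoscape(m$mat, s$mat, cellSize = m$cellSize, origin = m$origin)
}

#' Write a top-area mask as GeoJSON
#'
#' Each masked cell becomes one square polygon feature (planar
#' coordinates); consumers can dissolve downstream.
#'
#' @param surface An [AssignmentSurface-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMaskGeoJSON <- function(surface, path) {
  mask <- surface@topMask
  idx <- which(!is.na(mask) & mask, arr.ind = TRUE)
  d <- surface@cellSize; o <- surface@origin
  features <- lapply(seq_len(nrow(idx)), function(k) {
    r <- idx[k, 1]; cl <- idx[k, 2]
    x0 <- o[1] + (cl - 1) * d; y0 <- o[2] + (r - 1) * d
    ring <- list(c(x0, y0), c(x0 + d, y0), c(x0 + d, y0 + d),
                 c(x0, y0 + d), c(x0, y0))
    list(type = "Feature",
         properties = list(posterior = surface@posterior[r, cl]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write movement schedules as structured text
#'
#' YAML with a `camps` table (x, y, elevation), an `occupancy` table
#' (camp, start, end) and `year_length`.
#'
#' @param schedule A [MovementSchedule-class].
#' @param path File path.
#' @return `readSchedule()` returns a [MovementSchedule-class]; the
#'   writer returns `path` invisibly.
#' @export
writeSchedule <- function(schedule, path) {
  yaml::write_yaml(list(
    year_length = schedule@yearLength,
    camps = apply(schedule@camps, 1, as.list),
    occupancy = lapply(seq_len(nrow(schedule@occupancy)), function(i)
      as.list(schedule@occupancy[i, ]))), path)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  y <- yaml::read_yaml(path)
  camps <- do.call(rbind, lapply(y$camps, function(cp)
    data.frame(x = cp$x, y = cp$y, elevation = cp$elevation)))
  occ <- do.call(rbind, lapply(y$occupancy, function(oc)
    data.frame(camp = oc$camp, start = oc$start, end = oc$end)))
  MovementSchedule(camps, occ, yearLength = y$year_length)
}

#' Read a GPS track from CSV
#'
#' Columns `time` (days), `x`, `y` (m) and optionally `elevation`.
#'
#' @param path File path.
#' @return A [Track-class].
#' @export
readTrack <- function(path) {
  dat <- utils::read.csv(path)
  need <- c("time", "x", "y")
  if (!all(need %in% names(dat)))
    stop("track CSV needs columns: ", paste(need, collapse = ", "))
  Track(dat$time, dat$x, dat$y,
        if ("elevation" %in% names(dat)) dat$elevation else numeric(0))
}
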