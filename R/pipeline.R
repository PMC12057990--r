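#' @include io.R isoscape-fit.R elevation.R segmentation.R phase-model.R forward-model.R
NULL

#' Validate a pipeline run configuration
#'
#' Checks the structured config before any compute: every referenced
#' path must exist, a data source (either a `simulate` block or a
#' `profiles` path plus `isoscape` stem) must be present, and all seeds
#' must be explicit integers.
#'
#' @param config List (parsed config) or path to a YAML file.
#' @return The validated config list, invisibly on success; error
#'   otherwise.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed) || config$seed != as.integer(config$seed))
    stop("config must carry an explicit integer seed")
  hasSim <- !is.null(config$simulate)
  hasData <- !is.null(config$profiles) && !is.null(config$isoscape)
  if (!hasSim && !hasData)
    stop("config needs either a 'simulate' block or 'profiles' + 'isoscape'")
  for (p in c(config$profiles, config$curve, config$tracks)) {
    if (!is.null(p) && !file.exists(p)) stop("referenced path missing: ", p)
  }
  if (!hasSim) {
    for (suffix in c("_mean.asc", "_sd.asc"))
      if (!file.exists(paste0(config$isoscape, suffix)))
        stop("referenced path missing: ", paste0(config$isoscape, suffix))
  }
  invisible(config)
}

#' Run the full mobility-reconstruction pipeline
#'
#' Orchestrates the stages end to end from one structured config:
#' (1) obtain inputs — either generate the synthetic study system
#' (isoscape, schedule, environmental series, tooth profiles,
#' radiocarbon dataset) or load profiles/isoscape/curve from the
#' configured paths; (2) reduce profiles (rolling smoothing of Sr);
#' (3) pick features and run nested-scale geographic assignment and the
#' local/non-local call; (4) fit the seasonal anchor, invert d13C to
#' elevation, count relocations; (5) calibrate dates and fit the
#' single-phase model. Deterministic given the config seeds. Writes
#' tables, rasters and a `summary.json` into the run directory; on a
#' stage failure partial outputs are preserved and the error is
#' re-thrown after being logged.
#'
#' @param config List or YAML path (see [validateConfig()]).
#' @param outDir Run directory (default `config$out`, or a tempdir).
#' @return Invisibly, the summary list (also written as JSON).
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- validateConfig(config)
  outDir <- outDir %||% config$out %||% file.path(tempdir(), "isomob_run")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "pipeline.log")
  logMsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", file = logFile, append = TRUE, sep = "")
    message(line)
  }
  seed <- as.integer(config$seed)
  prm <- config$params %||% list()
  windowN <- prm$windowN %||% 35
  fraction <- prm$fraction %||% 0.10
  scalesKm <- unlist(prm$scalesKm %||% c(100, 200, 400))
  prominence <- prm$prominence %||% 5e-4
  nMcmc <- prm$nMcmc %||% 5000

  summary <- list(seed = seed)
  stage <- function(name, expr) {
    logMsg("stage %s", name)
    tryCatch(expr, error = function(e) {
      logMsg("stage %s FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- inputs ----
  profiles <- NULL; isoscape <- NULL; curve <- NULL; dates <- NULL
  site <- unlist(config$site %||% c(NA, NA))
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    stage("simulate", {
      isoArgs <- sim$isoscape %||% list()
      isoscape <- makeIsoscape(
        shape = unlist(isoArgs$shape %||% c(40, 40)),
        nPatches = isoArgs$nPatches %||% 3,
        sdLevel = isoArgs$sdLevel %||% 0.001,
        cellSize = isoArgs$cellSize %||% 1000,
        ratioRange = unlist(isoArgs$ratioRange %||% c(0.705, 0.718)),
        seed = seed)
      schArgs <- sim$schedule %||% list()
      camps <- if (!is.null(schArgs$camps))
        do.call(rbind, lapply(schArgs$camps, as.data.frame))
      else defaultCamps(isoscape)
      schedule <- makeSeasonalSchedule(camps,
        nYears = schArgs$nYears %||% 4,
        switchesPerYear = schArgs$switchesPerYear %||% 4)
      env <- simulateEnvironment(schedule, isoscape)
      toothArgs <- sim$tooth %||% list()
      timing <- ToothTiming(toothArgs$label %||% "M2")
      noise <- unlist(toothArgs$noiseSd %||%
                        c(Sr = 5e-4, d18O = 0.3, d13C = 0.1))
      profs <- recordTooth(env, timing,
        maturationWindowDays = toothArgs$maturationWindowDays %||% 45,
        nSamples = toothArgs$nSamples %||% 1000,
        noiseSd = noise, seed = seed + 1L)
      profiles <- profs
      if (is.na(site[1])) {
        ctr <- cellCenter(isoscape, gridDim(isoscape)[1] %/% 2,
                          gridDim(isoscape)[2] %/% 2)
        site <- c(ctr$x, ctr$y)
      }
      rcArgs <- sim$radiocarbon %||% list()
      curve <- syntheticCalCurve(
        unlist(rcArgs$curveRange %||% c(2500, 3500)))
      dates <- makeRadiocarbonDataset(
        rcArgs$start %||% 3000, rcArgs$end %||% 2950,
        rcArgs$nDates %||% 8, curve,
        labErrors = rcArgs$labError %||% 25, seed = seed + 2L)
      writeIsoscape(isoscape, file.path(outDir, "isoscape"))
      writeSchedule(schedule, file.path(outDir, "schedule.yml"))
      utils::write.csv(as.data.frame(env),
                       file.path(outDir, "environment.csv"),
                       row.names = FALSE)
      writeProfiles(profs, file.path(outDir, "profiles.csv"))
      utils::write.csv(dates, file.path(outDir, "radiocarbon.csv"),
                       row.names = FALSE)
    })
  } else {
    stage("load", {
      profiles <- readProfiles(config$profiles)
      isoscape <- readIsoscape(config$isoscape)
      if (!is.null(config$curve)) curve <- readCalCurve(config$curve)
      if (!is.null(config$dates))
        dates <- utils::read.csv(config$dates)
    })
  }

  ## ---- profile reduction ----
  srRaw <- profiles[[which(vapply(profiles, isotope, character(1)) == "Sr")[1]]]
  srSmooth <- stage("process-profiles", rollingSmooth(srRaw, windowN))
  writeProfiles(srSmooth, file.path(outDir, "sr_smoothed.csv"))

  ## ---- assignment ----
  assign_res <- stage("assign", {
    feats <- profileFeatures(srSmooth, prominence = prominence)
    surfaces <- nestedAssignment(feats[1, ], isoscape, site,
                                 scalesKm = scalesKm, fraction = fraction)
    for (nm in names(surfaces)) {
      writeAsciiGrid(surfaces[[nm]]@posterior,
        file.path(outDir, paste0("posterior_", nm, ".asc")),
        surfaces[[nm]]@cellSize, surfaces[[nm]]@origin)
      writeMaskGeoJSON(surfaces[[nm]],
        file.path(outDir, paste0("topmask_", nm, ".geojson")))
    }
    cls <- classifyLocal(feats, isoscape, site)
    list(features = feats, surfaces = surfaces, classification = cls)
  })
  summary$classification <- assign_res$classification$status
  summary$classificationRationale <- assign_res$classification$rationale

  ## ---- seasonality, elevation, relocations ----
  season_res <- stage("seasonality", {
    d18Oidx <- which(vapply(profiles, isotope, character(1)) == "d18O")
    d13Cidx <- which(vapply(profiles, isotope, character(1)) == "d13C")
    anchor <- if (length(d18Oidx)) fitSeasonalAnchor(profiles[[d18Oidx[1]]])
              else NULL
    elev <- if (length(d13Cidx))
      enamelToElevation(values(profiles[[d13Cidx[1]]]),
                        isArchaeological = FALSE, nMc = 2000,
                        seed = seed + 3L)
      else NULL
    rel <- countRelocations(srSmooth, anchor, penalty = prm$penalty)
    if (!is.null(elev))
      utils::write.csv(elev, file.path(outDir, "elevation.csv"),
                       row.names = FALSE)
    utils::write.csv(rel$segments, file.path(outDir, "segments.csv"),
                     row.names = FALSE)
    list(anchor = anchor, elevation = elev, relocations = rel)
  })
  summary$relocationsPerYear <- season_res$relocations$ratePerYear
  summary$nRelocations <- season_res$relocations$nRelocations
  if (!is.null(season_res$elevation))
    summary$elevation <- list(
      mean = mean(season_res$elevation$elevation),
      amplitude = diff(range(season_res$elevation$elevation)))
  if (!is.null(season_res$anchor) && !isDegenerate(season_res$anchor))
    summary$d18OAmplitudeFitted <- 2 * season_res$anchor@amplitude

  ## ---- chronology ----
  if (!is.null(dates) && !is.null(curve)) {
    chron <- stage("c14", {
      keep <- dates
      if (any(c("c_to_n", "collagen_yield") %in% names(dates)))
        keep <- qcFilter(dates)$retained
      pm <- phaseModel(keep, curve, nMcmc = nMcmc, seed = seed + 4L)
      utils::write.csv(phaseSummary(pm), file.path(outDir, "phase.csv"),
                       row.names = FALSE)
      pm
    })
    ps <- phaseSummary(chron)
    summary$phase <- list(
      startMedianCalBP = ps$median[ps$parameter == "start"],
      endMedianCalBP = ps$median[ps$parameter == "end"],
      spanMedianYears = ps$median[ps$parameter == "span"])
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logMsg("pipeline complete")
  invisible(summary)
}

## two camps straddling distinct isoscape zones (the most contrasting
## cells), used when the config does not specify camps
defaultCamps <- function(isoscape) {
  m <- meanGrid(isoscape)
  lo <- which(m == min(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  hi <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  a <- cellCenter(isoscape, lo[1], lo[2])
  b <- cellCenter(isoscape, hi[1], hi[2])
  data.frame(x = c(a$x, b$x), y = c(a$y, b$y), elevation = c(1900, 2500))
}
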