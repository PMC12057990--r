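#' @include grid-utils.R
NULL

#' Extract covariate values at sample sites
#'
#' Nearest-cell (containing-cell) lookup of every stack layer at each
#' sampling site; the rasters are the resolution authority, no
#' interpolation. Sites falling outside the extent or in a no-data cell
#' are dropped and the drop count reported via message and attribute.
#'
#' @param samples data.frame with columns `x`, `y` and the response
#'   column(s); typically also `ratio` (the site's bioavailable
#'   87Sr/86Sr) and `sample_kind`.
#' @param stack A [CovariateStack-class].
#' @return data.frame: the surviving sample rows with one appended column
#'   per layer; attribute `dropped` holds the number of dropped sites.
#' @export
extractCovariates <- function(samples, stack) {
  stopifnot(methods::is(stack, "CovariateStack"),
            all(c("x", "y") %in% names(samples)))
  feat <- vapply(stack@layers, function(m)
    lookupCells(stack, m, samples$x, samples$y),
    numeric(nrow(samples)))
  feat <- matrix(feat, nrow = nrow(samples),
                 dimnames = list(NULL, names(stack@layers)))
  keep <- stats::complete.cases(feat)
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message(nDropped, " site(s) outside the extent or in no-data cells ",
            "dropped")
  out <- cbind(samples[keep, , drop = FALSE],
               as.data.frame(feat[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "dropped") <- nDropped
  out
}

#' Drop highly correlated covariates
#'
#' Greedy pairwise filter: features are scanned in their given order and
#' a feature is dropped when its absolute Pearson correlation with an
#' earlier retained feature exceeds `threshold` (the later-listed member
#' of each offending pair goes). Constant features (undefined
#' correlation) are dropped with a warning. Order-stable.
#'
#' @param features data.frame/matrix of numeric features.
#' @param threshold Absolute-correlation cutoff (default 0.9).
#' @return The reduced data.frame; attribute `dropped` names the removed
#'   features.
#' @export
filterCorrelated <- function(features, threshold = 0.9) {
  features <- as.data.frame(features)
  if (ncol(features) < 2L) return(features)
  const <- vapply(features, function(v) stats::sd(v) == 0 || !any(is.finite(v)),
                  logical(1))
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(names(features)[const], collapse = ", "))
  }
  kept <- character(0)
  dropped <- names(features)[const]
  for (nm in names(features)[!const]) {
    r <- if (length(kept))
      suppressWarnings(abs(stats::cor(features[[nm]],
                                      features[, kept, drop = FALSE])))
      else numeric(0)
    if (length(r) && any(r > threshold, na.rm = TRUE))
      dropped <- c(dropped, nm)
    else kept <- c(kept, nm)
  }
  out <- features[, kept, drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Select relevant predictors by noise-thresholded permutation importance
#'
#' Single-stage variable selection: random forests with permutation
#' importance are fitted on the candidate features plus appended
#' pure-noise probe features, over several repetitions with fresh probe
#' draws; a candidate is retained when its importance exceeds the
#' largest probe importance in a majority of repetitions (a single
#' probe in a single forest is too easy to beat by chance) and its
#' mean importance clears a small fraction of the top feature's (probes
#' cannot flag a candidate's fixed in-sample spurious correlation; the
#' relative floor does). Deterministic for a fixed seed. If nothing
#' beats the noise, the single top feature is kept with a warning.
#'
#' @param features data.frame of candidate predictors.
#' @param response Numeric response (bioavailable 87Sr/86Sr).
#' @param seed Integer seed.
#' @param numTrees Trees per selection forest (default 500).
#' @param nNoise Noise probes per repetition (default 5).
#' @param reps Repetitions with fresh probes (default 7).
#' @param relFloor Minimum mean importance as a fraction of the top
#'   candidate's (default 0.01).
#' @return Character vector of retained predictor names, ranked by
#'   mean importance.
#' @export
selectVariables <- function(features, response, seed = 1L,
                            numTrees = 500, nNoise = 5, reps = 7,
                            relFloor = 0.01) {
  features <- as.data.frame(features)
  stopifnot(ncol(features) >= 1L, nrow(features) == length(response))
  withSeed(seed, {
    probes <- paste0("..noise", seq_len(nNoise))
    wins <- stats::setNames(integer(ncol(features)), names(features))
    impSum <- stats::setNames(numeric(ncol(features)), names(features))
    for (r in seq_len(reps)) {
      dat <- features
      for (pn in probes) dat[[pn]] <- stats::rnorm(nrow(dat))
      dat$..y <- response
      fit <- ranger::ranger(dependent.variable.name = "..y", data = dat,
        num.trees = numTrees, importance = "permutation",
        seed = seed + r)
      imp <- fit$variable.importance
      thr <- max(imp[probes])
      cand <- imp[names(features)]
      wins <- wins + (cand > thr)
      impSum <- impSum + cand
    }
    keep <- names(wins)[wins > reps / 2 &
                        impSum > relFloor * max(impSum)]
    if (length(keep) == 0L) {
      warning("no feature beats the noise benchmark; keeping the top one")
      keep <- names(impSum)[which.max(impSum)]
    }
    keep[order(impSum[keep], decreasing = TRUE)]
  })
}

#' Fit a bioavailable strontium isoscape by quantile random forest
#'
#' Trains a random-forest regression of site 87Sr/86Sr on the extracted
#' covariates (3000 trees by default), evaluates it by ten-fold
#' cross-validation, predicts the mean ratio for every stack cell, and
#' derives the per-cell spatial uncertainty from the same forest's
#' quantile predictions: the SD grid is the half-width of the central
#' `piLevel` (default 68.27%) prediction interval, i.e.
#' `(q_0.84135 - q_0.15865) / 2`.
#'
#' @param features data.frame of predictors at the training sites (as
#'   from [extractCovariates()], already filtered/selected).
#' @param response Site 87Sr/86Sr values (>= 20 required).
#' @param stack [CovariateStack-class] supplying prediction rasters; must
#'   contain every feature used.
#' @param numTrees Trees (default 3000). @param piLevel Central
#'   prediction-interval mass for the SD grid (default 0.6827).
#' @param seed Integer seed (forest and CV folds).
#' @param cvFolds Cross-validation folds (default 10).
#' @return An [SrIsoscape-class]; `metadata$cv` holds RMSE and percent
#'   variance explained, `metadata$predictors` the feature names.
#' @export
fitIsoscape <- function(features, response, stack, numTrees = 3000,
                        piLevel = 0.6827, seed = 1L, cvFolds = 10) {
  features <- as.data.frame(features)
  n <- nrow(features)
  stopifnot(n == length(response))
  if (n < 20) stop("at least 20 training points required")
  if (stats::sd(response) == 0)
    stop("degenerate constant response: variance explained undefined")
  missing <- setdiff(names(features), names(stack@layers))
  if (length(missing))
    stop("stack lacks layer(s): ", paste(missing, collapse = ", "))
  dat <- features
  dat$..y <- response

  withSeed(seed, {
    ## ten-fold CV on the training sites
    folds <- sample(rep_len(seq_len(cvFolds), n))
    pred_cv <- numeric(n)
    for (f in seq_len(cvFolds)) {
      hold <- folds == f
      fit_f <- ranger::ranger(dependent.variable.name = "..y",
        data = dat[!hold, , drop = FALSE], num.trees = numTrees,
        seed = seed + f)
      pred_cv[hold] <- stats::predict(fit_f,
        data = dat[hold, , drop = FALSE])$predictions
    }
    rmse <- sqrt(mean((pred_cv - response)^2))
    varExpl <- 100 * (1 - sum((pred_cv - response)^2) /
                          sum((response - mean(response))^2))

    fit <- ranger::ranger(dependent.variable.name = "..y", data = dat,
      num.trees = numTrees, quantreg = TRUE, seed = seed,
      keep.inbag = TRUE)

    dm <- gridDim(stack)
    cells <- as.data.frame(lapply(stack@layers[names(features)], as.vector))
    names(cells) <- names(features)
    ok <- stats::complete.cases(cells)
    meanV <- rep(NA_real_, nrow(cells))
    sdV <- rep(NA_real_, nrow(cells))
    if (any(ok)) {
      sub <- cells[ok, , drop = FALSE]
      meanV[ok] <- stats::predict(fit, data = sub)$predictions
      qlo <- (1 - piLevel) / 2
      qs <- stats::predict(fit, data = sub, type = "quantiles",
                           quantiles = c(qlo, 1 - qlo))$predictions
      sdV[ok] <- pmax((qs[, 2] - qs[, 1]) / 2, 1e-7)
    }
    SrIsoscape(matrix(meanV, dm[1], dm[2]), matrix(sdV, dm[1], dm[2]),
      cellSize = stack@cellSize, origin = stack@origin,
      metadata = list(predictors = names(features),
                      cv = list(rmse = rmse, varianceExplained = varExpl,
                                folds = cvFolds),
                      numTrees = numTrees, piLevel = piLevel, seed = seed,
                      model = fit))
  })
}

#' Validate an isoscape against held-out point samples
#'
#' @param isoscape An [SrIsoscape-class].
#' @param samples data.frame(x, y, ratio) of held-out sites (>= 3 inside
#'   the extent).
#' @return List with `rmse` and `r2` (squared Pearson correlation of
#'   predicted vs observed), plus the per-site table.
#' @export
validatePoints <- function(isoscape, samples) {
  stopifnot(all(c("x", "y", "ratio") %in% names(samples)))
  pred <- lookupIsoscape(isoscape, samples$x, samples$y)$mean
  ok <- !is.na(pred)
  if (sum(ok) < 3) stop("need at least 3 held-out points inside the extent")
  obs <- samples$ratio[ok]; prd <- pred[ok]
  rmse <- sqrt(mean((prd - obs)^2))
  r2 <- if (stats::sd(prd) == 0 || stats::sd(obs) == 0) NA_real_
        else stats::cor(prd, obs)^2
  list(rmse = rmse, r2 = r2,
       table = data.frame(x = samples$x[ok], y = samples$y[ok],
                          observed = obs, predicted = prd))
}
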