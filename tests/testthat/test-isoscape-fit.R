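# one heavier quantile-forest fixture shared across blocks
fixNoisy <- NULL
fixIso <- NULL
setupFit <- function() {
  if (is.null(fixNoisy)) {
    fixNoisy <<- learnableIsoscapeFixture(n = 500, noiseSd = 0.001,
                                          seed = 42)
    fixIso <<- fitIsoscape(fixNoisy$features, fixNoisy$response,
                           fixNoisy$stack, numTrees = 1000, seed = 1)
  }
}

test_that("covariate extraction is exact nearest-cell lookup", {
  m <- matrix(seq(0, 1, length.out = 100), 10, 10) # column-major ramp
  stack <- CovariateStack(list(ramp = m, flat = matrix(5, 10, 10)),
                          cellSize = 100)
  # site at the centre of cell (row 3, col 7)
  s <- data.frame(x = 6.5 * 100, y = 2.5 * 100, ratio = 0.71)
  f <- extractCovariates(s, stack)
  expect_equal(f$ramp, m[3, 7])
  expect_equal(f$flat, 5)

  # constant grid: identical feature for all sites
  many <- data.frame(x = runif(20, 0, 1000), y = runif(20, 0, 1000))
  expect_true(all(extractCovariates(many, stack)$flat == 5))

  # a site outside the extent is dropped and counted
  s3 <- data.frame(x = c(150, 250, -900), y = c(150, 250, 250))
  expect_message(f3 <- extractCovariates(s3, stack), "1 site")
  expect_equal(nrow(f3), 2)
  expect_equal(attr(f3, "dropped"), 1)
})

test_that("correlation filter removes duplicates and constructed pairs", {
  set.seed(6)
  a <- rnorm(200); b <- rnorm(200)
  # duplicated feature: one copy survives
  f1 <- filterCorrelated(data.frame(a = a, dup = a, b = b))
  expect_identical(names(f1), c("a", "b"))
  expect_identical(attr(f1, "dropped"), "dup")
  # independent features both survive (|r| verified < 0.9)
  expect_lt(abs(cor(a, b)), 0.9)
  expect_identical(names(filterCorrelated(data.frame(a = a, b = b))),
                   c("a", "b"))
  # constructed r ~ 0.95 pair: the later-listed member goes
  c95 <- 0.95 * scale(a)[, 1] + sqrt(1 - 0.95^2) * scale(b)[, 1]
  expect_gt(abs(cor(a, c95)), 0.9)
  f2 <- filterCorrelated(data.frame(a = a, c95 = c95, b = b))
  expect_identical(names(f2), c("a", "b"))
  # constant feature dropped with a warning
  expect_warning(f3 <- filterCorrelated(data.frame(a = a, k = rep(1, 200))),
                 "constant")
  expect_identical(names(f3), "a")
})

test_that("variable selection recovers a planted signal and keeps a lone feature", {
  set.seed(42)
  feats <- data.frame(A = rnorm(200))
  for (j in 1:5) feats[[paste0("junk", j)]] <- rnorm(200)
  resp <- feats$A + rnorm(200, 0, 0.01)
  sel <- selectVariables(feats, resp, seed = 1)
  expect_identical(sel, "A")
  # single feature is retained even when uninformative
  expect_warning(
    lone <- selectVariables(data.frame(A = rnorm(50)), rnorm(50), seed = 1),
    "noise benchmark")
  expect_identical(lone, "A")
})

test_that("quantile forest learns a smooth field and calibrates its SD", {
  setupFit()
  # noiseless signal: ten-fold CV variance explained above 90%
  fix0 <- learnableIsoscapeFixture(n = 500, noiseSd = 0, seed = 42)
  iso0 <- fitIsoscape(fix0$features, fix0$response, fix0$stack,
                      numTrees = 1000, seed = 1)
  expect_gt(iso0@metadata$cv$varianceExplained, 90)

  # homoscedastic sigma = 0.001: median SD grid within 30% of the truth
  expect_gt(median(sdGrid(fixIso)), 0.0007)
  expect_lt(median(sdGrid(fixIso)), 0.0013)
  expect_true(all(sdGrid(fixIso) > 0))

  # forest means never leave the training response range
  expect_gte(min(meanGrid(fixIso)), min(fixNoisy$response))
  expect_lte(max(meanGrid(fixIso)), max(fixNoisy$response))

  # widening the interval never shrinks the SD grid
  isoWide <- fitIsoscape(fixNoisy$features, fixNoisy$response,
                         fixNoisy$stack, numTrees = 1000, piLevel = 0.9,
                         seed = 1)
  expect_true(all(sdGrid(isoWide) >= sdGrid(fixIso) - 1e-12))

  expect_error(
    fitIsoscape(fixNoisy$features, rep(0.71, 500), fixNoisy$stack,
                seed = 1), "degenerate")
  expect_error(
    fitIsoscape(fixNoisy$features[1:10, ], fixNoisy$response[1:10],
                fixNoisy$stack, seed = 1), "20")
})

test_that("held-out validation reports RMSE and squared correlation", {
  m <- matrix(seq(0.710, 0.715, length.out = 64), 8, 8)
  iso <- SrIsoscape(m, matrix(1e-3, 8, 8), cellSize = 1000)
  pts <- data.frame(x = c(1500, 3500, 5500, 7500),
                    y = c(1500, 3500, 5500, 7500))
  pred <- lookupIsoscape(iso, pts$x, pts$y)$mean
  # exact observations: RMSE 0, R2 1
  v0 <- validatePoints(iso, cbind(pts, ratio = pred))
  expect_equal(v0$rmse, 0)
  expect_equal(v0$r2, 1)
  # constant offset: bias shows in RMSE, not correlation
  v1 <- validatePoints(iso, cbind(pts, ratio = pred + 0.001))
  expect_equal(v1$rmse, 0.001)
  expect_equal(v1$r2, 1)
  # hand-computed RMSE on a seeded noisy case
  set.seed(3)
  obs <- pred + rnorm(4, 0, 5e-4)
  v2 <- validatePoints(iso, cbind(pts, ratio = obs))
  expect_equal(v2$rmse, sqrt(mean((pred - obs)^2)))
  expect_error(validatePoints(iso, data.frame(x = 1, y = 1, ratio = 1)),
               "3")
})
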