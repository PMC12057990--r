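test_that("track annotation is exact cell lookup with documented edges", {
  iso <- twoZoneIsoscape(gap = 0.004, n = 20)
  # track confined to one cell
  tr1 <- Track(1:5, rep(1500, 5), rep(1500, 5))
  a1 <- annotateTrack(tr1, iso)
  expect_true(all(a1$ratio == meanGrid(iso)[2, 2]))

  # half-open convention: a fix exactly on the zone boundary belongs to
  # the east (higher-index) cell
  bnd <- Track(1, 10 * 1000, 500)
  expect_equal(annotateTrack(bnd, iso)$ratio, meanGrid(iso)[1, 11])

  # 100 random fixes equal the brute-force per-fix lookup
  set.seed(8)
  tr <- Track(sort(runif(100, 0, 50)), runif(100, 0, 20000),
              runif(100, 0, 20000))
  ann <- annotateTrack(tr, iso)
  oracle <- vapply(seq_len(100), function(i) {
    col <- floor(tr@x[i] / 1000) + 1
    row <- floor(tr@y[i] / 1000) + 1
    meanGrid(iso)[row, col]
  }, numeric(1))
  expect_identical(ann$ratio, oracle)

  # out-of-extent fixes are excluded and counted
  trBad <- Track(1:3, c(1500, -5000, 1500), c(1500, 1500, 1500))
  expect_warning(aBad <- annotateTrack(trBad, iso), "excluded")
  expect_equal(attr(aBad, "excluded"), 1)
  expect_equal(nrow(aBad), 2)
})

test_that("profile prediction shares the recording kernel exactly", {
  tm <- ToothTiming("M2", crownLengthMm = 70)
  # constant-ratio track: constant predicted profile
  cst <- data.frame(time = seq(0, 1500, by = 5), x = 1, y = 1,
                    ratio = 0.7123, gapAfter = FALSE)
  p <- predictProfile(cst, tm, maturationWindowDays = 90, nSamples = 50)
  expect_true(all(abs(values(p) - 0.7123) < 1e-12))

  # square-wave series: ramped profile per the rectangular-kernel form
  tStep <- 700; width <- 100
  series <- list(time = c(0, tStep - 1e-9, tStep, 1500),
                 value = c(0.710, 0.710, 0.714, 0.714))
  p2 <- predictProfile(series, tm, width, nSamples = 300)
  tEnd <- tm@endAgeMonths * 365 / 12; tStart <- tm@startAgeMonths * 365 / 12
  t0 <- tEnd - distances(p2) / 70 * (tEnd - tStart)
  frac <- pmin(pmax((t0 + width - tStep) / width, 0), 1)
  expect_equal(values(p2), 0.710 + 0.004 * frac, tolerance = 1e-7)

  # round trip: the same series through recordTooth at zero noise is
  # identical (shared kernel)
  env <- envFromSeries(seq(0.5, 1500), approx(series$time, series$value,
                                              seq(0.5, 1500))$y)
  fromEnv <- recordTooth(env, tm, width, 300, noiseSd = 0, seed = 1)$Sr
  fromTrack <- predictProfile(list(time = env@time, value = env@srRatio),
                              tm, width, 300)
  expect_equal(values(fromEnv), values(fromTrack), tolerance = 1e-12)

  # coverage gaps inside the formation window error out
  shortSeries <- list(time = seq(300, 900), value = rep(0.711, 601))
  expect_error(predictProfile(shortSeries, tm, width, 50), "cover")
})

test_that("profile comparison reports rmse, bias and rank correlation", {
  d <- seq(0, 70, length.out = 80)
  a <- IsotopeProfile("a", "Sr", d, 0.711 + 1e-3 * sin(d / 6))
  expect_equal(compareProfiles(a, a),
               list(rmse = 0, bias = 0, spearman = 1, nGrid = 200))
  shifted <- IsotopeProfile("b", "Sr", d, values(a) + 0.0005)
  cmp <- compareProfiles(a, shifted)
  expect_equal(cmp$bias, 0.0005, tolerance = 1e-9)
  expect_equal(cmp$spearman, 1)
  # seeded noisy pair against the direct formula
  set.seed(10)
  noisy <- IsotopeProfile("c", "Sr", d, values(a) + rnorm(80, 0, 2e-4))
  cmp2 <- compareProfiles(a, noisy, nGrid = 80)
  g <- seq(0, 70, length.out = 80)
  va <- approx(d, values(a), g)$y; vn <- approx(d, values(noisy), g)$y
  expect_equal(cmp2$rmse, sqrt(mean((vn - va)^2)))
  disjoint <- IsotopeProfile("d", "Sr", d + 100, values(a))
  expect_error(compareProfiles(a, disjoint), "overlap")
})

test_that("an isoscape offset shifts predicted profiles by that constant", {
  iso <- twoZoneIsoscape(gap = 0.004, n = 20)
  isoShift <- SrIsoscape(meanGrid(iso) + 0.001, sdGrid(iso),
                         cellSize = 1000)
  set.seed(3)
  tr <- Track(seq(0, 1500, by = 2), runif(751, 0, 20000),
              runif(751, 0, 20000))
  tm <- ToothTiming("M2", crownLengthMm = 70)
  p1 <- predictProfile(annotateTrack(tr, iso), tm, 90, 60)
  p2 <- predictProfile(annotateTrack(tr, isoShift), tm, 90, 60)
  expect_equal(values(p2) - values(p1), rep(0.001, 60), tolerance = 1e-9)
})
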