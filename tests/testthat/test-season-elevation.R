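test_that("the carbon-elevation chain inverts the calibration exactly", {
  em <- ElevationModel()
  # diet at the intercept maps to elevation zero
  e0 <- enamelToElevation(-24.14 - em@dietEnamelOffset,
                          isArchaeological = FALSE, nMc = 200)
  expect_equal(e0$elevation, 0)
  expect_equal(e0$d13C_diet, -24.14)

  # diet -25.59 -> 1000 m, cross-checked by bisection on the forward chain
  e1 <- enamelToElevation(-25.59 - em@dietEnamelOffset,
                          isArchaeological = FALSE, nMc = 200)
  expect_equal(e1$elevation, 1000, tolerance = 1e-6)
  root <- uniroot(function(z) dietFromElevation(z, em) - (-25.59),
                  c(-1e4, 1e4), tol = 1e-9)$root
  expect_equal(e1$elevation, root, tolerance = 1e-6)

  # archaeological enamel -10 permil: Suess then fractionation then Eq
  e2 <- enamelToElevation(-10, isArchaeological = TRUE, nMc = 200)
  expect_equal(e2$d13C_diet, -25.7)
  expect_equal(e2$elevation, (-25.7 + 24.14) / (-1.45e-3),
               tolerance = 1e-9)
  expect_equal(e2$elevation, 1075.86, tolerance = 1e-4)
  expect_true(e2$implausible) # below the 1500 m plausibility floor

  # strictly decreasing in d13C, round trip to 1e-9
  x <- seq(-12, -6, by = 0.5)
  ee <- enamelToElevation(x, nMc = 100)
  expect_true(all(diff(ee$elevation) < 0))
  back <- dietFromElevation(ee$elevation, em)
  expect_equal(back, ee$d13C_diet, tolerance = 1e-9)

  # Monte-Carlo uncertainty is seeded and positive
  a <- enamelToElevation(-10, nMc = 5000, seed = 4)
  b <- enamelToElevation(-10, nMc = 5000, seed = 4)
  expect_identical(a$sd, b$sd)
  expect_gt(a$sd, 0)
  expect_lt(a$lower, a$elevation)
  expect_gt(a$upper, a$elevation)
})

test_that("seasonal anchor recovers sinusoids and flags flat profiles", {
  d <- seq(0, 70, length.out = 60)
  pure <- IsotopeProfile("p", "d18O", d,
    -12.8 + 2.45 * sin(2 * pi * (d - 4) / 28))
  a <- fitSeasonalAnchor(pure)
  expect_false(isDegenerate(a))
  expect_equal(a@amplitude, 2.45, tolerance = 1e-6)
  expect_equal(a@periodMm, 28, tolerance = 1e-6)
  expect_equal(nYears(a), 70 / 28, tolerance = 1e-6)
  # peaks and troughs alternate and sit a half-period apart
  pt <- sort(c(a@peaksMm, a@troughsMm))
  expect_equal(diff(pt), rep(14, length(pt) - 1), tolerance = 1e-4)

  # noisy recovery: amplitude within 3 SE of truth across 50 replicates
  set.seed(77)
  amps <- replicate(50, {
    y <- -12.8 + 2.45 * sin(2 * pi * (d - 4) / 28) + rnorm(60, 0, 0.3)
    fitSeasonalAnchor(IsotopeProfile("n", "d18O", d, y))@amplitude
  })
  se <- sd(amps) / sqrt(50)
  expect_lt(abs(mean(amps) - 2.45), 3 * se + 1e-3)

  # constant profile: degenerate flag, no anchor
  flat <- fitSeasonalAnchor(IsotopeProfile("f", "d18O", d, rep(-12, 60)))
  expect_true(isDegenerate(flat))
  expect_error(fitSeasonalAnchor(IsotopeProfile("s", "d18O", 1:5,
                                                rnorm(5))), "8")
})

test_that("profile amplitude is the order-invariant range", {
  p <- IsotopeProfile("x", "d18O", 1:3, c(-18.0, -10, -5.7))
  expect_equal(profileAmplitude(p), 12.3)
  expect_equal(profileAmplitude(c(-5.7, -18.0, -10)), 12.3)
  expect_equal(profileAmplitude(rep(3, 5)), 0)
  expect_error(profileAmplitude(1), "2")
})
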