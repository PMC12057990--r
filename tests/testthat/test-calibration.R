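test_that("collagen QC applies the C/N-or-yield rule", {
  s <- data.frame(id = c("a", "b", "c", "d"),
                  c_to_n = c(3.2, 3.5, 3.5, NA),
                  collagen_yield = c(1, 6, 4, NA))
  qc <- qcFilter(s)
  expect_identical(qc$retained$id, c("a", "b")) # in-range C/N; OR-clause yield
  expect_false(qc$report$retained[3]) # both criteria fail
  expect_match(qc$report$reason[4], "indeterminate")
})

test_that("calibration matches the Gaussian closed form on an identity curve", {
  curve <- syntheticCalCurve(c(2000, 4000), curveSd = 1e-9)
  cal <- calibrate(3000, 30, curve)
  expect_equal(cal$density, dnorm(cal$grid, 3000, 30), tolerance = 1e-9)
  expect_equal(cal$median, 3000)
  # density integrates to 1 for arbitrary curves
  wig <- syntheticCalCurve(c(2000, 4000), curveSd = 12,
                           wiggleAmplitude = 30, wigglePeriod = 120)
  calw <- calibrate(2900, 25, wig)
  step <- diff(calw$grid)[1]
  expect_equal(sum((calw$density[-1] + calw$density[-length(calw$density)])
                   / 2) * step, 1, tolerance = 1e-9)
})

test_that("calibration equals a dense quadrature oracle on a wiggly curve", {
  wig <- syntheticCalCurve(c(2000, 4000), curveSd = 12,
                           wiggleAmplitude = 30, wigglePeriod = 120)
  cal <- calibrate(2900, 25, wig)
  # oracle: same model evaluated independently and normalized by dense
  # trapezoid integration on a 10x finer grid
  fine <- seq(2000, 4000, by = 0.1)
  mu <- approx(wig@calBP, wig@mu, fine)$y
  sg <- approx(wig@calBP, wig@sigma, fine)$y
  df <- dnorm(2900, mu, sqrt(25^2 + sg^2))
  df <- df / (sum((df[-1] + df[-length(df)]) / 2) * 0.1)
  oracle <- approx(fine, df, cal$grid)$y
  expect_lt(max(abs(cal$density - oracle)), 1e-6)
})

test_that("calibration is stable under grid refinement and guards edges", {
  wig <- syntheticCalCurve(c(2500, 3500), curveSd = 10,
                           wiggleAmplitude = 20, wigglePeriod = 150)
  c1 <- calibrate(3000, 30, wig, step = 1)
  c05 <- calibrate(3000, 30, wig, step = 0.5)
  expect_lt(max(abs(c1$hpd - c05$hpd)), 1)
  expect_lt(abs(c1$median - c05$median), 1)
  # HPD mass is at least the nominal level
  inHpd <- rep(FALSE, length(c1$grid))
  for (r in seq_len(nrow(c1$hpd)))
    inHpd <- inHpd | (c1$grid >= c1$hpd[r, 1] & c1$grid <= c1$hpd[r, 2])
  expect_gte(sum(c1$density[inHpd]), 0.954)
  # a curve that stops near the date: posterior mass at the boundary
  short <- syntheticCalCurve(c(2980, 3500), curveSd = 10)
  expect_error(calibrate(3000, 30, short), "narrow")
})

test_that("cal BP converts to BCE with the 1950 datum and no year zero", {
  expect_equal(calBPtoBCE(2991), 1042)
  expect_equal(calBPtoBCE(1950), 1)   # 1 BCE
  expect_equal(calBPtoBCE(1949), -1)  # 1 CE
  expect_equal(calBPtoBCE(c(3000, 2000)), c(1051, 51))
})

test_that("IntCal-dialect curve files round-trip", {
  path <- tempfile(fileext = ".14c")
  writeLines(c("# synthetic curve", "# CAL BP, 14C age, Error",
               "3000, 2870, 12", "2999, 2868, 12", "2998, 2867, 11"),
             path)
  cv <- readCalCurve(path)
  expect_s4_class(cv, "CalibrationCurve")
  expect_equal(cv@calBP, c(2998, 2999, 3000))
  expect_equal(cv@mu, c(2867, 2868, 2870))
  expect_equal(cv@sigma, c(11, 12, 12))
})
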