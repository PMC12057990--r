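test_that("environment series reflects camps, season and elevation", {
  iso <- twoZoneIsoscape(gap = 0.003)
  camps <- twoZoneCamps()

  # single camp, zero amplitude: all three series constant
  sch1 <- makeSeasonalSchedule(camps[1, ], nYears = 2, switchesPerYear = 1)
  env1 <- simulateEnvironment(sch1, iso,
    d18OParams = list(mean = -12.8, amplitude = 0, phaseDay = 80))
  expect_true(all(env1@srRatio == env1@srRatio[1]))
  expect_true(all(env1@d18O == -12.8))
  expect_true(all(env1@d13C == env1@d13C[1]))

  # peak-to-trough range of the seasonal cycle is twice the amplitude
  env2 <- simulateEnvironment(sch1, iso,
    d18OParams = list(mean = -12.8, amplitude = 2.45, phaseDay = 80))
  expect_equal(max(env2@d18O) - min(env2@d18O), 4.9, tolerance = 1e-3)

  # two camps, 4 switches/year: piecewise-constant Sr with 4 jumps/year,
  # counted brute-force from the first differences
  sch4 <- makeSeasonalSchedule(camps, nYears = 1, switchesPerYear = 4)
  env4 <- simulateEnvironment(sch4, iso)
  expect_equal(sum(diff(env4@srRatio) != 0), 3) # 4 spells = 3 interior switches
  sch4b <- makeSeasonalSchedule(camps, nYears = 2, switchesPerYear = 4)
  env4b <- simulateEnvironment(sch4b, iso)
  expect_equal(sum(diff(env4b@srRatio) != 0), 7)

  # d13C follows the elevation calibration forward chain
  em <- ElevationModel()
  expected <- (em@slope * camps$elevation[1] + em@intercept) -
    em@dietEnamelOffset
  expect_equal(env1@d13C[1], expected)

  # camp outside the grid is reported by index
  badCamps <- camps; badCamps$x[2] <- 1e9
  schBad <- makeSeasonalSchedule(badCamps, nYears = 1)
  expect_error(simulateEnvironment(schBad, iso), "camp")
})

test_that("tooth recorder reproduces constants and the step closed form", {
  tm <- ToothTiming("M2", crownLengthMm = 70)

  # constant environment: every sample equals the constant at zero noise
  envC <- envFromSeries(seq(0.5, 1500), rep(0.7115, 1500))
  prof <- recordTooth(envC, tm, maturationWindowDays = 90,
                      nSamples = 40, noiseSd = 0, seed = 1)
  expect_true(all(abs(values(prof$Sr) - 0.7115) < 1e-12))
  expect_equal(length(prof), 3L)

  # step change: rectangular-kernel convolution gives a linear ramp of
  # exactly the maturation window's temporal extent
  tStep <- 600; width <- 120
  time <- c(0, tStep - 1e-9, tStep, 1500)
  envS <- envFromSeries(time, c(0, 0, 1, 1))
  p <- recordTooth(envS, tm, maturationWindowDays = width,
                   nSamples = 400, noiseSd = 0, seed = 1)$Sr
  age <- p@metadata$ageDays
  expected <- pmin(pmax((age + width - tStep) / width, 0), 1)
  expect_equal(values(p), expected, tolerance = 1e-7)

  # ramp extent in time equals the window
  ramp <- age[values(p) > 1e-9 & values(p) < 1 - 1e-9]
  expect_lt(diff(range(ramp)), width)
  expect_gt(diff(range(ramp)), width - 2 * diff(range(age)) / 399)

  # distances run from the ERJ with age decreasing as distance grows
  expect_equal(min(distances(p)), 0)
  expect_equal(max(distances(p)), 70)
  expect_true(all(diff(age) < 0) == (diff(distances(p))[1] > 0))

  # insufficient coverage errors with the required range
  envShort <- envFromSeries(seq(300, 800), rep(0.71, 501))
  expect_error(recordTooth(envShort, tm, 90, 40, 0, 1), "cover")
})

test_that("sinusoid attenuation matches the rectangular-kernel factor", {
  tm <- ToothTiming("M2", crownLengthMm = 70)
  P <- 365; A <- 2; width <- 120
  time <- seq(0.25, 1500, by = 0.5)
  envS <- envFromSeries(time, A * sin(2 * pi * time / P))
  p <- recordTooth(envS, tm, maturationWindowDays = width,
                   nSamples = 500, noiseSd = 0, seed = 1)$Sr
  att <- abs(sin(pi * width / P) / (pi * width / P))
  # closed form evaluated per sample (window mean of a sine is the sine
  # at the window midpoint scaled by the sinc factor)
  age <- p@metadata$ageDays
  closed <- A * att * sin(2 * pi * (age + width / 2) / P)
  expect_equal(values(p), closed, tolerance = 1e-4)
  # and against a quadrature oracle on a fine grid
  quad <- vapply(age, function(t0) {
    tt <- seq(t0, t0 + width, length.out = 4001)
    mean(A * sin(2 * pi * tt / P))
  }, numeric(1))
  # the recorder integrates the half-day-sampled interpolant, the oracle
  # the analytic sine; they agree to the interpolation error
  expect_equal(values(p), quad, tolerance = 1e-3)
  # observed amplitude is attenuated accordingly (interior samples only)
  inner <- values(p)[age > P / 2 & age < max(age) - P / 2]
  expect_equal(max(abs(inner)), A * att, tolerance = 5e-3)
})

test_that("recording is linear in the environmental input at zero noise", {
  tm <- ToothTiming("M1", crownLengthMm = 55)
  time <- seq(0.5, 1200)
  set.seed(9)
  v1 <- cumsum(rnorm(length(time), 0, 0.01))
  v2 <- sin(2 * pi * time / 200)
  rec <- function(v) values(recordTooth(envFromSeries(time, v), tm,
    maturationWindowDays = 60, nSamples = 80, noiseSd = 0, seed = 1)$Sr)
  a <- 2.5; b <- -1.3
  expect_equal(rec(a * v1 + b * v2), a * rec(v1) + b * rec(v2),
               tolerance = 1e-10)
})
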