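# Shared fixtures built in code at test time.

# two-zone isoscape: left half at `base`, right half `base + gap`
twoZoneIsoscape <- function(gap = 0.002, base = 0.711, n = 40,
                            sd = 0.001, cellSize = 1000) {
  m <- matrix(base, n, n)
  m[, (n %/% 2 + 1):n] <- base + gap
  SrIsoscape(m, matrix(sd, n, n), cellSize = cellSize)
}

# camps in the middle of each zone of a twoZoneIsoscape
twoZoneCamps <- function(n = 40, cellSize = 1000,
                         elevation = c(1900, 2500)) {
  data.frame(x = c(n / 4, 3 * n / 4) * cellSize,
             y = c(n / 2, n / 2) * cellSize, elevation = elevation)
}

# environment series wrapping one numeric series into all four channels
envFromSeries <- function(time, value) {
  new("EnvironmentSeries", time = time, srRatio = value, d18O = value,
      d13C = value, elevation = value)
}

# a smooth two-covariate stack and sample sites with a learnable response
learnableIsoscapeFixture <- function(n = 500, noiseSd = 0, seed = 42,
                                     nr = 30, nc = 30) {
  set.seed(seed)
  xg <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  yg <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)
  stack <- CovariateStack(list(a = xg, b = yg), cellSize = 1000)
  samples <- data.frame(x = runif(n, 0, nc * 1000),
                        y = runif(n, 0, nr * 1000))
  feat <- extractCovariates(samples, stack)
  truth <- 0.710 + 0.008 * feat$a + 0.004 * sin(2 * pi * feat$b)
  list(stack = stack, features = feat[, c("a", "b")],
       response = truth + rnorm(nrow(feat), 0, noiseSd), truth = truth)
}

# independent brute-force assignment: normal density per cell, normalized
bruteForcePosterior <- function(m, s, muGrid, sdGrid) {
  lik <- matrix(NA_real_, nrow(muGrid), ncol(muGrid))
  for (i in seq_len(nrow(muGrid))) {
    for (j in seq_len(ncol(muGrid))) {
      if (!is.na(muGrid[i, j]))
        lik[i, j] <- dnorm(m, muGrid[i, j], sqrt(sdGrid[i, j]^2 + s^2))
    }
  }
  lik / sum(lik, na.rm = TRUE)
}
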