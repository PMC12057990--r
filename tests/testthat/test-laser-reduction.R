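makeTransect <- function(n = 10, i87, i86, i85 = 0, i83 = 0,
                         standards = data.frame(position = c(-1, 100),
                                                ratio = c(0.71308, 0.71308))) {
  intens <- cbind("88" = rep(8, n), "87" = rep_len(i87, n),
                  "86" = rep_len(i86, n), "85" = rep_len(i85, n),
                  "84" = rep(0.01, n), "83" = rep_len(i83, n))
  LaserTransect(seq_len(n), intens, standards)
}

test_that("interference stripping reduces to the raw ratio when clean", {
  tr <- makeTransect(i87 = 0.71, i86 = 1.0)
  out <- correctInterferences(tr)
  expect_equal(out$ratio, rep(0.71, 10))
  expect_true(all(out$valid))
})

test_that("Rb correction subtracts the abundance-scaled 85Rb signal", {
  # 85Rb = 0.010 V at ratio 0.3857 takes 0.003857 V off mass 87
  tr <- makeTransect(i87 = 0.713857, i86 = 1.0, i85 = 0.010)
  out <- correctInterferences(tr, naturalRatios(rb87_85 = 0.3857))
  expect_equal(out$ratio, rep((0.713857 - 0.003857) / 1.0, 10))
})

test_that("injected interferences are recovered exactly (round trip)", {
  set.seed(4)
  n <- 50
  trueRatio <- 0.7110 + cumsum(rnorm(n, 0, 1e-4))
  i86sr <- runif(n, 0.8, 1.2)
  i87sr <- trueRatio * i86sr
  rb85 <- runif(n, 0, 0.02); kr83 <- runif(n, 0, 0.004)
  rat <- naturalRatios()
  intens <- cbind("88" = i86sr * 8.375, # approx natural 88/86
                  "87" = i87sr + rb85 * rat$rb87_85,
                  "86" = i86sr + kr83 * rat$kr86_83,
                  "85" = rb85,
                  "84" = 0.01 + kr83 * rat$kr84_83,
                  "83" = kr83)
  tr <- LaserTransect(seq_len(n), intens,
                      data.frame(position = c(0, n + 1),
                                 ratio = c(0.71308, 0.71308)))
  out <- correctInterferences(tr, rat)
  expect_lt(max(abs(out$ratio - trueRatio)), 1e-6)
})

test_that("non-positive corrected 86 beams are flagged invalid", {
  tr <- makeTransect(i87 = 0.71, i86 = c(1, 0.0001), i83 = 0.01)
  expect_warning(out <- correctInterferences(tr), "invalid")
  expect_true(any(!out$valid))
  expect_true(all(is.na(out$ratio[!out$valid])))
})

test_that("bracketing normalization applies interpolated standard factors", {
  raw <- data.frame(position = c(25, 50, 75), ratio = c(0.711, 0.712, 0.713))
  # constant measured standard 0.71401 vs certified 0.71308
  stds <- data.frame(position = c(0, 100), ratio = c(0.71401, 0.71401))
  out <- bracketNormalize(raw, stds, certifiedValue = 0.71308)
  expect_equal(out$factor, rep(0.71308 / 0.71401, 3))
  expect_equal(out$ratio[1], 0.711 * 0.71308 / 0.71401, tolerance = 1e-12)

  # exact standards: factor 1 everywhere
  stds1 <- data.frame(position = c(0, 100), ratio = c(0.71308, 0.71308))
  expect_equal(bracketNormalize(raw, stds1)$factor, rep(1, 3))

  # midway between unequal brackets: mean of the two factors
  stds2 <- data.frame(position = c(0, 100), ratio = c(0.7138, 0.7142))
  f1 <- 0.71308 / 0.7138; f2 <- 0.71308 / 0.7142
  out2 <- bracketNormalize(data.frame(position = 50, ratio = 0.711), stds2)
  expect_equal(out2$factor, (f1 + f2) / 2)

  # scale equivariance: doubling raw ratios doubles corrected ratios
  raw2 <- raw; raw2$ratio <- raw2$ratio * 2
  expect_equal(bracketNormalize(raw2, stds)$ratio,
               bracketNormalize(raw, stds)$ratio * 2)

  # unflanked points fall back to the nearest standard with a warning
  expect_warning(
    outside <- bracketNormalize(data.frame(position = 150, ratio = 0.711),
                                stds2), "fallback")
  expect_equal(outside$factor, f2)
})
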