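# Morlet CWT core: frequency grids, forward/inverse transform, cone of
# influence.

test_that("frequency grid construction covers the requested band", {
  f <- makeFrequencyGrid(0.001, 0.5, 500)
  expect_length(f, 500)
  expect_equal(f[1], 0.001)
  expect_equal(f[500], 0.5)
  expect_equal(unique(round(diff(f), 12)), 1e-3)

  expect_equal(makeFrequencyGrid(0.07, 0.14, 2), c(0.07, 0.14))

  fl <- makeFrequencyGrid(0.01, 0.16, 100, spacing = "log")
  ratios <- fl[-1] / fl[-length(fl)]
  expect_lt(diff(range(ratios)), 1e-12)

  expect_error(makeFrequencyGrid(0.1, 0.6, 10, samplingRate = 1), "Nyquist")
  expect_error(makeFrequencyGrid(0.1, 0.2, 1), "at least 2")
  expect_error(makeFrequencyGrid(0.2, 0.1, 10), "fMin")
})

test_that("Morlet parameters enforce their invariants", {
  expect_error(morletParams(c(0.1, 0.6), 1), "Nyquist")
  expect_error(morletParams(c(0.2, 0.1), 1), "increasing")
  expect_error(morletParams(0.1, 1, m = -1), "positive")
  p <- morletParams(c(0.1, 0.2), 1)
  expect_equal(sigmaT(p), 5 / (2 * pi * c(0.1, 0.2)))
})

test_that("the transform acts as a matched filter on a pure cosine", {
  p <- defaultGrid()
  n <- 512
  x <- cos(2 * pi * 0.1 * (0:(n - 1)))
  tf <- cwtForward(x, p)
  int <- interiorCols(p, n)
  peaks <- apply(Mod(coefficients2d(tf))[, int], 2, which.max)
  expect_true(all(abs(frequencies(tf)[peaks] - 0.1) < 0.015))
})

test_that("zero input gives zero coefficients and errors are caught", {
  p <- defaultGrid()
  tf <- cwtForward(numeric(64), p)
  expect_true(all(Mod(coefficients2d(tf)) == 0))
  expect_error(cwtForward(c(1, NA, rep(0, 30)), p), "finite")
  expect_error(cwtForward(numeric(8), p), "16")
})

test_that("impulse response is a Gaussian bump of width sigma_t(f)", {
  p <- defaultGrid()
  n <- 512
  x <- numeric(n); t0 <- 256
  x[t0] <- 1
  tf <- cwtForward(x, p)
  # frequencies well below Nyquist, where the sampled filter's tail
  # truncation is negligible
  for (j in c(8, 16, 24)) {
    f <- frequencies(tf)[j]
    st <- 5 / (2 * pi * f)
    # closed-form modulus of the Morlet response to a unit impulse
    expected <- (st * sqrt(pi))^(-1 / 2) *
      exp(-((seq_len(n) - t0))^2 / (2 * st^2))
    expect_lt(max(abs(Mod(coefficients2d(tf))[j, ] - expected)), 1e-4)
  }
})

test_that("the transform is linear and shift-covariant away from edges", {
  # top of the band kept clear of Nyquist so filter-truncation sidelobes
  # stay below the comparison tolerance
  p <- defaultGrid(fMin = 0.05, fMax = 0.3)
  n <- 400
  set.seed(101)
  x <- rnorm(n); y <- rnorm(n)
  Wx <- coefficients2d(cwtForward(x, p))
  Wy <- coefficients2d(cwtForward(y, p))
  Wmix <- coefficients2d(cwtForward(2 * x - 0.5 * y, p))
  expect_lt(max(Mod(Wmix - (2 * Wx - 0.5 * Wy))), 1e-10)

  k <- 10
  xs <- c(numeric(k), x[1:(n - k)])
  Ws <- coefficients2d(cwtForward(xs, p))
  # margin of 5 envelope widths: beyond it the zero-padded edge contributes
  # a vanishing fraction of the coefficient
  margin <- ceiling(5 * max(sigmaT(p))) + k
  int <- (margin + 1):(n - margin)
  expect_lt(max(Mod(Ws[, int] - Wx[, int - k])), 1e-3 * max(Mod(Wx)))
})

test_that("forward-inverse round trip meets the 1% criterion in-band", {
  p <- morletParams(makeFrequencyGrid(0.02, 0.3, 200), 1)
  n <- 1024
  x <- twoChirps(n)
  xr <- cwtInverse(cwtForward(x, p))
  int <- interiorCols(p, n)
  expect_lt(relativeReconstructionError(x[int], xr[int]), 0.01)

  # all-zero coefficients invert to the zero series
  tf <- cwtForward(numeric(64), p)
  expect_true(all(cwtInverse(tf) == 0))
})

test_that("a narrowband grid recovers a matching sinusoid", {
  n <- 512
  f0 <- 0.1
  p <- morletParams(seq(0.08, 0.12, length.out = 9), 1)
  x <- cos(2 * pi * f0 * (0:(n - 1)))
  xr <- cwtInverse(cwtForward(x, p))
  int <- interiorCols(p, n)
  expect_lt(relativeReconstructionError(x[int], xr[int]), 0.05)
})

test_that("relative reconstruction error matches its definition", {
  x <- sin(seq_len(100))
  expect_equal(relativeReconstructionError(x, x), 0)
  expect_equal(relativeReconstructionError(x, numeric(100)), 1)
  expect_equal(relativeReconstructionError(x, x * 1.01), 0.01)
  expect_error(relativeReconstructionError(numeric(5), numeric(5)), "norm")
  expect_error(relativeReconstructionError(x, x[1:10]), "lengths")
})

test_that("COI half-width scales as 1/f and masks edges only", {
  p <- morletParams(c(0.05, 0.1, 0.2), 1)
  hw <- coneOfInfluence(p, 512)
  expect_equal(hw[1] / hw[2], 2, tolerance = 1e-12)
  expect_equal(hw[2] / hw[3], 2, tolerance = 1e-12)
  expect_equal(hw, sqrt(2) * 5 / (2 * pi * c(0.05, 0.1, 0.2)))
  expect_true(all(diff(hw) < 0))

  int <- coiInterior(p, 512)
  expect_true(all(int[, 256]))           # centre is interior
  expect_false(any(int[, 1]))            # edges are contaminated
  # low-frequency rows fully contaminated when the record is short
  intShort <- coiInterior(p, 32)
  expect_false(any(intShort[1, ]))
})
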