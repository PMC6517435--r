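# Nonstationary wavelet-domain surrogates and the stationary iAAFT
# baseline.

test_that("wavelet surrogates preserve the filtered amplitude distribution
           exactly", {
  p <- defaultGrid()
  set.seed(21)
  x <- chirpSignal(512, 0.05, 0.3) + 0.3 * rnorm(512)
  filt <- cwtInverse(cwtForward(x, p))
  s1 <- waveletSurrogate(x, p)
  expect_identical(sort(s1), sort(filt))
  s2 <- waveletSurrogate(x, p)
  expect_false(identical(s1, s2))     # fresh noise phase each call
  expect_identical(sort(s2), sort(filt))
  # refinement iterations keep the rescaling exact too
  s3 <- waveletSurrogate(x, p, nIterations = 2)
  expect_identical(sort(s3), sort(filt))
  expect_error(waveletSurrogate(rep(1, 64), p), "constant")
})

test_that("wavelet surrogates track the TF modulus far better than iAAFT
           on a chirp", {
  p <- defaultGrid()
  n <- 512
  x <- chirpSignal(n, 0.05, 0.35)
  int <- interiorCols(p, n)
  modX <- Mod(coefficients2d(cwtForward(x, p)))[, int]
  set.seed(22)
  corW <- corI <- numeric(5)
  for (r in 1:5) {
    sw <- waveletSurrogate(x, p)
    si <- iaaftSurrogate(x)
    corW[r] <- cor(as.vector(modX),
                   as.vector(Mod(coefficients2d(cwtForward(sw, p)))[, int]))
    corI[r] <- cor(as.vector(modX),
                   as.vector(Mod(coefficients2d(cwtForward(si, p)))[, int]))
  }
  expect_gt(median(corW), median(corI))
  expect_gt(median(corW), 0.5)
})

test_that("refinement iterations do not degrade the TF-modulus match", {
  p <- defaultGrid()
  n <- 512
  x <- chirpSignal(n, 0.05, 0.35)
  int <- interiorCols(p, n)
  modX <- Mod(coefficients2d(cwtForward(x, p)))[, int]
  discrepancy <- function(nIter) {
    set.seed(23)  # same noise stream for both settings
    s <- waveletSurrogate(x, p, nIterations = nIter)
    modS <- Mod(coefficients2d(cwtForward(s, p)))[, int]
    sqrt(mean((modS - modX)^2)) / sqrt(mean(modX^2))
  }
  d0 <- discrepancy(0)
  d2 <- discrepancy(2)
  expect_lte(d2, d0 * 1.05)
  expect_lt(d0, 0.8)
})

test_that("iAAFT preserves amplitudes exactly and converges the spectrum", {
  set.seed(24)
  x <- as.numeric(arima.sim(list(ar = 0.8), 256))
  s <- iaaftSurrogate(x)
  expect_identical(sort(s), sort(x))
  expect_error(iaaftSurrogate(rep(2, 64)), "constant")

  # spectral discrepancy non-increasing across iterations
  amp <- Mod(fft(x))
  disc <- vapply(c(1L, 3L, 10L, 50L), function(it) {
    set.seed(25)
    sqrt(mean((Mod(fft(iaaftSurrogate(x, maxIter = it))) - amp)^2))
  }, numeric(1))
  expect_true(all(diff(disc) <= 1e-8))

  # white-noise statistics are preserved (identical sorted values)
  set.seed(26)
  g <- rnorm(512)
  sg <- iaaftSurrogate(g)
  expect_equal(mean(sg), mean(g))
  expect_equal(sd(sg), sd(g))
})

test_that("ensembles are reproducible and destroy cross-channel coherence", {
  p <- defaultGrid(nFreqs = 25)
  n <- 400
  set.seed(27)
  common <- chirpSignal(n, 0.1, 0.2)
  X <- rbind(common + 0.2 * rnorm(n), common + 0.2 * rnorm(n))
  e1 <- surrogateEnsemble(X, p, K = 3, seed = 99)
  e2 <- surrogateEnsemble(X, p, K = 3, seed = 99)
  expect_identical(realisations(e1), realisations(e2))
  expect_error(surrogateEnsemble(X, p, K = 0), "at least 1")

  # coherence of the original pair vastly exceeds the surrogate ensemble's
  # in the band the common chirp occupies
  int <- coiInterior(p, n)
  band <- p@frequencies >= 0.1 & p@frequencies <= 0.2
  psiOf <- function(A) {
    tf <- lapply(1:2, function(i) cwtForward(A[i, ], p))
    psi <- tvsc(coherenceMatrix(tf))
    median(psi[band, ][int[band, ]])
  }
  orig <- psiOf(standardizeChannels(X))
  surr <- vapply(1:3, function(k) psiOf(realisations(e1)[k, , ]), numeric(1))
  expect_gt(orig, 0.9)
  expect_lt(max(surr), orig - 0.2)
})
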