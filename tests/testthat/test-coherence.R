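# Cross-spectra, smoothing, the pairwise coherence matrix and the
# eigenvalue-based spatial coherence statistic.

test_that("cross-spectrum identities hold", {
  p <- defaultGrid()
  set.seed(7)
  n <- 256
  ti <- cwtForward(rnorm(n), p)
  tj <- cwtForward(rnorm(n), p)
  auto <- crossSpectrum(ti, ti)
  expect_true(all(Im(auto) == 0 | abs(Im(auto)) < 1e-14 * Mod(auto)))
  expect_equal(Re(auto), Mod(coefficients2d(ti))^2, tolerance = 1e-12)
  expect_equal(crossSpectrum(ti, tj), Conj(crossSpectrum(tj, ti)))
  pOther <- defaultGrid(nFreqs = 20)
  expect_error(crossSpectrum(ti, cwtForward(rnorm(n), pOther)), "grid")
})

test_that("cross-spectrum phase recovers a known lag between sinusoids", {
  p <- defaultGrid()
  n <- 512
  t <- 0:(n - 1)
  phi <- pi / 3
  ti <- cwtForward(cos(2 * pi * 0.1 * t + phi), p)
  tj <- cwtForward(cos(2 * pi * 0.1 * t), p)
  j <- which.min(abs(frequencies(ti) - 0.1))
  int <- interiorCols(p, n)
  ph <- Arg(crossSpectrum(ti, tj)[j, int])
  expect_lt(max(abs(ph - phi)), 0.05)
})

test_that("smoothing preserves constants, reduces variance, and can be
           near-identity", {
  p <- defaultGrid()
  n <- 256
  const <- matrix(1 + 2i, length(p@frequencies), n)
  smC <- smoothTF(const, smoothingSpec("gaussian", 3, 5L), p)
  expect_lt(max(Mod(smC - (1 + 2i))), 1e-10)

  set.seed(8)
  noise <- matrix(rnorm(length(p@frequencies) * n), ncol = n)
  sm <- smoothTF(noise, smoothingSpec("gaussian", 3, 5L), p)
  expect_lt(stats::var(as.vector(Re(sm))), stats::var(as.vector(noise)))

  tiny <- smoothTF(noise, smoothingSpec("gaussian", 1e-4, 1L), p)
  expect_lt(max(abs(Re(tiny) - noise)), 1e-8)

  expect_error(smoothTF(noise, smoothingSpec(freqBins = 99L), p), "freqBins")
})

test_that("identical channels give an all-ones matrix and Psi = 1", {
  p <- defaultGrid()
  n <- 512
  tf <- cwtForward(chirpSignal(n, 0.08, 0.25), p)
  cf <- coherenceMatrix(list(tf, tf, tf, tf))
  # evaluate where the channels carry usable power (off-ridge TF points of
  # a pure chirp are silent and flagged)
  ok <- coiInterior(p, n) & !cf@lowPower
  expect_gt(mean(ok), 0.2)
  offdiag <- cf@sigma[1, 2, , ]
  expect_lt(max(Mod(offdiag[ok] - 1)), 1e-8)
  psi <- tvsc(cf)
  expect_lt(max(abs(psi[ok] - 1)), 1e-6)
})

test_that("independent channels under heavy smoothing give low coherence", {
  p <- defaultGrid()
  set.seed(9)
  n <- 1024
  tfds <- lapply(1:2, function(i) cwtForward(rnorm(n), p))
  cf <- coherenceMatrix(tfds, smoothingSpec("gaussian", 5, 11L))
  int <- coiInterior(p, n)
  expect_lt(median(Mod(cf@sigma[1, 2, , ][int])), 0.4)
})

test_that("the bivariate off-diagonal is the classic wavelet coherence", {
  p <- defaultGrid()
  set.seed(10)
  n <- 512
  x <- chirpSignal(n, 0.1, 0.2) + 0.5 * rnorm(n)
  y <- chirpSignal(n, 0.1, 0.2) + 0.5 * rnorm(n)
  tfds <- list(cwtForward(x, p), cwtForward(y, p))
  spec <- smoothingSpec()
  cf <- coherenceMatrix(tfds, spec)
  # recompute the smoothed coherence directly from its definition
  num <- smoothTF(crossSpectrum(tfds[[1]], tfds[[2]]), spec, p)
  d1 <- Re(smoothTF(Mod(coefficients2d(tfds[[1]]))^2, spec, p))
  d2 <- Re(smoothTF(Mod(coefficients2d(tfds[[2]]))^2, spec, p))
  expect_equal(cf@sigma[1, 2, , ], num / sqrt(d1 * d2), tolerance = 1e-10)
  expect_true(all(Mod(cf@sigma[1, 2, , ]) <= 1 + 1e-9))
  # diagonal is exactly one
  expect_true(all(cf@sigma[1, 1, , ] == 1 + 0i))
})

test_that("Psi via the eigen path equals |C12| for two channels", {
  p <- defaultGrid()
  set.seed(11)
  n <- 256
  tfds <- lapply(1:2, function(i) cwtForward(rnorm(n), p))
  cf <- coherenceMatrix(tfds)
  psiEig <- tvsc(cf, method = "eigen")
  psiClosed <- tvsc(cf, method = "closed2")
  expect_lt(max(abs(psiEig - psiClosed)), 1e-10)
  expect_equal(psiClosed, Mod(cf@sigma[1, 2, , ]), tolerance = 1e-12)
})

test_that("the eigen path matches a power-iteration oracle to 1e-8", {
  set.seed(12)
  for (M in c(3L, 5L, 8L)) {
    P <- 20L
    sigma <- array(0 + 0i, dim = c(M, M, 1L, P))
    expected <- numeric(P)
    for (k in seq_len(P)) {
      A <- randomCoherenceMatrix(M)
      sigma[, , 1L, k] <- A
      expected[k] <- powerIterLambdaMax(A)
    }
    cf <- new("CoherenceField", sigma = sigma,
              psi = matrix(numeric(0), 0, 0),
              frequencies = 0.1, times = seq_len(P) - 1,
              nChannels = M, lowPower = matrix(FALSE, 1L, P))
    psi <- tvsc(cf, method = "eigen")
    expect_lt(max(abs(psi - (expected - 1) / (M - 1))), 1e-8)
  }
})

test_that("algebraic anchors: all-ones and identity matrices", {
  M <- 6L
  ones <- array(1 + 0i, dim = c(M, M, 1L, 1L))
  eye <- array(0 + 0i, dim = c(M, M, 1L, 1L))
  for (i in seq_len(M)) eye[i, i, 1L, 1L] <- 1
  mk <- function(sig) new("CoherenceField", sigma = sig,
                          psi = matrix(numeric(0), 0, 0), frequencies = 0.1,
                          times = 0, nChannels = M,
                          lowPower = matrix(FALSE, 1L, 1L))
  expect_equal(tvsc(mk(ones))[1, 1], 1, tolerance = 1e-12)
  expect_equal(tvsc(mk(eye))[1, 1], 0, tolerance = 1e-12)
})

test_that("Psi is bounded, permutation-invariant, and rejects
           non-Hermitian input", {
  p <- defaultGrid(nFreqs = 25)
  set.seed(13)
  n <- 400
  X <- matrix(rnorm(4 * n), 4)
  common <- chirpSignal(n, 0.1, 0.2)
  X <- X + matrix(rep(common, each = 4), 4) * 0.8
  tfds <- lapply(1:4, function(i) cwtForward(X[i, ], p))
  cf <- coherenceMatrix(tfds)
  psi <- tvsc(cf)
  expect_true(all(psi >= 0 & psi <= 1))

  perm <- c(3, 1, 4, 2)
  psiPerm <- tvsc(coherenceMatrix(tfds[perm]))
  expect_lt(max(abs(psi - psiPerm)), 1e-9)

  bad <- cf
  bad@sigma[1, 2, 1, 1] <- bad@sigma[1, 2, 1, 1] + 0.1
  expect_error(tvsc(bad, method = "eigen"), "Hermitian")
})

test_that("Psi responds monotonically to common coupling strength", {
  p <- defaultGrid(nFreqs = 25)
  n <- 600
  common <- chirpSignal(n, 0.12, 0.18)
  med <- vapply(c(0, 0.5, 1.5, 4), function(a) {
    set.seed(14)  # same noise at every coupling level
    X <- matrix(rnorm(4 * n), 4) + a * matrix(rep(common, each = 4), 4)
    tfds <- lapply(1:4, function(i) cwtForward(X[i, ], p))
    int <- coiInterior(p, n)
    rows <- frequencies(tfds[[1]]) >= 0.12 & frequencies(tfds[[1]]) <= 0.18
    psi <- tvsc(coherenceMatrix(tfds))
    median(psi[rows, ][int[rows, ]])
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})
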