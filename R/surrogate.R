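# Nonstationary surrogate data by phase randomisation in the wavelet
# domain, and the stationary iAAFT baseline.
#
# Wavelet surrogate of a series x: (1) draw a Gaussian white-noise series
# of the same length; (2) take its wavelet phase phi_noise(t,f); (3) combine
# with the wavelet modulus of x: |W_x| exp(i phi_noise); (4) invert the
# recombined field; (5) rank-rescale the result to the distribution of the
# wavelet-filtered original (forward-then-inverse of x over the analysis
# band). The surrogate thus preserves both the amplitude distribution and
# the time-frequency modulus of the original while destroying its phase
# structure; repeating step 2 with the surrogate's own phase refines the
# TF match.

# Shared worker: one surrogate from precomputed modulus, filtered-original
# sorted values and grid machinery. Consumes the caller's RNG stream.
recombineSurrogate <- function(modW, targetSorted, params, n, weights,
                               nIterations) {
  current <- stats::rnorm(n)
  for (it in 0:nIterations) {
    ph <- Arg(cwtForward(current, params)@coefficients)
    current <- rawInverse(modW * exp(1i * ph), weights)
  }
  targetSorted[rank(current, ties.method = "first")]
}

#' Nonstationary wavelet-domain surrogate
#'
#' Generates one surrogate realisation of a series by phase randomisation in
#' the continuous-wavelet domain (see the package vignette for the
#' algorithm). The surrogate's sorted values equal exactly the sorted values
#' of the wavelet-filtered original over the analysis band, and its
#' time-frequency modulus closely tracks the original's — unlike stationary
#' Fourier surrogates, which scramble nonstationary structure across the
#' whole record.
#'
#' Randomness is drawn from R's RNG stream; call `set.seed()` beforehand
#' for reproducibility.
#'
#' @param x finite, non-constant real series.
#' @param params a [MorletParams-class]; the grid defines the filtering band
#'   the surrogate is rescaled against.
#' @param nIterations number of refinement iterations (default 0, a single
#'   pass); each iteration replaces the noise phase by the current
#'   surrogate's own wavelet phase and recombines again. Rescaling is
#'   applied once, after the final iteration.
#' @return numeric surrogate series of the same length as `x`.
#' @export
waveletSurrogate <- function(x, params, nIterations = 0L) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0)
    stop("constant input: rank rescaling is undefined")
  n <- length(x)
  weights <- reconstructionGain(params, n)
  tf <- cwtForward(x, params)
  target <- sort(rawInverse(tf@coefficients, weights))
  recombineSurrogate(Mod(tf@coefficients), target, params, n, weights,
                     as.integer(nIterations))
}

#' Stationary iAAFT surrogate
#'
#' Iterative amplitude-adjusted Fourier transform surrogate: preserves the
#' amplitude distribution of `x` exactly and converges its Fourier amplitude
#' spectrum toward the original's. Iteration alternates imposing the
#' original Fourier amplitudes and rank-rescaling to the original values,
#' stopping when the rank permutation stabilises or after `maxIter`
#' iterations. Uses R's RNG stream.
#'
#' @param x finite, non-constant real series.
#' @param maxIter iteration cap (default 100).
#' @return numeric surrogate series.
#' @export
iaaftSurrogate <- function(x, maxIter = 100L) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) stop("constant input")
  n <- length(x)
  amp <- Mod(stats::fft(x))
  sortedX <- sort(x)
  s <- sample(x)
  prevRank <- integer(0)
  for (it in seq_len(maxIter)) {
    ph <- Arg(stats::fft(s))
    s2 <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE)) / n
    r <- rank(s2, ties.method = "first")
    s <- sortedX[r]
    if (identical(r, prevRank)) break
    prevRank <- r
  }
  s
}

#' Surrogate ensemble for a multichannel record
#'
#' Generates `K` independent surrogate realisations of an `M x n` record.
#' Within each realisation every channel is randomised with an independent
#' noise phase, destroying inter-channel coherence while preserving each
#' channel's own time-frequency modulus (wavelet algorithm) or Fourier
#' spectrum (iAAFT). Given `seed`, channels and realisations consume
#' successive substreams of one seeded generator, so the ensemble is
#' bit-reproducible.
#'
#' @param X numeric matrix, channels in rows (`M >= 1`).
#' @param params a [MorletParams-class] (wavelet algorithm only).
#' @param K number of realisations (default 100).
#' @param nIterations wavelet-surrogate refinement iterations (default 0).
#' @param seed optional integer seed.
#' @param algorithm `"wavelet"` (default) or `"iaaft"`.
#' @return A [SurrogateEnsemble-class] with `realisations` of shape
#'   `K x M x n`.
#' @export
surrogateEnsemble <- function(X, params, K = 100L, nIterations = 0L,
                              seed = NULL, algorithm = c("wavelet", "iaaft")) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  if (K < 1L) stop("'K' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(X); n <- ncol(X)
  out <- array(NA_real_, dim = c(K, M, n))
  if (algorithm == "wavelet") {
    weights <- reconstructionGain(params, n)
    modW <- vector("list", M)
    target <- vector("list", M)
    for (i in seq_len(M)) {
      tf <- cwtForward(X[i, ], params)
      modW[[i]] <- Mod(tf@coefficients)
      target[[i]] <- sort(rawInverse(tf@coefficients, weights))
    }
    for (k in seq_len(K))
      for (i in seq_len(M))
        out[k, i, ] <- recombineSurrogate(modW[[i]], target[[i]], params, n,
                                          weights, as.integer(nIterations))
  } else {
    for (k in seq_len(K))
      for (i in seq_len(M))
        out[k, i, ] <- iaaftSurrogate(X[i, ])
  }
  new("SurrogateEnsemble", realisations = out, algorithm = algorithm,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      iterations = as.integer(nIterations))
}
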