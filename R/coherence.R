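# Smoothed pairwise wavelet coherence and the eigenvalue-based
# time-varying spatial coherence Psi(t, f).
#
# The complex coherence between channels i and j is
#   C_ij(t,f) = <W_i W_j*> / ( |<W_i W_i*>|^(1/2) |<W_j W_j*>|^(1/2) )
# where <.> smooths in time (kernel half-width proportional to sigma_t(f))
# and across adjacent frequency rows. Collecting all pairs into the
# Hermitian unit-diagonal matrix Sigma(t,f), the spatial coherence is
#   Psi(t,f) = (lambda_max(Sigma) - 1) / (M - 1),
# which is 1 when all M channels are pairwise coherent and 0 when Sigma is
# the identity; for M = 2 it reduces to |C_12|, the square root of the
# classic wavelet coherence.

sameGrid <- function(a, b) {
  isTRUE(all.equal(a@frequencies, b@frequencies)) &&
    isTRUE(all.equal(a@times, b@times)) &&
    a@samplingRate == b@samplingRate
}

#' Wavelet cross-spectrum
#'
#' Elementwise product of one decomposition with the complex conjugate of
#' another on the same grid: `W_i(t,f) * Conj(W_j(t,f))`.
#'
#' @param tfdI,tfdJ [TFDecomposition-class] objects on identical grids.
#' @return complex matrix `n_freqs x n_times`.
#' @export
crossSpectrum <- function(tfdI, tfdJ) {
  if (!sameGrid(tfdI, tfdJ)) stop("decompositions are on different grids")
  tfdI@coefficients * Conj(tfdJ@coefficients)
}

# Precompute the per-row time-smoothing kernels (as DFT-domain transfer
# functions on the padded length) for a grid; reused across the many fields
# smoothed in one coherence computation.
makeSmoother <- function(spec, params, nTimes) {
  fs <- params@samplingRate
  st <- sigmaT(params) * spec@timeHalfwidthFactor
  N <- nextPow2(2L * nTimes)
  nf <- length(st)
  Kmat <- matrix(0, N, nf)
  for (j in seq_len(nf)) {
    sSamp <- st[j] * fs
    if (spec@timeKernel == "gaussian") {
      L <- max(1L, ceiling(4 * sSamp))
      lag <- -L:L
      k <- exp(-lag^2 / (2 * max(sSamp, 1e-8)^2))
    } else {
      L <- max(0L, round(sSamp))
      lag <- -L:L
      k <- rep(1, length(lag))
    }
    k <- k / sum(k)
    kpad <- numeric(N)
    kpad[((lag) %% N) + 1L] <- k
    Kmat[, j] <- kpad
  }
  K <- stats::mvfft(Kmat)
  # edge renormalisation: kernel mass falling outside the record is
  # discarded, so divide by the smoothed all-ones indicator
  ones <- stats::fft(c(rep(1, nTimes), numeric(N - nTimes)))
  norm <- Re(stats::mvfft(K * ones, inverse = TRUE)[seq_len(nTimes), ,
                                                   drop = FALSE] / N)
  norm[norm < 1e-12] <- 1e-12
  list(K = K, norm = t(norm), N = N, nTimes = nTimes,
       freqBins = spec@freqBins)
}

applySmoother <- function(field, sm) {
  nt <- ncol(field)
  if (nt != sm$nTimes) stop("field does not match the smoother's grid")
  P <- matrix(0 + 0i, sm$N, nrow(field))
  P[seq_len(nt), ] <- t(field)
  Fp <- stats::mvfft(P) * sm$K
  out <- t(stats::mvfft(Fp, inverse = TRUE)[seq_len(nt), , drop = FALSE] / sm$N)
  rowRunningMean(out / sm$norm, sm$freqBins)
}

#' Smooth a time-frequency field
#'
#' Applies the coherence smoothing operator: each frequency row is convolved
#' in time with the chosen kernel of half-width
#' `timeHalfwidthFactor * sigma_t(f)`, then a boxcar average is taken over
#' `freqBins` adjacent frequency rows (truncated and renormalised at the
#' grid edges). Real and imaginary parts are smoothed identically; kernel
#' mass is normalised to one so constant fields pass through unchanged.
#'
#' @param field real or complex matrix `n_freqs x n_times`.
#' @param spec a [SmoothingSpec-class].
#' @param params the [MorletParams-class] the field was computed with.
#' @return smoothed matrix (complex).
#' @export
smoothTF <- function(field, spec, params) {
  if (nrow(field) != length(params@frequencies))
    stop("field rows do not match the frequency grid")
  if (spec@freqBins > nrow(field))
    stop("'freqBins' exceeds the number of frequency rows")
  applySmoother(field, makeSmoother(spec, params, ncol(field)))
}

#' Pairwise coherence matrix field
#'
#' Computes the Hermitian `M x M` matrix of smoothed pairwise complex
#' coherences at every TF point. The diagonal is exactly 1. At TF points
#' where a channel's smoothed auto-spectrum falls below `1e-12` times that
#' channel's median auto-spectrum, the affected off-diagonal entries are set
#' to 0 and the point is flagged in the `lowPower` slot (the matrix stays
#' well-defined for the eigen-analysis while the unreliability is recorded).
#'
#' @param tfds list of `M >= 2` [TFDecomposition-class] objects on a common
#'   grid.
#' @param spec a [SmoothingSpec-class]; default [smoothingSpec()].
#' @return A [CoherenceField-class] with the `sigma` array populated (call
#'   [tvsc()] for the Psi map).
#' @export
coherenceMatrix <- function(tfds, spec = smoothingSpec()) {
  M <- length(tfds)
  if (M < 2L) stop("at least two channels are required")
  for (k in 2:M)
    if (!sameGrid(tfds[[1L]], tfds[[k]]))
      stop("all decompositions must share one grid")
  freqs <- tfds[[1L]]@frequencies
  times <- tfds[[1L]]@times
  params <- morletParams(freqs, tfds[[1L]]@samplingRate, tfds[[1L]]@m)
  if (spec@freqBins > length(freqs))
    stop("'freqBins' exceeds the number of frequency rows")
  sm <- makeSmoother(spec, params, length(times))

  auto <- vector("list", M)
  low <- vector("list", M)
  for (i in seq_len(M)) {
    # computed through the same arithmetic as the cross-spectra so that the
    # coherence of identical channels is exactly 1 where power is reliable
    a <- Re(applySmoother(
      tfds[[i]]@coefficients * Conj(tfds[[i]]@coefficients), sm))
    # floor: 1e-12 of the channel's median power, raised to 1e-9 of its
    # peak power so points at the FFT round-off noise floor are flagged
    # rather than producing coherences of noise ratios
    eps <- max(1e-12 * stats::median(a), 1e-9 * max(a))
    low[[i]] <- !(a > eps)
    a[low[[i]]] <- eps + (eps <= 0)  # guard against division by zero
    auto[[i]] <- a
  }

  nf <- length(freqs); nt <- length(times)
  sigma <- array(0 + 0i, dim = c(M, M, nf, nt))
  lowAny <- matrix(FALSE, nf, nt)
  for (i in seq_len(M)) sigma[i, i, , ] <- 1 + 0i
  for (i in seq_len(M - 1L)) {
    for (j in (i + 1L):M) {
      cr <- applySmoother(
        tfds[[i]]@coefficients * Conj(tfds[[j]]@coefficients), sm)
      C <- cr / sqrt(auto[[i]] * auto[[j]])
      bad <- low[[i]] | low[[j]]
      C[bad] <- 0 + 0i
      lowAny <- lowAny | bad
      sigma[i, j, , ] <- C
      sigma[j, i, , ] <- Conj(C)
    }
  }
  new("CoherenceField", sigma = sigma,
      psi = matrix(numeric(0), 0L, 0L),
      frequencies = freqs, times = times, nChannels = as.integer(M),
      lowPower = lowAny)
}

#' Time-varying spatial coherence
#'
#' Maps the coherence matrix field to the spatial coherence statistic
#' \eqn{\Psi(t,f) = (\lambda_{max} - 1)/(M - 1)} at every TF point, where
#' \eqn{\lambda_{max}} is the largest eigenvalue of the Hermitian matrix of
#' pairwise coherences. \eqn{\Psi} is bounded in \[0, 1\]: it equals 1 when
#' the matrix is all ones (all channels locally pairwise coherent) and 0
#' when it is the identity (all channels uncorrelated). For `M = 2` the
#' closed form \eqn{\lambda_{max} = 1 + |C_{12}|} gives
#' \eqn{\Psi = |C_{12}|}, the modulus of the classic wavelet coherence.
#'
#' Values outside \[0, 1\] by at most `1e-6` (eigen-solver round-off) are
#' clipped; larger excursions raise an error.
#'
#' @param field a [CoherenceField-class] from [coherenceMatrix()].
#' @param method `"auto"` (closed form for `M = 2`, eigen-solver otherwise),
#'   `"eigen"` (force the Hermitian eigen-solver), or `"closed2"` (force the
#'   bivariate closed form; `M = 2` only).
#' @return numeric matrix `n_freqs x n_times` of Psi values.
#' @export
tvsc <- function(field, method = c("auto", "eigen", "closed2")) {
  method <- match.arg(method)
  M <- field@nChannels
  d <- dim(field@sigma)
  nf <- d[3L]; nt <- d[4L]
  if (method == "auto") method <- if (M == 2L) "closed2" else "eigen"
  if (method == "closed2") {
    if (M != 2L) stop("closed form applies to M = 2 only")
    psi <- Mod(field@sigma[1L, 2L, , ])
    dim(psi) <- c(nf, nt)
  } else {
    sig <- field@sigma
    dim(sig) <- c(M, M, nf * nt)
    herm <- max(Mod(sig - Conj(aperm(sig, c(2L, 1L, 3L)))))
    if (herm > 1e-8)
      stop("coherence matrix is not Hermitian within tolerance")
    lam <- largestEigHerm(sig)
    psi <- matrix((lam - 1) / (M - 1), nf, nt)
  }
  bad <- max(0, max(psi) - 1, -min(psi))
  if (bad > 1e-6)
    stop("Psi outside [0, 1] beyond numerical tolerance (max excess ",
         format(bad), ")")
  psi[psi > 1] <- 1
  psi[psi < 0] <- 0
  psi
}
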