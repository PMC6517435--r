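# Surrogate-based significance of the spatial coherence map: z-test per TF
# point against the surrogate null, one-sided p-values, and
# Benjamini-Hochberg FDR restricted to the cone-of-influence interior.

#' z-test of an observed Psi map against a surrogate null ensemble
#'
#' At each TF point, `z = (Psi_obs - mean(Psi_null)) / sd(Psi_null)` with
#' the unbiased (K - 1) standard deviation over the `K` surrogate maps, and
#' the one-sided upper-tail normal p-value (the alternative of interest is
#' coherence above the null, not anti-coherence). Points where the
#' surrogate SD is zero cannot exceed a degenerate null: their z is set to 0
#' and p to 1.
#'
#' @param psiObs numeric matrix `n_freqs x n_times`.
#' @param psiNull numeric array `n_freqs x n_times x K`, `K >= 2`.
#' @return list with matrices `z` and `p`.
#' @export
zTest <- function(psiObs, psiNull) {
  d <- dim(psiNull)
  if (length(d) != 3L || d[3L] < 2L)
    stop("'psiNull' must be an n_freqs x n_times x K array with K >= 2")
  if (!identical(d[1:2], dim(psiObs)))
    stop("observed and null maps are on different grids")
  K <- d[3L]
  mu <- rowMeans(psiNull, dims = 2L)
  ss <- rowSums(psiNull^2, dims = 2L)
  v <- pmax((ss - K * mu^2) / (K - 1), 0)
  s <- sqrt(v)
  z <- matrix(0, d[1L], d[2L])
  ok <- s > 0
  z[ok] <- (psiObs[ok] - mu[ok]) / s[ok]
  p <- stats::pnorm(z, lower.tail = FALSE)
  p[!ok] <- 1
  list(z = z, p = p)
}

#' FDR mask over the cone-of-influence interior
#'
#' Benjamini-Hochberg step-up procedure applied to the p-values of the TF
#' points inside the COI interior only; edge-contaminated points would
#' inflate the test count and are never declared significant. BH (rather
#' than a dependency-adjusted variant) is appropriate here: smoothing makes
#' neighbouring p-values positively dependent, for which BH retains control.
#'
#' @param p numeric matrix of one-sided p-values.
#' @param q FDR level in (0, 1); default 0.05.
#' @param coiInterior logical matrix, `TRUE` inside the interior.
#' @return logical matrix; `TRUE` where significant (always `FALSE` outside
#'   the interior).
#' @export
fdrMask <- function(p, q = 0.05, coiInterior) {
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  if (!identical(dim(p), dim(coiInterior)))
    stop("'p' and 'coiInterior' must share dimensions")
  idx <- which(coiInterior)
  if (length(idx) == 0L) stop("the COI interior is empty")
  mask <- matrix(FALSE, nrow(p), ncol(p))
  mask[idx] <- stats::p.adjust(p[idx], method = "BH") <= q
  mask
}

#' End-to-end detection of transient spatial coherence
#'
#' Full pipeline: each channel is standardized (zero mean, unit variance),
#' wavelet-transformed, and the observed spatial coherence map
#' \eqn{\Psi(t,f)} computed; `K` nonstationary surrogate realisations of the
#' record provide the Monte Carlo null of mutually uncorrelated channels
#' with the same per-channel time-frequency structure; a one-sided z-test
#' and Benjamini-Hochberg FDR at level `q`, restricted to the
#' cone-of-influence interior, give the final significance mask.
#'
#' @param X numeric matrix (channels in rows) or [TimeSeriesSet-class].
#' @param params a [MorletParams-class]. When `X` is a `TimeSeriesSet` its
#'   sampling rate must agree.
#' @param spec a [SmoothingSpec-class]; default [smoothingSpec()].
#' @param K surrogate ensemble size (default 100).
#' @param q FDR level (default 0.05).
#' @param nIterations wavelet-surrogate refinement iterations (default 0).
#' @param seed optional integer seed making the run fully reproducible.
#' @return list with elements `psi` (observed map), `significance`
#'   (a [SignificanceMap-class]), `frequencies` and `times`.
#' @examples
#' \donttest{
#' set.seed(7)
#' X <- matrix(rnorm(3 * 300), nrow = 3)
#' p <- morletParams(makeFrequencyGrid(0.05, 0.3, 20), samplingRate = 1)
#' res <- runDetection(X, p, K = 20, seed = 1)
#' res$significance
#' }
#' @export
runDetection <- function(X, params, spec = smoothingSpec(), K = 100L,
                         q = 0.05, nIterations = 0L, seed = NULL) {
  if (is(X, "TimeSeriesSet")) {
    if (!isTRUE(all.equal(X@samplingRate, params@samplingRate)))
      stop("sampling rates of the data and the analysis parameters differ")
    X <- X@data
  }
  X <- as.matrix(X)
  M <- nrow(X); n <- ncol(X)
  if (M < 2L) stop("at least two channels are required")
  if (!is.null(seed)) set.seed(seed)
  X <- standardizeChannels(X)

  tfds <- lapply(seq_len(M), function(i) cwtForward(X[i, ], params))
  psiObs <- tvsc(coherenceMatrix(tfds, spec))

  ens <- surrogateEnsemble(X, params, K = K, nIterations = nIterations)
  nf <- length(params@frequencies)
  psiNull <- array(NA_real_, dim = c(nf, n, K))
  for (k in seq_len(K)) {
    stf <- lapply(seq_len(M),
                  function(i) cwtForward(ens@realisations[k, i, ], params))
    psiNull[, , k] <- tvsc(coherenceMatrix(stf, spec))
  }

  zt <- zTest(psiObs, psiNull)
  interior <- coiInterior(params, n)
  mask <- fdrMask(zt$p, q, interior)
  sig <- new("SignificanceMap", z = zt$z, p = zt$p, mask = mask,
             qLevel = q, coiInterior = interior,
             frequencies = params@frequencies,
             times = (seq_len(n) - 1L) / params@samplingRate)
  list(psi = psiObs, significance = sig,
       frequencies = params@frequencies, times = sig@times)
}
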