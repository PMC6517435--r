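#' @import methods
NULL

#' Morlet analysis parameters
#'
#' Parameters of the complex Morlet continuous wavelet transform: the
#' dimensionless wavelet width \eqn{m = f_0/\sigma_f}, the set of analysis
#' frequencies, and the sampling rate. For an analysis frequency \eqn{f} the
#' temporal width of the wavelet envelope is \eqn{\sigma_t(f) = m/(2\pi f)}
#' and its spectral width \eqn{\sigma_f = 1/(2\pi\sigma_t)}.
#'
#' @slot m numeric(1). Wavelet width (default 5, which makes the Morlet
#'   wavelet approximately analytic).
#' @slot frequencies numeric. Strictly increasing analysis frequencies in Hz
#'   (cycles per sample when the sampling rate is 1), all positive and below
#'   the Nyquist frequency.
#' @slot samplingRate numeric(1). Sampling rate in Hz.
#'
#' @seealso [morletParams()], [cwtForward()]
#' @export
setClass("MorletParams",
  slots = c(m = "numeric", frequencies = "numeric", samplingRate = "numeric"))

setValidity("MorletParams", function(object) {
  msg <- character()
  if (length(object@m) != 1L || !is.finite(object@m) || object@m <= 0)
    msg <- c(msg, "'m' must be a single positive number")
  f <- object@frequencies
  if (length(f) < 1L || anyNA(f) || any(!is.finite(f)))
    msg <- c(msg, "'frequencies' must be a non-empty finite vector")
  else {
    if (any(f <= 0)) msg <- c(msg, "all frequencies must be positive")
    if (is.unsorted(f, strictly = TRUE))
      msg <- c(msg, "'frequencies' must be strictly increasing")
  }
  fs <- object@samplingRate
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    msg <- c(msg, "'samplingRate' must be a single positive number")
  else if (length(f) && max(f) >= fs / 2)
    msg <- c(msg, "all frequencies must be below the Nyquist frequency fs/2")
  if (length(msg)) msg else TRUE
})

#' @param frequencies numeric vector of analysis frequencies (Hz).
#' @param samplingRate sampling rate (Hz).
#' @param m wavelet width (dimensionless); default 5.
#' @return A `MorletParams` object.
#' @rdname MorletParams-class
#' @examples
#' p <- morletParams(makeFrequencyGrid(0.02, 0.4, 50), samplingRate = 1)
#' sigmaT(p)[1:3]
#' @export
morletParams <- function(frequencies, samplingRate, m = 5) {
  new("MorletParams", m = as.numeric(m),
      frequencies = as.numeric(frequencies),
      samplingRate = as.numeric(samplingRate))
}

#' Time-frequency decomposition
#'
#' Complex continuous-wavelet coefficients of a single real-valued series on
#' a frequency-by-time grid, together with the per-frequency half-width of
#' the cone of influence (the region near the record edges where the finite
#' length of the series contaminates the coefficients).
#'
#' @slot coefficients complex matrix, `n_freqs x n_times`.
#' @slot frequencies numeric, Hz; matches the rows of `coefficients`.
#' @slot times numeric, seconds; matches the columns.
#' @slot coiHalfwidth numeric, seconds; e-folding half-width of the wavelet
#'   power envelope at each frequency, monotonically decreasing in frequency.
#' @slot samplingRate numeric(1), Hz.
#' @slot m numeric(1), the Morlet width the decomposition was computed with.
#'
#' @seealso [cwtForward()], [cwtInverse()], [coiInterior()]
#' @export
setClass("TFDecomposition",
  slots = c(coefficients = "matrix", frequencies = "numeric",
            times = "numeric", coiHalfwidth = "numeric",
            samplingRate = "numeric", m = "numeric"))

setValidity("TFDecomposition", function(object) {
  msg <- character()
  d <- dim(object@coefficients)
  if (!is.complex(object@coefficients))
    msg <- c(msg, "'coefficients' must be a complex matrix")
  if (d[1L] != length(object@frequencies))
    msg <- c(msg, "rows of 'coefficients' must match 'frequencies'")
  if (d[2L] != length(object@times))
    msg <- c(msg, "columns of 'coefficients' must match 'times'")
  if (length(object@coiHalfwidth) != length(object@frequencies))
    msg <- c(msg, "'coiHalfwidth' must match 'frequencies'")
  else if (length(object@coiHalfwidth) > 1L &&
           any(diff(object@coiHalfwidth) >= 0))
    msg <- c(msg, "'coiHalfwidth' must be strictly decreasing in frequency")
  if (length(msg)) msg else TRUE
})

#' Time-frequency smoothing specification
#'
#' The smoothing operator applied to wavelet auto- and cross-spectra before
#' forming coherences: a scale-adaptive kernel in time (half-width a fixed
#' multiple of the Morlet envelope width \eqn{\sigma_t(f)}) followed by a
#' boxcar average over an odd number of adjacent frequency rows.
#'
#' @slot timeKernel character(1), `"gaussian"` or `"boxcar"`.
#' @slot timeHalfwidthFactor numeric(1) > 0, kernel half-width as a multiple
#'   of \eqn{\sigma_t(f)}.
#' @slot freqBins integer(1), odd number of adjacent frequency rows averaged.
#' @export
setClass("SmoothingSpec",
  slots = c(timeKernel = "character", timeHalfwidthFactor = "numeric",
            freqBins = "integer"))

setValidity("SmoothingSpec", function(object) {
  msg <- character()
  if (!object@timeKernel %in% c("gaussian", "boxcar"))
    msg <- c(msg, "'timeKernel' must be \"gaussian\" or \"boxcar\"")
  if (length(object@timeHalfwidthFactor) != 1L ||
      !is.finite(object@timeHalfwidthFactor) ||
      object@timeHalfwidthFactor <= 0)
    msg <- c(msg, "'timeHalfwidthFactor' must be a single positive number")
  if (length(object@freqBins) != 1L || object@freqBins < 1L ||
      object@freqBins %% 2L == 0L)
    msg <- c(msg, "'freqBins' must be an odd positive integer")
  if (length(msg)) msg else TRUE
})

#' @param timeKernel `"gaussian"` (default) or `"boxcar"`.
#' @param timeHalfwidthFactor positive multiple of \eqn{\sigma_t(f)}
#'   (default 3; calibrated so the bivariate coherence of independent white
#'   noise stays well below 1, see the vignette).
#' @param freqBins odd number of adjacent frequency rows to average
#'   (default 5).
#' @return A `SmoothingSpec` object.
#' @rdname SmoothingSpec-class
#' @export
smoothingSpec <- function(timeKernel = c("gaussian", "boxcar"),
                          timeHalfwidthFactor = 3, freqBins = 5L) {
  new("SmoothingSpec", timeKernel = match.arg(timeKernel),
      timeHalfwidthFactor = as.numeric(timeHalfwidthFactor),
      freqBins = as.integer(freqBins))
}

#' Pairwise coherence field and spatial coherence map
#'
#' At every time-frequency point, the Hermitian `M x M` matrix of pairwise
#' complex wavelet coherences between `M` channels (unit diagonal, entries
#' bounded by 1 in modulus) and, once computed, the time-varying spatial
#' coherence \eqn{\Psi(t,f) = (\lambda_{max} - 1)/(M - 1)} derived from its
#' largest eigenvalue.
#'
#' @slot sigma complex array `M x M x n_freqs x n_times` of pairwise
#'   coherences.
#' @slot psi numeric matrix `n_freqs x n_times` in \[0, 1\], or a 0 x 0
#'   matrix before [tvsc()] has been applied.
#' @slot frequencies,times grid axes.
#' @slot nChannels integer(1), `M`.
#' @slot lowPower logical matrix flagging TF points where at least one
#'   channel's smoothed auto-spectrum was numerically negligible (the
#'   corresponding coherence entries are set to 0 there).
#' @seealso [coherenceMatrix()], [tvsc()]
#' @export
setClass("CoherenceField",
  slots = c(sigma = "array", psi = "matrix", frequencies = "numeric",
            times = "numeric", nChannels = "integer", lowPower = "matrix"))

setValidity("CoherenceField", function(object) {
  msg <- character()
  d <- dim(object@sigma)
  if (length(d) != 4L || d[1L] != d[2L])
    msg <- c(msg, "'sigma' must be an M x M x n_freqs x n_times array")
  else {
    if (d[1L] != object@nChannels)
      msg <- c(msg, "'nChannels' must match dim(sigma)[1]")
    if (d[3L] != length(object@frequencies) || d[4L] != length(object@times))
      msg <- c(msg, "'sigma' grid must match 'frequencies' and 'times'")
  }
  if (length(msg)) msg else TRUE
})

#' Significance map over the time-frequency plane
#'
#' Result of the surrogate-based z-test of the spatial coherence map against
#' the null hypothesis of uncorrelated channels, with Benjamini-Hochberg
#' false-discovery-rate control applied to the p-values of the points inside
#' the cone-of-influence interior (points declared significant are always
#' inside that interior).
#'
#' @slot z numeric matrix of z-scores, `n_freqs x n_times`.
#' @slot p numeric matrix of one-sided p-values in \[0, 1\].
#' @slot mask logical matrix; `TRUE` where coherence is significant after
#'   FDR correction.
#' @slot qLevel numeric(1), FDR level.
#' @slot coiInterior logical matrix; `TRUE` where the point is unaffected by
#'   edge effects.
#' @slot frequencies,times grid axes.
#' @seealso [zTest()], [fdrMask()], [runDetection()]
#' @export
setClass("SignificanceMap",
  slots = c(z = "matrix", p = "matrix", mask = "matrix", qLevel = "numeric",
            coiInterior = "matrix", frequencies = "numeric",
            times = "numeric"))

setValidity("SignificanceMap", function(object) {
  msg <- character()
  d <- dim(object@z)
  if (!identical(d, dim(object@p)) || !identical(d, dim(object@mask)) ||
      !identical(d, dim(object@coiInterior)))
    msg <- c(msg, "'z', 'p', 'mask' and 'coiInterior' must share dimensions")
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (any(object@mask & !object@coiInterior))
    msg <- c(msg, "significant points must lie inside the COI interior")
  if (length(object@qLevel) != 1L || object@qLevel <= 0 || object@qLevel >= 1)
    msg <- c(msg, "'qLevel' must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Ensemble of surrogate realisations
#'
#' `K` independent surrogate realisations of an `M`-channel record, each
#' channel randomised with an independent noise phase so that inter-channel
#' coherence is destroyed while each channel's own time-frequency modulus
#' (wavelet algorithm) or Fourier spectrum (iAAFT) is preserved.
#'
#' @slot realisations numeric array `K x M x n`.
#' @slot algorithm character(1), `"wavelet"` or `"iaaft"`.
#' @slot seed integer(1) or NA, the seed the ensemble was generated from.
#' @slot iterations integer(1), refinement iterations used.
#' @seealso [surrogateEnsemble()]
#' @export
setClass("SurrogateEnsemble",
  slots = c(realisations = "array", algorithm = "character",
            seed = "integer", iterations = "integer"))

setValidity("SurrogateEnsemble", function(object) {
  msg <- character()
  if (length(dim(object@realisations)) != 3L)
    msg <- c(msg, "'realisations' must be a K x M x n array")
  if (any(!is.finite(object@realisations)))
    msg <- c(msg, "'realisations' must be finite")
  if (!object@algorithm %in% c("wavelet", "iaaft"))
    msg <- c(msg, "'algorithm' must be \"wavelet\" or \"iaaft\"")
  if (length(msg)) msg else TRUE
})

#' Multichannel time-series container
#'
#' An `M x n` real matrix of channels by samples with its sampling rate,
#' channel labels, and a mask recording which entries were missing in the
#' source file (and hence which entries [imputeLocalAverage()] filled in).
#'
#' @slot data numeric matrix, channels in rows.
#' @slot samplingRate numeric(1), Hz.
#' @slot channelLabels character, unique, one per row.
#' @slot missingMask logical matrix, same shape as `data`.
#' @seealso [readMatrix()], [imputeLocalAverage()], [standardizeChannels()]
#' @export
setClass("TimeSeriesSet",
  slots = c(data = "matrix", samplingRate = "numeric",
            channelLabels = "character", missingMask = "matrix"))

setValidity("TimeSeriesSet", function(object) {
  msg <- character()
  if (nrow(object@data) < 1L) msg <- c(msg, "at least one channel required")
  if (length(object@channelLabels) != nrow(object@data))
    msg <- c(msg, "'channelLabels' must have one entry per channel")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "'channelLabels' must be unique")
  if (!identical(dim(object@missingMask), dim(object@data)))
    msg <- c(msg, "'missingMask' must match 'data'")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "'samplingRate' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Simulated benchmark dataset
#'
#' A channels-by-samples matrix produced by one of the benchmark simulators
#' together with the ground-truth window of the strongly coupled regime (in
#' recorded-sample indices) and the generating parameters.
#'
#' @slot data numeric matrix, `M x n`.
#' @slot samplingRate numeric(1).
#' @slot groundTruthWindow numeric(2), `[start, end)` sample-index interval
#'   of the synchronized regime.
#' @slot model character(1), `"ar"` or `"rossler"`.
#' @slot params list of generating parameters (including the seed).
#' @seealso [simulateAR()], [simulateRossler()]
#' @export
setClass("SimulatedDataset",
  slots = c(data = "matrix", samplingRate = "numeric",
            groundTruthWindow = "numeric", model = "character",
            params = "list"))

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  if (any(!is.finite(object@data))) msg <- c(msg, "'data' must be finite")
  w <- object@groundTruthWindow
  if (length(w) != 2L || w[1L] >= w[2L] || w[1L] < 0 ||
      w[2L] > ncol(object@data))
    msg <- c(msg, "'groundTruthWindow' must be a valid [start, end) interval")
  if (length(msg)) msg else TRUE
})
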