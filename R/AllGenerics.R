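#' Accessors for tvsc objects
#'
#' Small accessor generics for the package's S4 containers: the complex
#' wavelet coefficients, the grid axes, the spatial coherence map, the
#' significance mask, the underlying data matrix, and the ground-truth
#' coupling window of a simulated benchmark.
#'
#' @param object a tvsc S4 object.
#' @return The slot contents (a matrix, vector or array as documented in the
#'   class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coefficients2d", function(object) standardGeneric("coefficients2d"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(object) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("psiMap", function(object) standardGeneric("psiMap"))
#' @rdname accessors
#' @export
setGeneric("significanceMask", function(object) standardGeneric("significanceMask"))
#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("groundTruthWindow", function(object) standardGeneric("groundTruthWindow"))
#' @rdname accessors
#' @export
setGeneric("realisations", function(object) standardGeneric("realisations"))

#' @rdname accessors
#' @export
setMethod("coefficients2d", "TFDecomposition", function(object) object@coefficients)
#' @rdname accessors
#' @export
setMethod("frequencies", "TFDecomposition", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("frequencies", "CoherenceField", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("frequencies", "SignificanceMap", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("timeAxis", "TFDecomposition", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("timeAxis", "CoherenceField", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("timeAxis", "SignificanceMap", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("samplingRate", "TFDecomposition", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "TimeSeriesSet", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SimulatedDataset", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("psiMap", "CoherenceField", function(object) object@psi)
#' @rdname accessors
#' @export
setMethod("significanceMask", "SignificanceMap", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("seriesData", "TimeSeriesSet", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("seriesData", "SimulatedDataset", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("groundTruthWindow", "SimulatedDataset", function(object) object@groundTruthWindow)
#' @rdname accessors
#' @export
setMethod("realisations", "SurrogateEnsemble", function(object) object@realisations)

setMethod("show", "MorletParams", function(object) {
  f <- object@frequencies
  cat("MorletParams: m =", object@m, "| fs =", object@samplingRate, "Hz |",
      length(f), "frequencies in [", min(f), ",", max(f), "] Hz\n")
})

setMethod("show", "TFDecomposition", function(object) {
  cat("TFDecomposition:", nrow(object@coefficients), "frequencies x",
      ncol(object@coefficients), "time points | fs =", object@samplingRate,
      "Hz | m =", object@m, "\n")
})

setMethod("show", "SmoothingSpec", function(object) {
  cat("SmoothingSpec:", object@timeKernel, "time kernel, half-width",
      object@timeHalfwidthFactor, "x sigma_t(f),", object@freqBins,
      "frequency bins\n")
})

setMethod("show", "CoherenceField", function(object) {
  cat("CoherenceField:", object@nChannels, "channels |",
      length(object@frequencies), "frequencies x", length(object@times),
      "time points |", if (length(object@psi)) "psi computed" else
      "psi not yet computed", "\n")
})

setMethod("show", "SignificanceMap", function(object) {
  int <- sum(object@coiInterior)
  cat("SignificanceMap:", nrow(object@z), "frequencies x", ncol(object@z),
      "time points | q =", object@qLevel, "|",
      sum(object@mask), "significant of", int, "COI-interior points\n")
})

setMethod("show", "SurrogateEnsemble", function(object) {
  d <- dim(object@realisations)
  cat("SurrogateEnsemble:", d[1L], "realisations x", d[2L], "channels x",
      d[3L], "samples |", object@algorithm, "algorithm |",
      object@iterations, "refinement iterations\n")
})

setMethod("show", "TimeSeriesSet", function(object) {
  cat("TimeSeriesSet:", nrow(object@data), "channels x", ncol(object@data),
      "samples | fs =", object@samplingRate, "Hz |",
      sum(object@missingMask), "missing entries\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  w <- object@groundTruthWindow
  cat("SimulatedDataset (", object@model, "): ", nrow(object@data),
      " channels x ", ncol(object@data), " samples | coupled window [",
      w[1L], ", ", w[2L], ")\n", sep = "")
})
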