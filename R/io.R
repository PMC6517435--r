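# Delimited-text I/O for time-series matrices and TF maps, plus the
# preprocessing steps applied before any analysis: local-average imputation
# of missing values and per-channel standardization.

detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) "," else ""
}

#' Read a time-series matrix from delimited text
#'
#' Reads a comma- or whitespace/tab-separated matrix, one channel per
#' column (default) or per row, with an optional header line of channel
#' labels. Empty cells and `NA`/`NaN` tokens mark missing values, which are
#' recorded in the returned object's `missingMask` (impute with
#' [imputeLocalAverage()] before analysis). Any other non-numeric cell is an
#' error.
#'
#' @param path file path.
#' @param orientation `"channels_in_columns"` (default) or
#'   `"channels_in_rows"`.
#' @param samplingRate sampling rate to attach (default 1).
#' @return A [TimeSeriesSet-class].
#' @export
readMatrix <- function(path,
                       orientation = c("channels_in_columns",
                                       "channels_in_rows"),
                       samplingRate = 1) {
  orientation <- match.arg(orientation)
  sep <- detectSep(path)
  first <- scan(path, what = character(), nlines = 1L, sep = sep,
                quiet = TRUE, strip.white = TRUE)
  numericLike <- function(v)
    v %in% c("", "NA", "NaN") | !is.na(suppressWarnings(as.numeric(v)))
  header <- !all(numericLike(first))
  df <- utils::read.table(path, header = header, sep = sep,
                          na.strings = c("", "NA", "NaN"),
                          check.names = FALSE, strip.white = TRUE)
  nonNum <- !vapply(df, is.numeric, logical(1L)) &
    !vapply(df, function(col) all(is.na(col)), logical(1L))
  if (any(nonNum))
    stop("non-numeric cells in column(s): ",
         paste(names(df)[nonNum], collapse = ", "))
  m <- as.matrix(df)
  mode(m) <- "numeric"
  if (orientation == "channels_in_columns") {
    labels <- if (header) colnames(m) else paste0("ch", seq_len(ncol(m)))
    m <- t(m)
  } else {
    labels <- paste0("ch", seq_len(nrow(m)))
  }
  dimnames(m) <- NULL
  new("TimeSeriesSet", data = m, samplingRate = samplingRate,
      channelLabels = labels, missingMask = is.na(m))
}

#' Write a time-series matrix as delimited text
#'
#' Writes channels in columns with a header of channel labels, at full
#' precision so that a read/write round trip reproduces the values.
#'
#' @param ts a [TimeSeriesSet-class] or a channels-by-samples matrix.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
writeMatrix <- function(ts, path, sep = "\t") {
  if (is(ts, "TimeSeriesSet")) {
    m <- t(ts@data)
    colnames(m) <- ts@channelLabels
  } else {
    m <- t(as.matrix(ts))
    colnames(m) <- paste0("ch", seq_len(ncol(m)))
  }
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Impute missing values by local averaging
#'
#' Each missing value is replaced by the mean of its two nearest observed
#' temporal neighbours. Runs of consecutive missing values are filled by
#' linear interpolation between the flanking observed points (which reduces
#' to the two-neighbour mean for an isolated gap), and a missing value at a
#' record boundary copies the nearest observed value. Only masked positions
#' are touched; the mask is kept as provenance.
#'
#' @param ts a [TimeSeriesSet-class].
#' @return A [TimeSeriesSet-class] with finite data.
#' @export
imputeLocalAverage <- function(ts) {
  m <- ts@data
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    obs <- which(!is.na(x))
    if (length(obs) == 0L)
      stop("channel ", ts@channelLabels[i], " is fully missing")
    if (length(obs) < length(x))
      m[i, ] <- stats::approx(obs, x[obs], xout = seq_along(x),
                              rule = 2)$y
  }
  new("TimeSeriesSet", data = m, samplingRate = ts@samplingRate,
      channelLabels = ts@channelLabels, missingMask = ts@missingMask)
}

#' Standardize channels to zero mean and unit variance
#'
#' Centers and scales each channel to mean 0 and (population, i.e. divisor
#' `n`) standard deviation 1 — the normalisation applied to every channel
#' before wavelet analysis.
#'
#' @param x a [TimeSeriesSet-class] or a channels-by-samples matrix.
#' @return object of the same kind with standardized channels.
#' @export
standardizeChannels <- function(x) {
  isSet <- is(x, "TimeSeriesSet")
  m <- if (isSet) x@data else as.matrix(x)
  if (any(!is.finite(m)))
    stop("non-finite values; impute before standardizing")
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  if (any(s == 0)) stop("constant channel cannot be standardized")
  m <- (m - mu) / s
  if (isSet)
    new("TimeSeriesSet", data = m, samplingRate = x@samplingRate,
        channelLabels = x@channelLabels, missingMask = x@missingMask)
  else m
}

#' Export / read a time-frequency map as delimited text
#'
#' Writes a `n_freqs x n_times` map (rows are frequencies) with a two-line
#' header carrying the time and frequency axes; `readTFMap()` parses the
#' same format back.
#'
#' @param map numeric or logical matrix `n_freqs x n_times`.
#' @param frequencies,times grid axes.
#' @param path file path.
#' @return `exportTFMap()` returns `path` invisibly; `readTFMap()` returns
#'   a list with `map`, `frequencies`, `times`.
#' @export
exportTFMap <- function(map, frequencies, times, path) {
  if (!identical(dim(map), c(length(frequencies), length(times))))
    stop("'map' must be n_freqs x n_times")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# times\t", paste(format(times, digits = 17), collapse = "\t")),
    paste0("# frequencies\t",
           paste(format(frequencies, digits = 17), collapse = "\t"))), con)
  utils::write.table(map, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname exportTFMap
#' @export
readTFMap <- function(path) {
  hdr <- readLines(path, n = 2L)
  parseAxis <- function(line) as.numeric(strsplit(line, "\t")[[1L]][-1L])
  times <- parseAxis(hdr[1L])
  freqs <- parseAxis(hdr[2L])
  m <- as.matrix(utils::read.table(path, skip = 2L, sep = "\t",
                                   header = FALSE))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(length(freqs), length(times))))
    stop("map dimensions do not match the header axes")
  list(map = m, frequencies = freqs, times = times)
}
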