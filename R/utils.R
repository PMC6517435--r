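# Shared internal helpers.

nextPow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream (used for the deterministic reconstruction-gain probe).
withFixedSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trapezoidal quadrature weights for an arbitrary strictly increasing grid.
trapezoidWeights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  w <- numeric(n)
  w[1L] <- (x[2L] - x[1L]) / 2
  w[n] <- (x[n] - x[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  w
}

# Running mean over rows (window of k rows, truncated at the edges and
# renormalised); works for real and complex matrices.
rowRunningMean <- function(m, k) {
  if (k <= 1L) return(m)
  nf <- nrow(m)
  if (k > nf) stop("'freqBins' exceeds the number of frequency rows")
  h <- (k - 1L) %/% 2L
  cs <- rbind(matrix(0, 1L, ncol(m)), apply(m, 2L, cumsum))
  lo <- pmax(seq_len(nf) - h, 1L)
  hi <- pmin(seq_len(nf) + h, nf)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

sigmaTOf <- function(m, f) m / (2 * pi * f)

#' Temporal width of the Morlet envelope
#'
#' Returns \eqn{\sigma_t(f) = m/(2\pi f)} for each analysis frequency, the
#' standard deviation (in seconds) of the Gaussian envelope of the Morlet
#' atom centred at that frequency.
#'
#' @param params a [MorletParams-class] object.
#' @return numeric vector, one value per analysis frequency.
#' @export
sigmaT <- function(params) sigmaTOf(params@m, params@frequencies)
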