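# Benchmark simulators with known ground-truth synchrony windows: a
# 5-variable coupled autoregressive system whose coupling strengths switch
# at a known time, and a random network of noisy nonidentical Rossler
# oscillators whose diffusive coupling is switched on during a known
# window.

#' Coupled autoregressive benchmark
#'
#' Iterates a 5-variable AR system driven by independent unit-variance
#' Gaussian innovations:
#' \deqn{x_{1,t} = 0.95\sqrt2\, x_{1,t-1} - 0.9025 x_{1,t-2} + \epsilon_1}
#' \deqn{x_{2,t} = 0.6 x_{2,t-1} - 0.3 x_{2,t-2} + k_2 x_{1,t-1} + \epsilon_2}
#' \deqn{x_{3,t} = 0.8 x_{3,t-1} - 0.5 x_{2,t-2} + 0.4 x_{1,t-1} + \epsilon_3}
#' \deqn{x_{4,t} = k_1 x_{1,t-2} + 0.25\sqrt2\, x_{4,t-1}
#'   + 0.25\sqrt2\, x_{5,t-1} + \epsilon_4}
#' \deqn{x_{5,t} = -0.25\sqrt2\, x_{4,t-1} + 0.25\sqrt2\, x_{5,t-1}
#'   + \epsilon_5}
#' The coupling strengths take the pre-switch values for `t < switchTime`
#' and the post-switch values for `t >= switchTime` (sample indices counted
#' after burn-in). Defaults: `k1` switches from 0 to -0.5 and `k2` from 0.15
#' to 0.4 at `t = 1000` in a 2000-sample record. The driver `x1` is an AR(2)
#' with a spectral peak near 0.125 cycles/sample.
#'
#' @param nSamples record length after burn-in (default 2000).
#' @param switchTime sample index of the coupling switch (default 1000).
#' @param k1Pre,k1Post,k2Pre,k2Post coupling strengths before/after the
#'   switch.
#' @param noiseSd innovation standard deviation (default 1).
#' @param burnIn samples simulated and discarded before the record starts
#'   (default 100), so the switch index refers to recorded samples.
#' @param x3SelfLag if `TRUE`, the `-0.5` lag-2 term in the third equation
#'   reads `x3` instead of `x2` (the system as written feeds `x2`'s lag into
#'   `x3`; this flag switches to a self-lag variant). Default `FALSE`.
#' @param seed optional integer seed.
#' @return A [SimulatedDataset-class] (`5 x nSamples`, sampling rate 1,
#'   ground-truth window `[switchTime, nSamples)`).
#' @export
simulateAR <- function(nSamples = 2000L, switchTime = 1000L,
                       k1Pre = 0, k1Post = -0.5, k2Pre = 0.15, k2Post = 0.4,
                       noiseSd = 1, burnIn = 100L, x3SelfLag = FALSE,
                       seed = NULL) {
  if (switchTime <= 0L || switchTime >= nSamples)
    stop("'switchTime' must lie strictly inside (0, nSamples)")
  if (!is.null(seed)) set.seed(seed)
  N <- burnIn + nSamples
  x <- matrix(0, 5L, N)
  e <- matrix(stats::rnorm(5L * N, sd = noiseSd), 5L, N)
  a <- 0.95 * sqrt(2); b <- 0.25 * sqrt(2)
  for (t in 3:N) {
    post <- (t - burnIn) >= switchTime
    k1 <- if (post) k1Post else k1Pre
    k2 <- if (post) k2Post else k2Pre
    lag3 <- if (x3SelfLag) x[3L, t - 2L] else x[2L, t - 2L]
    x[1L, t] <- a * x[1L, t - 1L] - 0.9025 * x[1L, t - 2L] + e[1L, t]
    x[2L, t] <- 0.6 * x[2L, t - 1L] - 0.3 * x[2L, t - 2L] +
      k2 * x[1L, t - 1L] + e[2L, t]
    x[3L, t] <- 0.8 * x[3L, t - 1L] - 0.5 * lag3 +
      0.4 * x[1L, t - 1L] + e[3L, t]
    x[4L, t] <- k1 * x[1L, t - 2L] + b * x[4L, t - 1L] +
      b * x[5L, t - 1L] + e[4L, t]
    x[5L, t] <- -b * x[4L, t - 1L] + b * x[5L, t - 1L] + e[5L, t]
  }
  if (any(!is.finite(x)) || max(abs(x)) > 1e6)
    stop("AR trajectory diverged; coefficients outside the stable region")
  new("SimulatedDataset",
      data = x[, (burnIn + 1L):N, drop = FALSE], samplingRate = 1,
      groundTruthWindow = c(switchTime, nSamples), model = "ar",
      params = list(nSamples = nSamples, switchTime = switchTime,
                    k1Pre = k1Pre, k1Post = k1Post, k2Pre = k2Pre,
                    k2Post = k2Post, noiseSd = noiseSd, burnIn = burnIn,
                    x3SelfLag = x3SelfLag, seed = seed))
}

#' Random graph with a prescribed mean degree
#'
#' Samples an Erdos-Renyi graph with exactly `n * km / 2` undirected edges
#' (so the mean degree is exactly `km`), resampling until the graph is
#' connected. Uses R's RNG stream.
#'
#' @param n number of nodes.
#' @param km mean degree; `n * km` must be even and `km < n`.
#' @param maxTries resampling cap (default 1000).
#' @return symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
randomMeanDegreeGraph <- function(n, km, maxTries = 1000L) {
  if (km >= n) stop("'km' must be smaller than 'n'")
  nEdges <- n * km / 2
  if (abs(nEdges - round(nEdges)) > 1e-9)
    stop("'n * km' must be even")
  nEdges <- as.integer(round(nEdges))
  for (i in seq_len(maxTries)) {
    g <- igraph::sample_gnm(n, nEdges)
    if (igraph::is_connected(g))
      return(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
  }
  stop("failed to sample a connected graph")
}

#' Rossler-network benchmark
#'
#' Integrates a network of `M` nonidentical chaotic Rossler oscillators
#' \deqn{\dot x_i = -\omega_i y_i - z_i
#'   + \lambda(t) \sum_j \xi_{ij}(x_j - x_i) + \eta_i}
#' \deqn{\dot y_i = \omega_i x_i + 0.165 y_i}
#' \deqn{\dot z_i = 0.2 + z_i (x_i - 10)}
#' by Euler-Maruyama, with Gaussian white noise of intensity
#' \eqn{\langle\eta_i(t)\eta_i(t')\rangle = 2D\,\delta(t-t')} on the
#' x-equations only. Natural frequencies \eqn{\omega_i} are drawn uniformly
#' from `omegaRange`; the coupling matrix \eqn{\xi} is a connected random
#' graph of mean degree `meanDegree`. The diffusive coupling strength is
#' `lambdaOn` for recorded times inside `couplingWindow` and `lambdaOff`
#' elsewhere. The x-coordinates are recorded every `sampleInterval` time
#' units after discarding `transient` time units.
#'
#' @param nOscillators number of oscillators (default 10).
#' @param omegaRange range of natural frequencies (default `c(0.98, 1.1)`).
#' @param nSamples recorded samples (default 1200).
#' @param couplingWindow recorded-time interval (open) with strong coupling
#'   (default `c(500, 900)`).
#' @param lambdaOn,lambdaOff coupling strengths inside/outside the window
#'   (defaults 0.5 and 0.001).
#' @param meanDegree mean degree of the random coupling graph (default 4).
#' @param D noise intensity (default 0.01).
#' @param dtIntegration Euler-Maruyama step (default 0.01 time units).
#' @param sampleInterval recording interval (default 1 time unit; the
#'   oscillators' rotation then appears near 0.16 cycles/sample).
#' @param transient time units discarded before recording (default 200).
#' @param adjacency optional adjacency matrix overriding the random graph.
#' @param seed optional integer seed.
#' @return A [SimulatedDataset-class] (`nOscillators x nSamples`,
#'   sampling rate `1/sampleInterval`, ground-truth window
#'   `couplingWindow`). The adjacency and frequencies used are in `params`.
#' @export
simulateRossler <- function(nOscillators = 10L, omegaRange = c(0.98, 1.1),
                            nSamples = 1200L, couplingWindow = c(500, 900),
                            lambdaOn = 0.5, lambdaOff = 0.001,
                            meanDegree = 4, D = 0.01, dtIntegration = 0.01,
                            sampleInterval = 1, transient = 200,
                            adjacency = NULL, seed = NULL) {
  if (dtIntegration >= sampleInterval)
    stop("'dtIntegration' must be much smaller than 'sampleInterval'")
  if (D < 0) stop("'D' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  M <- as.integer(nOscillators)
  if (is.null(adjacency)) adjacency <- randomMeanDegreeGraph(M, meanDegree)
  if (!isTRUE(all.equal(adjacency, t(adjacency))) ||
      any(diag(adjacency) != 0))
    stop("'adjacency' must be symmetric with zero diagonal")
  deg <- rowSums(adjacency)
  omega <- stats::runif(M, omegaRange[1L], omegaRange[2L])

  x <- stats::runif(M, -5, 5); y <- stats::runif(M, -5, 5)
  z <- stats::runif(M, 0, 1)
  dt <- dtIntegration
  noiseSd <- sqrt(2 * D * dt)
  stepsPerSample <- round(sampleInterval / dt)
  nTransient <- round(transient / dt)
  out <- matrix(NA_real_, M, nSamples)
  total <- nTransient + nSamples * stepsPerSample
  recIdx <- 0L
  for (s in seq_len(total)) {
    # recorded time of the current step; the coupling schedule is stated in
    # recorded-sample units
    tRec <- (s - nTransient) * dt / sampleInterval
    lam <- if (tRec > couplingWindow[1L] && tRec < couplingWindow[2L])
      lambdaOn else lambdaOff
    coup <- lam * (drop(adjacency %*% x) - deg * x)
    dx <- -omega * y - z + coup
    dy <- omega * x + 0.165 * y
    dz <- 0.2 + z * (x - 10)
    x <- x + dt * dx + if (noiseSd > 0) stats::rnorm(M, sd = noiseSd) else 0
    y <- y + dt * dy
    z <- z + dt * dz
    if (max(abs(x), abs(y), abs(z)) > 1e4)
      stop("Rossler trajectory escaped (seed ",
           if (is.null(seed)) "unset" else seed, ", step ", s, ")")
    if (s > nTransient && (s - nTransient) %% stepsPerSample == 0L) {
      recIdx <- recIdx + 1L
      out[, recIdx] <- x
    }
  }
  new("SimulatedDataset", data = out, samplingRate = 1 / sampleInterval,
      groundTruthWindow = as.numeric(couplingWindow), model = "rossler",
      params = list(nOscillators = M, omegaRange = omegaRange,
                    nSamples = nSamples, couplingWindow = couplingWindow,
                    lambdaOn = lambdaOn, lambdaOff = lambdaOff,
                    meanDegree = meanDegree, D = D,
                    dtIntegration = dtIntegration,
                    sampleInterval = sampleInterval, transient = transient,
                    adjacency = adjacency, omega = omega, seed = seed))
}
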