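# Shared fixtures built in code.

# Linear chirp with instantaneous frequency sweeping f0 -> f1 (cycles per
# sample) over n samples.
chirpSignal <- function(n, f0, f1) {
  cos(2 * pi * cumsum(seq(f0, f1, length.out = n)))
}

# Two-component band-limited test signal.
twoChirps <- function(n) {
  chirpSignal(n, 0.05, 0.12) + chirpSignal(n, 0.13, 0.2)
}

defaultGrid <- function(nFreqs = 40, fMin = 0.02, fMax = 0.4) {
  morletParams(makeFrequencyGrid(fMin, fMax, nFreqs), samplingRate = 1)
}

# Time columns inside the COI at every grid frequency.
interiorCols <- function(params, n) {
  t <- (seq_len(n) - 1L) / params@samplingRate
  hw <- max(coneOfInfluence(params, n))
  which(pmin(t, t[n] - t) >= hw)
}

# Power-iteration largest eigenvalue of one Hermitian matrix: the
# independent oracle for the compiled eigen path. Iterates on the shifted
# matrix A + M I (all eigenvalues positive by Gershgorin for unit-diagonal
# matrices with bounded entries) so convergence is to the algebraically
# largest eigenvalue, then removes the shift.
powerIterLambdaMax <- function(A, iters = 2000, tol = 1e-14) {
  M <- nrow(A)
  B <- A + diag(M + 0i, M)
  v <- complex(real = seq_len(M), imaginary = rev(seq_len(M)))
  v <- v / sqrt(sum(Mod(v)^2))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- as.vector(B %*% v)
    lamNew <- Re(sum(Conj(v) * w))
    v <- w / sqrt(sum(Mod(w)^2))
    if (abs(lamNew - lam) < tol * max(1, abs(lamNew))) break
    lam <- lamNew
  }
  Re(sum(Conj(v) * as.vector(B %*% v))) - M
}

# Random Hermitian unit-diagonal matrix with |off-diagonal| <= 1.
randomCoherenceMatrix <- function(M) {
  A <- matrix(complex(real = stats::runif(M * M, -0.7, 0.7),
                      imaginary = stats::runif(M * M, -0.7, 0.7)), M, M)
  A <- (A + Conj(t(A))) / 2
  diag(A) <- 1
  A
}
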