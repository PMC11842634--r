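## Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache, inherits = FALSE))
    assign(name, expr, envir = .fixtureCache)
  get(name, envir = .fixtureCache, inherits = FALSE)
}

## noiseless, artifact-free, fully phase-locked configuration
quietConfig <- function(errorProb = 0, ...) {
  simConfig(noiseSigma = 0, couplingEffect = 0, artifactRate = 0,
            errorProb = errorProb, ...)
}

zeroGain <- function() {
  stats::setNames(rep(0, 12),
                  c("O1", "O2", "P3", "P4", "Pz", "C3", "C4", "Cz",
                    "F3", "F4", "Fz", "Fpz"))
}

## a clean 20-window phase-locked session, F3-filtered (continuous)
quietF3Session <- function() fixture("quietF3", {
  ses <- simulateSession(quietConfig(nEpisodes = 1L,
                                     actionsPerEpisode = 20L, seed = 3L))
  bandpassFilter(ses, bandConfig("F3"), continuous = TRUE)
})

## a default-condition session (noise 3 uV, coupling on), 120 trials
defaultSession <- function() fixture("default120", {
  simulateSession(simConfig(nEpisodes = 4L, actionsPerEpisode = 30L,
                            seed = 7L))
})

## brute-force O(N^2) DFT-based analytic-signal oracle (independent of the
## package's FFT path)
hilbertOracleImag <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  X <- as.vector(W %*% x)                     # direct DFT
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  z <- as.vector(Conj(W) %*% (X * h)) / n     # inverse DFT
  Im(z)
}

## brute-force unnormalized cross-correlation oracle
xcorrOracle <- function(response, template, nDelays) {
  L <- length(template)
  vapply(seq_len(nDelays) - 1L, function(tau) {
    s <- 0
    for (k in seq_len(L)) s <- s + template[k] * response[k + tau]
    s
  }, numeric(1))
}

## two-sided Butterworth band-pass magnitude response (squared for the
## forward-backward pass), evaluated analytically from the coefficients
butterMag2 <- function(lowHz, highHz, fHz, fs = 125, order = 4) {
  bt <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  w <- 2 * pi * fHz / fs
  zb <- sum(bt$b * exp(-1i * w * (seq_along(bt$b) - 1)))
  za <- sum(bt$a * exp(-1i * w * (seq_along(bt$a) - 1)))
  Mod(zb / za)^2
}
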