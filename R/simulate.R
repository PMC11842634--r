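## Synthetic response-coupled EEG generator.
##
## Every epoch is the sum of: 1/f background noise, a phase-locked SSVEP
## whose envelope follows the flicker (delayed by responseDelayS, active for
## activeS), an ErrP transient on error trials, an error-trial coupling
## perturbation of the SSVEP, and occasional spike/blink artifacts.

## Deterministic per-trial seed derivation (Lehmer step, keeps values < 2^31)
.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i) %% 2147483647)
}

.localSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate the maze agent's action labels
#'
#' Independent Bernoulli draws: with probability `errorProb` an action is an
#' agent error (eliciting an ErrP in the observer), otherwise a correct move.
#'
#' @param errorProb per-action error probability in [0, 1]
#' @param nActions number of actions (>= 1)
#' @param seed integer seed
#' @return factor of length `nActions` with levels `error`, `non-error`
#' @examples
#' table(simulateAgentActions(0.2, 1000, seed = 1))
#' @export
simulateAgentActions <- function(errorProb, nActions, seed = 1L) {
  if (errorProb < 0 || errorProb > 1)
    stop("errorProb must lie in [0, 1]")
  if (nActions < 1) stop("nActions must be >= 1")
  draws <- .localSeed(seed, stats::rbinom(nActions, 1L, errorProb))
  factor(ifelse(draws == 1L, "error", "non-error"),
         levels = c("error", "non-error"))
}

#' Biphasic theta-band ErrP template
#'
#' A Gaussian-windowed theta oscillation with a negative deflection near
#' 250 ms and a positive deflection near 320 ms after action onset, peak
#' absolute amplitude 1 (scaled per channel by the config's `errpGain`).
#' Dominant spectral energy sits in the 4-8 Hz theta band. The waveform is
#' an assumption of the generator: the shape is chosen for theta dominance
#' and typical ErrP morphology, not fitted to any recording.
#'
#' @param samplingRate Hz
#' @param windowS window length in seconds
#' @param negPeakS,posPeakS latencies (s) of the negative/positive peaks
#' @return numeric waveform of `round(windowS * samplingRate)` samples
#' @export
errpTemplate <- function(samplingRate = 125, windowS = 1.8,
                         negPeakS = 0.25, posPeakS = 0.32) {
  n <- as.integer(round(windowS * samplingRate))
  t <- (seq_len(n) - 1L) / samplingRate
  f <- 1 / (2 * (posPeakS - negPeakS))        # half period between the peaks
  center <- (negPeakS + posPeakS) / 2
  w <- exp(-((t - center) / 0.09)^2) * cos(2 * pi * f * (t - negPeakS) + pi)
  w / max(abs(w))
}

#' Seeded 1/f (pink) background noise
#'
#' Spectral shaping of white Gaussian noise with a 1/sqrt(f) amplitude
#' profile, rescaled to unit standard deviation.
#'
#' @param n samples
#' @param seed integer seed
#' @return numeric vector of length `n`, sd 1
#' @export
pinkNoise <- function(n, seed = 1L) {
  white <- .localSeed(seed, stats::rnorm(n))
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                    # DC kept at weight of bin 1
  f <- pmin(f, n - f + 1)                      # mirrored for negative freqs
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

.ssvepComponent <- function(config, label, jitterRad) {
  fs <- config@samplingRate
  n <- windowSamples(config)
  t <- (seq_len(n) - 1L) / fs
  active <- t >= config@responseDelayS &
    t < config@responseDelayS + config@activeS
  amp <- 1
  phi <- config@phaseLagRad
  if (label == "error" && config@couplingEffect != 0) {
    amp <- 1 - config@couplingEffect
    phi <- phi + jitterRad
  }
  ## carrier phase is absolute (sin(2*pi*F0*t + phi)) so the cross-correlation
  ## with the stimulus template is proportional to cos(2*pi*F0*tau + phi)
  out <- amp * sin(2 * pi * config@flickerHz * t + phi) * active
  ## the lagged response persists past the window edge: the spill-over of the
  ## previous window's response occupies the first responseDelayS + activeS -
  ## windowS seconds, phase-continuous with the previous window's carrier
  spill <- config@responseDelayS + config@activeS - config@windowS
  if (spill > 0) {
    head <- t < spill
    out[head] <- amp * sin(2 * pi * config@flickerHz *
                             (t[head] + config@windowS) + phi)
  }
  out
}

.injectArtifact <- function(epoch, config, kind, at, chIdx) {
  n <- ncol(epoch)
  if (kind == "spike") {
    idx <- at:min(n, at + 2L)
    epoch[chIdx, idx] <- epoch[chIdx, idx] + 100   # > 75 uV threshold
  } else {                                          # blink at frontal sites
    frontal <- which(rownames(epoch) %in% c("Fpz", "F3", "F4", "Fz"))
    if (!length(frontal)) frontal <- chIdx
    t <- seq_len(n)
    bump <- 130 * exp(-((t - at) / (0.05 * n))^2)
    epoch[frontal, ] <- epoch[frontal, ] + rep(bump, each = length(frontal))
  }
  epoch
}

#' Synthesize one coupled-EEG epoch
#'
#' Composes pink noise, the phase-locked SSVEP (per-channel `ssvepGain`,
#' strongest over parieto-occipital sites), the ErrP transient on error
#' trials (per-channel `errpGain`, strongest fronto-centrally), the
#' error-trial coupling perturbation, and optional artifacts.
#'
#' @param config a \linkS4class{SimConfig}
#' @param label `"error"` or `"non-error"`
#' @param trialSeed integer seed for this trial's noise/artifacts
#' @return channels x samples microvolt matrix
#' @export
synthEpoch <- function(config, label = "non-error", trialSeed = 1L) {
  validObject(config)
  label <- match.arg(label, c("error", "non-error"))
  fs <- config@samplingRate
  n <- windowSamples(config)
  nc <- length(config@channels)
  draws <- .localSeed(trialSeed, list(
    noiseSeeds = sample.int(2^30, nc),
    jitter = stats::rnorm(1, 0, config@couplingEffect * 0.5),
    artifactU = stats::runif(1),
    artifactKind = sample(c("spike", "blink"), 1),
    artifactAt = sample.int(n - 3L, 1),
    artifactCh = sample.int(nc, 1)))
  epoch <- matrix(0, nc, n, dimnames = list(config@channels, NULL))
  if (config@noiseSigma > 0)
    for (c in seq_len(nc))
      epoch[c, ] <- config@noiseSigma * pinkNoise(n, draws$noiseSeeds[c])
  ssvep <- .ssvepComponent(config, label, draws$jitter)
  epoch <- epoch + config@ssvepGain[config@channels] %o% ssvep
  if (label == "error") {
    tmpl <- errpTemplate(fs, config@windowS)
    epoch <- epoch + config@errpGain[config@channels] %o% tmpl
  }
  if (config@artifactRate > 0 && draws$artifactU < config@artifactRate)
    epoch <- .injectArtifact(epoch, config, draws$artifactKind,
                             draws$artifactAt, draws$artifactCh)
  epoch
}

#' Simulate a full session for one user
#'
#' `nEpisodes * actionsPerEpisode` consecutive action windows with labels
#' drawn by [simulateAgentActions()]; deterministic for a fixed config.
#'
#' @param config a \linkS4class{SimConfig}
#' @param userId identifier
#' @return an \linkS4class{EpochSet}
#' @examples
#' ses <- simulateSession(simConfig(nEpisodes = 1, actionsPerEpisode = 4))
#' dim(epochs(ses))  # 4 x 12 x 225
#' @export
simulateSession <- function(config, userId = "user01") {
  validObject(config)
  nTr <- config@nEpisodes * config@actionsPerEpisode
  labs <- simulateAgentActions(config@errorProb, nTr, seed = config@seed)
  n <- windowSamples(config)
  arr <- array(0, dim = c(nTr, length(config@channels), n),
               dimnames = list(NULL, config@channels, NULL))
  for (i in seq_len(nTr))
    arr[i, , ] <- synthEpoch(config, as.character(labs[i]),
                             .deriveSeed(config@seed, i))
  epochSet(arr, labs, onsets = as.integer((seq_len(nTr) - 1L) * n),
           samplingRate = config@samplingRate, channels = config@channels,
           userId = userId, config = config)
}

#' Simulate a cohort with per-user noise levels
#'
#' One session per user, sharing `baseConfig` except for a user-specific
#' `noiseSigma` and a derived seed. The noise ramp is the handle that makes
#' SSVEP fidelity and detection accuracy co-vary across users.
#'
#' @param nUsers number of users
#' @param perUserNoise numeric vector of per-user noise sigmas (microvolts),
#'   length `nUsers`
#' @param baseConfig a \linkS4class{SimConfig}
#' @param seed integer cohort seed
#' @return named list of \linkS4class{EpochSet}s
#' @export
simulateCohort <- function(nUsers, perUserNoise, baseConfig = simConfig(),
                           seed = 1L) {
  if (length(perUserNoise) != nUsers)
    stop("perUserNoise must have length nUsers")
  out <- vector("list", nUsers)
  for (u in seq_len(nUsers)) {
    cfg <- baseConfig
    cfg@noiseSigma <- perUserNoise[u]
    cfg@seed <- .deriveSeed(seed, u * 1000L)
    out[[u]] <- simulateSession(cfg, userId = sprintf("user%02d", u))
  }
  names(out) <- vapply(out, userId, character(1))
  out
}
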