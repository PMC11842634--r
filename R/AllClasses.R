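#' @import methods
NULL

## Default 12-channel montage used throughout: parieto-occipital first,
## then fronto-central, matching the E3/E2 split.
.MONTAGE12 <- c("O1", "O2", "P3", "P4", "Pz",
                "C3", "C4", "Cz", "F3", "F4", "Fz", "Fpz")

.defaultSsvepGain <- function() {
  c(O1 = 1.3, O2 = 1.3, P3 = 1.0, P4 = 1.0, Pz = 1.0,
    C3 = 0.2, C4 = 0.2, Cz = 0.2, F3 = 0.15, F4 = 0.15, Fz = 0.15,
    Fpz = 0.1)
}

.defaultErrpGain <- function() {
  c(O1 = 0.4, O2 = 0.4, P3 = 0.6, P4 = 0.6, Pz = 0.8,
    C3 = 2.0, C4 = 2.0, Cz = 3.0, F3 = 2.0, F4 = 2.0, Fz = 2.6,
    Fpz = 1.0)
}

#' Simulation configuration for a response-coupled EEG session
#'
#' Holds every parameter of the generative model: the action-window
#' geometry (1.8 s = 1.6 s active 12.5 Hz flicker + 200 ms flicker-off),
#' the agent error probability, the stimulus-to-response phase lag and
#' envelope delay of the SSVEP, per-channel SSVEP/ErrP gains in microvolts,
#' the error-trial coupling perturbation, pink-noise level, artifact rate
#' and the master seed.
#'
#' @slot samplingRate sampling rate in Hz
#' @slot channels ordered montage labels
#' @slot windowS,activeS,offS action-window, flicker-on and flicker-off
#'   durations in seconds; `windowS == activeS + offS`
#' @slot flickerHz flicker (SSVEP) frequency in Hz
#' @slot errorProb per-action probability of an agent error
#' @slot nEpisodes,actionsPerEpisode session size
#' @slot phaseLagRad stimulus-to-response carrier phase lag in radians
#' @slot responseDelayS SSVEP envelope onset delay in seconds
#' @slot ssvepGain,errpGain named per-channel amplitudes in microvolts
#' @slot couplingEffect fractional SSVEP amplitude attenuation (plus phase
#'   jitter of the same magnitude in radians) on error trials
#' @slot noiseSigma pink-noise standard deviation in microvolts
#' @slot artifactRate per-trial probability of an injected spike/blink
#' @slot seed master integer seed
#' @export
setClass("SimConfig",
  representation(samplingRate = "numeric", channels = "character",
    windowS = "numeric", activeS = "numeric", offS = "numeric",
    flickerHz = "numeric", errorProb = "numeric",
    nEpisodes = "integer", actionsPerEpisode = "integer",
    phaseLagRad = "numeric", responseDelayS = "numeric",
    ssvepGain = "numeric", errpGain = "numeric",
    couplingEffect = "numeric", noiseSigma = "numeric",
    artifactRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (abs(object@windowS - (object@activeS + object@offS)) > 1e-9)
    msg <- c(msg, "windowS must equal activeS + offS")
  if (object@errorProb < 0 || object@errorProb > 1)
    msg <- c(msg, "errorProb must lie in [0, 1]")
  if (object@samplingRate <= 2 * object@flickerHz)
    msg <- c(msg, "samplingRate must exceed twice flickerHz (Nyquist)")
  if (!all(object@channels %in% names(object@ssvepGain)))
    msg <- c(msg, "ssvepGain must name every channel")
  if (!all(object@channels %in% names(object@errpGain)))
    msg <- c(msg, "errpGain must name every channel")
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Build a SimConfig
#'
#' Defaults reproduce the study conditions the generator emulates: 125 Hz
#' sampling, the 12-channel montage, 1.8 s windows (1.6 s active flicker at
#' 12.5 Hz + 200 ms off), error probability 0.2, a 4.05 rad phase lag with a
#' 0.27 s response-envelope delay, and 10 episodes of 30 actions.
#'
#' @param samplingRate Hz
#' @param channels ordered montage labels
#' @param windowS,activeS,offS seconds
#' @param flickerHz Hz
#' @param errorProb probability of an agent error per action
#' @param nEpisodes,actionsPerEpisode session size
#' @param phaseLagRad radians
#' @param responseDelayS seconds
#' @param ssvepGain,errpGain named per-channel microvolt amplitudes
#' @param couplingEffect dimensionless error-trial SSVEP perturbation
#' @param noiseSigma microvolts
#' @param artifactRate per-trial artifact probability
#' @param seed integer master seed
#' @return a validated \linkS4class{SimConfig}
#' @examples
#' cfg <- simConfig(nEpisodes = 2, actionsPerEpisode = 5)
#' windowSamples(cfg)  # 225
#' @export
simConfig <- function(samplingRate = 125, channels = .MONTAGE12,
                      windowS = 1.8, activeS = 1.6, offS = 0.2,
                      flickerHz = 12.5, errorProb = 0.2,
                      nEpisodes = 10L, actionsPerEpisode = 30L,
                      phaseLagRad = 4.05, responseDelayS = 0.27,
                      ssvepGain = .defaultSsvepGain(),
                      errpGain = .defaultErrpGain(),
                      couplingEffect = 0.2, noiseSigma = 3,
                      artifactRate = 0.02, seed = 1L) {
  new("SimConfig", samplingRate = samplingRate, channels = channels,
      windowS = windowS, activeS = activeS, offS = offS,
      flickerHz = flickerHz, errorProb = errorProb,
      nEpisodes = as.integer(nEpisodes),
      actionsPerEpisode = as.integer(actionsPerEpisode),
      phaseLagRad = phaseLagRad, responseDelayS = responseDelayS,
      ssvepGain = ssvepGain, errpGain = errpGain,
      couplingEffect = couplingEffect, noiseSigma = noiseSigma,
      artifactRate = artifactRate, seed = as.integer(seed))
}

#' Samples per action window
#' @param config a \linkS4class{SimConfig}
#' @return integer number of samples in one action window
#' @export
windowSamples <- function(config) {
  as.integer(round(config@windowS * config@samplingRate))
}

#' Epoched EEG session container
#'
#' The central data object: a trials x channels x samples microvolt array
#' with per-trial labels (`error` / `non-error`), action-onset sample
#' indices (0-based, on the window grid), the sampling rate, montage and
#' the generating \linkS4class{SimConfig} (when simulated).
#'
#' @slot epochs numeric array, trials x channels x samples
#' @slot labels factor with levels `error`, `non-error`
#' @slot onsets integer 0-based onset sample of each action window
#' @slot samplingRate Hz
#' @slot channels montage labels (dimension 2 of `epochs`)
#' @slot userId identifier
#' @slot config the generating SimConfig, or NULL for imported data
#' @export
setClass("EpochSet",
  representation(epochs = "array", labels = "factor", onsets = "integer",
    samplingRate = "numeric", channels = "character", userId = "character",
    config = "ANY"))

setValidity("EpochSet", function(object) {
  d <- dim(object@epochs)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "epochs must be a 3-D trials x channels x samples array")
  else {
    if (d[2] != length(object@channels))
      msg <- c(msg, "channel count mismatch")
    if (d[1] != length(object@labels))
      msg <- c(msg, "labels length must equal trial count")
    if (d[1] != length(object@onsets))
      msg <- c(msg, "onsets length must equal trial count")
  }
  if (!all(levels(object@labels) %in% c("error", "non-error")))
    msg <- c(msg, "labels levels must be 'error'/'non-error'")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#' @param epochs trials x channels x samples array (microvolts)
#' @param labels character or factor of `error`/`non-error`
#' @param onsets 0-based onset samples (defaults to a contiguous grid)
#' @param samplingRate Hz
#' @param channels montage labels
#' @param userId identifier
#' @param config optional generating \linkS4class{SimConfig}
#' @return an \linkS4class{EpochSet}
#' @export
epochSet <- function(epochs, labels, onsets = NULL, samplingRate = 125,
                     channels = NULL, userId = "user", config = NULL) {
  if (is.null(channels)) {
    channels <- dimnames(epochs)[[2]]
    if (is.null(channels)) channels <- paste0("ch", seq_len(dim(epochs)[2]))
  }
  if (is.null(onsets))
    onsets <- as.integer((seq_len(dim(epochs)[1]) - 1L) * dim(epochs)[3])
  labels <- factor(as.character(labels), levels = c("error", "non-error"))
  new("EpochSet", epochs = epochs, labels = labels,
      onsets = as.integer(onsets), samplingRate = samplingRate,
      channels = channels, userId = userId, config = config)
}

#' Stimulus waveform template
#'
#' The analytic model of the flicker stimulus: `repetitions` concatenated
#' action windows, each an `activeS`-second sine at `f0` (amplitude `a0`)
#' followed by `offS` seconds of zeros.
#'
#' @slot samples amplitude series
#' @slot f0 flicker frequency (Hz)
#' @slot a0 amplitude
#' @slot activeS,offS seconds
#' @slot repetitions action-window repetition count (1..150)
#' @slot samplingRate Hz
#' @export
setClass("StimulusTemplate",
  representation(samples = "numeric", f0 = "numeric", a0 = "numeric",
    activeS = "numeric", offS = "numeric", repetitions = "integer",
    samplingRate = "numeric"))

setValidity("StimulusTemplate", function(object) {
  if (max(abs(object@samples)) > abs(object@a0) + 1e-9)
    "samples must be bounded by a0" else TRUE
})

#' Analytic signal (Hilbert construction)
#'
#' A real series plus i times its discrete Hilbert transform, with the
#' derived instantaneous envelope and wrapped phase.
#'
#' @slot real original series
#' @slot imag discrete Hilbert transform
#' @slot envelope instantaneous amplitude, >= 0
#' @slot phase instantaneous phase in (-pi, pi]
#' @export
setClass("AnalyticSignal",
  representation(real = "numeric", imag = "numeric",
    envelope = "numeric", phase = "numeric"))

setValidity("AnalyticSignal", function(object) {
  n <- length(object@real)
  if (length(object@imag) != n || length(object@envelope) != n ||
      length(object@phase) != n)
    return("component lengths must match")
  if (any(abs(object@envelope^2 - (object@real^2 + object@imag^2)) >
          1e-6 * (1 + max(object@envelope^2))))
    return("envelope^2 must equal real^2 + imag^2")
  TRUE
})

#' Cross-correlogram over an action window
#'
#' Unnormalized sliding inner product `C(tau)` of a stimulus template
#' against a response, at every integer-sample delay admissible within one
#' action window.
#'
#' @slot delayS delay axis in seconds
#' @slot values `C(tau)`
#' @slot windowId identifier of the action window
#' @export
setClass("Correlogram",
  representation(delayS = "numeric", values = "numeric",
    windowId = "integer"))

setValidity("Correlogram", function(object) {
  if (length(object@delayS) != length(object@values))
    "delay axis and values must have equal length" else TRUE
})

#' Histogram of cross-correlation peak delays
#'
#' @slot breaks bin edges in seconds
#' @slot counts per-bin counts of window-wise global-maximum delays
#' @slot mids bin centers in seconds
#' @slot modalZone center of the most populated bin (seconds)
#' @export
setClass("DelayHistogram",
  representation(breaks = "numeric", counts = "numeric", mids = "numeric",
    modalZone = "numeric"))

setValidity("DelayHistogram", function(object) {
  msg <- character()
  if (length(object@breaks) != length(object@counts) + 1L)
    msg <- c(msg, "breaks must have length(counts) + 1")
  if (length(object@mids) != length(object@counts))
    msg <- c(msg, "mids must match counts")
  if (length(object@counts) &&
      !isTRUE(all.equal(object@modalZone,
                        object@mids[which.max(object@counts)])))
    msg <- c(msg, "modalZone must be the center of the fullest bin")
  if (length(msg)) msg else TRUE
})

#' Stimulus-response phase-lag estimate
#'
#' Mean phase lag recovered from cross-correlation peak delays via the
#' maxima condition `2*pi*F0*tau + Phi = 2*n*pi`, with the equivalent
#' delay offset `delta = Phi / (2*pi*F0)`.
#'
#' @slot phiBar mean phase lag in [0, 2*pi)
#' @slot delta delay offset in seconds, exactly `phiBar / (2*pi*f0)`
#' @slot f0 flicker frequency (Hz)
#' @slot nWindows number of action windows aggregated
#' @export
setClass("PhaseLagEstimate",
  representation(phiBar = "numeric", delta = "numeric", f0 = "numeric",
    nWindows = "integer"))

setValidity("PhaseLagEstimate", function(object) {
  msg <- character()
  if (object@phiBar < 0 || object@phiBar >= 2 * pi)
    msg <- c(msg, "phiBar must lie in [0, 2*pi)")
  if (abs(object@delta - object@phiBar / (2 * pi * object@f0)) > 1e-12)
    msg <- c(msg, "delta must equal phiBar / (2*pi*f0)")
  if (length(msg)) msg else TRUE
})

#' Fitted xDAWN spatial-filter model
#'
#' Per-class least-squares evoked prototypes and spatial filters solving
#' the generalized eigenproblem that maximizes the evoked-to-total signal
#' power ratio.
#'
#' @slot filters named list (per class) of channels x nFilters matrices,
#'   unit-norm columns
#' @slot patterns named list of corresponding forward patterns
#' @slot prototypes named list of nFilters x samples filtered evoked
#'   prototypes
#' @slot evoked named list of channels x samples evoked estimates
#' @slot classes class labels, `error` then `non-error`
#' @slot nFilters filters retained per class
#' @slot channels montage the model was fitted on
#' @export
setClass("XdawnModel",
  representation(filters = "list", patterns = "list", prototypes = "list",
    evoked = "list", classes = "character", nFilters = "integer",
    channels = "character"))

setValidity("XdawnModel", function(object) {
  ok <- all(vapply(object@filters, function(f)
    all(abs(sqrt(colSums(f^2)) - 1) < 1e-6), logical(1)))
  if (!ok) "spatial filters must have unit-norm columns" else TRUE
})
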