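## Analytic signals, PLV, stimulus templates, cross-correlation delay
## analysis and stimulus-response phase-lag estimation.

.wrapPhase <- function(x) Arg(exp(1i * x))   # (-pi, pi]

#' Discrete analytic signal via the Hilbert transform
#'
#' FFT construction: negative-frequency components are zeroed and positive
#' ones doubled, giving `x + i*H(x)` whose modulus is the instantaneous
#' envelope and whose argument the instantaneous phase.
#'
#' @param x real numeric series, length >= 8
#' @return an \linkS4class{AnalyticSignal}
#' @examples
#' a <- hilbertAnalytic(cos(2 * pi * 12.5 * (0:199) / 125))
#' range(a@envelope)
#' @export
hilbertAnalytic <- function(x) {
  if (!is.numeric(x) || length(x) < 8) stop("x must be numeric, length >= 8")
  if (any(!is.finite(x))) stop("x must be finite")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  new("AnalyticSignal", real = x, imag = Im(z),
      envelope = Mod(z), phase = Arg(z))
}

#' Instantaneous stimulus-response phase lag
#'
#' Per-sample wrapped difference of the two instantaneous phase series,
#' `arg(e^{i*PhiR} * e^{-i*PhiS})`, in (-pi, pi].
#'
#' @param response,stimulus \linkS4class{AnalyticSignal}s of equal length
#' @return numeric phase-lag series in (-pi, pi]
#' @export
instantaneousPhaseLag <- function(response, stimulus) {
  stopifnot(is(response, "AnalyticSignal"), is(stimulus, "AnalyticSignal"))
  if (length(response@phase) != length(stimulus@phase))
    stop("response and stimulus must have equal length")
  .wrapPhase(response@phase - stimulus@phase)
}

#' Phase-locking value
#'
#' Modulus of the mean unit phasor of a phase-lag series:
#' `PLV = |mean(exp(i * dphi))|`, in [0, 1]. 1 means perfect locking.
#'
#' @param phaseLag numeric phase-lag series (radians), nonempty
#' @return scalar PLV
#' @export
plv <- function(phaseLag) {
  if (!length(phaseLag)) stop("phase-lag series must be nonempty")
  min(1, Mod(mean(exp(1i * phaseLag))))
}

#' Sliding-window PLV of a response against the stimulus
#'
#' The phase-lag series between the analytic response and analytic stimulus
#' is summarized by [plv()] over sliding windows of `windowS` seconds
#' (`floor(windowS * samplingRate)` samples) advanced by `stride` samples.
#'
#' @param response numeric response series
#' @param stimulus a \linkS4class{StimulusTemplate} or numeric series of
#'   the same length as `response`
#' @param windowS window length in seconds (default 0.5)
#' @param stride hop in samples (default 1)
#' @param samplingRate Hz (taken from the template when given)
#' @return list with `values`, `tS` (window start times), `windowSamples`,
#'   `stride`
#' @export
slidingPlv <- function(response, stimulus, windowS = 0.5, stride = 1L,
                       samplingRate = 125) {
  if (is(stimulus, "StimulusTemplate")) {
    samplingRate <- stimulus@samplingRate
    stimulus <- stimulus@samples
  }
  stimulus <- stimulus[seq_along(response)]
  w <- as.integer(floor(windowS * samplingRate))
  if (w > length(response)) stop("window longer than series")
  dphi <- instantaneousPhaseLag(hilbertAnalytic(response),
                                hilbertAnalytic(stimulus))
  starts <- seq.int(1L, length(response) - w + 1L, by = stride)
  vals <- vapply(starts, function(s) plv(dphi[s:(s + w - 1L)]), numeric(1))
  list(values = vals, tS = (starts - 1L) / samplingRate,
       windowSamples = w, stride = as.integer(stride))
}

#' Build the synthetic stimulus template
#'
#' `repetitions` concatenated action windows, each `activeS` seconds of
#' `a0 * sin(2*pi*f0*t)` followed by `offS` seconds of zeros (the
#' flicker-off anchor).
#'
#' @param f0 flicker frequency in Hz
#' @param a0 amplitude (the correlogram is scale-free in `a0`; default 1)
#' @param repetitions number of concatenated action windows, 1..150
#' @param samplingRate Hz
#' @param activeS,offS seconds
#' @return a \linkS4class{StimulusTemplate}
#' @examples
#' tpl <- makeStimulusTemplate(12.5, repetitions = 1)
#' length(tpl@samples)  # 225
#' @export
makeStimulusTemplate <- function(f0 = 12.5, a0 = 1, repetitions = 1L,
                                 samplingRate = 125, activeS = 1.6,
                                 offS = 0.2) {
  if (repetitions < 1 || repetitions > 150)
    stop("repetitions must lie in [1, 150]")
  nAct <- as.integer(round(activeS * samplingRate))
  nOff <- as.integer(round(offS * samplingRate))
  t <- (seq_len(nAct) - 1L) / samplingRate
  one <- c(a0 * sin(2 * pi * f0 * t), numeric(nOff))
  new("StimulusTemplate", samples = rep(one, repetitions), f0 = f0, a0 = a0,
      activeS = activeS, offS = offS, repetitions = as.integer(repetitions),
      samplingRate = samplingRate)
}

#' Cross-correlate a response with the stimulus template
#'
#' Unnormalized sliding inner product
#' `C(tau) = sum_k template[k] * response[k + tau]` at every integer-sample
#' delay `tau = 0 .. nDelays-1` (the admissible delay range of one action
#' window). No normalization is applied, matching the closed-form
#' correlogram whose constants scale but never shift the maxima.
#'
#' @param response numeric series, at least
#'   `length(template) + nDelays - 1` samples
#' @param template a \linkS4class{StimulusTemplate}
#' @param nDelays number of delays (default: one action window)
#' @param windowId identifier stored in the result
#' @return a \linkS4class{Correlogram}
#' @export
crossCorrelate <- function(response, template, nDelays = NULL,
                           windowId = 1L) {
  stopifnot(is(template, "StimulusTemplate"))
  tpl <- template@samples
  fs <- template@samplingRate
  if (is.null(nDelays))
    nDelays <- as.integer(round((template@activeS + template@offS) * fs))
  if (length(tpl) > length(response))
    stop("template longer than response")
  nDelays <- min(nDelays, length(response) - length(tpl) + 1L)
  L <- length(tpl)
  vals <- vapply(seq_len(nDelays) - 1L,
                 function(tau) sum(tpl * response[(tau + 1L):(tau + L)]),
                 numeric(1))
  new("Correlogram", delayS = (seq_len(nDelays) - 1L) / fs, values = vals,
      windowId = as.integer(windowId))
}

#' Local maxima of a correlogram
#'
#' Returns the delays of local maxima whose value is at least
#' `minProminence` times the global maximum, always including the global
#' maximum itself (endpoints included; ties broken toward the earliest
#' delay). An all-zero correlogram yields an empty result.
#'
#' @param correlogram a \linkS4class{Correlogram}
#' @param minProminence fraction of the global maximum (default 0.5)
#' @return numeric vector of delays in seconds (possibly empty)
#' @export
findCorrelationMaxima <- function(correlogram, minProminence = 0.5) {
  stopifnot(is(correlogram, "Correlogram"))
  v <- correlogram@values
  n <- length(v)
  if (!n || all(v == 0)) return(numeric(0))
  gmax <- max(v)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  isMax <- v > left & v >= right          # strict left, ties -> earliest
  isMax[which.max(v)] <- TRUE
  keep <- isMax & v >= minProminence * gmax
  correlogram@delayS[keep]
}

#' Histogram of per-window cross-correlation peak delays
#'
#' @param delays numeric vector of per-window global-maximum delays (s)
#' @param binS bin width in seconds (default one sample at 125 Hz, 8 ms,
#'   fine enough to resolve the 80 ms maxima lattice)
#' @param rangeS optional c(min, max) delay range for the bins
#' @return a \linkS4class{DelayHistogram}
#' @export
peakDelayHistogram <- function(delays, binS = 0.008, rangeS = NULL) {
  if (!length(delays)) stop("at least one window is required")
  if (is.null(rangeS)) rangeS <- range(delays)
  lo <- floor(rangeS[1] / binS) * binS
  hi <- ceiling((rangeS[2] + 1e-12) / binS) * binS
  if (hi <= lo) hi <- lo + binS
  breaks <- seq(lo, hi, by = binS)
  h <- graphics::hist(delays, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  new("DelayHistogram", breaks = h$breaks, counts = as.numeric(h$counts),
      mids = h$mids, modalZone = h$mids[which.max(h$counts)])
}

#' Delay lattice of the correlogram maxima condition
#'
#' Closed form of the maxima condition `2*pi*f0*tau + phiBar = 2*n*pi`:
#' `tau = n/f0 - phiBar/(2*pi*f0)`. At `f0 = 12.5` Hz successive maxima are
#' separated by 80 ms.
#'
#' @param phiBar mean phase lag in radians
#' @param f0 flicker frequency in Hz
#' @param n integer maxima indices
#' @return numeric delays in seconds
#' @examples
#' latticeDelays(4.05, 12.5, 4)  # ~0.27 s
#' @export
latticeDelays <- function(phiBar, f0 = 12.5, n = 1:4) {
  n / f0 - phiBar / (2 * pi * f0)
}

#' Estimate the mean phase lag from peak delays
#'
#' Inverts the maxima condition: each delay contributes a wrapped phase
#' `(-2*pi*f0*tau) mod 2*pi`; the estimate is their circular mean, mapped
#' to [0, 2*pi), with `delta = phiBar / (2*pi*f0)`.
#'
#' @param delays numeric peak delays in seconds, nonempty
#' @param f0 flicker frequency in Hz
#' @return a \linkS4class{PhaseLagEstimate}
#' @examples
#' estimatePhaseLag(0.26843, 12.5)  # ~4.05 rad
#' @export
estimatePhaseLag <- function(delays, f0 = 12.5) {
  if (!length(delays)) stop("delays must be nonempty")
  theta <- (-2 * pi * f0 * delays) %% (2 * pi)
  phiBar <- Arg(mean(exp(1i * theta))) %% (2 * pi)
  if (2 * pi - phiBar < 1e-9) phiBar <- 0   # snap the wrap-around boundary
  new("PhaseLagEstimate", phiBar = phiBar, delta = phiBar / (2 * pi * f0),
      f0 = f0, nWindows = length(delays))
}

## Internal: concatenate the (already preprocessed) O1/O2-average response
## of a session into one continuous series, trials in onset order.
.sessionResponse <- function(x, channels = c("O1", "O2")) {
  channels <- intersect(channels, channelNames(x))
  if (!length(channels)) stop("none of the requested channels present")
  sel <- selectElectrodes(x, channels)
  arr <- epochs(sel)
  ord <- order(onsets(sel))
  resp <- apply(arr[ord, , , drop = FALSE], c(1, 3), mean)  # trials x samples
  as.numeric(t(resp))
}

## Internal: per-window single-repetition correlogram matrix (nWin x W).
## C1[i, tau+1] = sum_k tpl1[k] * y[(i-1)W + tau + k]. Window i spills one
## window length into window i+1, so the last window is not computable.
## Because an r-repetition template is r concatenated copies of the
## single-window template, the r-repetition correlogram of window i is
## simply colSums(C1[i:(i+r-1), ]) -- sweeps over r are cumsum-cheap.
.sessionC1 <- function(y, tpl1, W) {
  nWin <- floor(length(y) / W)
  nAna <- max(0L, nWin - 1L)
  C1 <- matrix(NA_real_, nWin, W)
  if (nAna) {
    Y <- matrix(0, nAna, 2L * W - 1L)   # extended per-window segments
    for (i in seq_len(nAna))
      Y[i, ] <- y[((i - 1L) * W + 1L):((i + 1L) * W - 1L)]
    for (tau in 0:(W - 1L))
      C1[seq_len(nAna), tau + 1L] <-
        Y[, (tau + 1L):(tau + W), drop = FALSE] %*% tpl1
  }
  C1
}

## r-repetition correlograms from the single-rep matrix: rows are windows
## (only windows with i + r - 1 <= usable rows are returned).
.repCorrelograms <- function(C1, r) {
  usable <- which(stats::complete.cases(C1))
  if (!length(usable)) return(NULL)
  maxRow <- max(usable)
  nAna <- maxRow - r + 1L
  if (nAna < 1L) return(NULL)
  S <- apply(C1[seq_len(maxRow), , drop = FALSE], 2, cumsum)
  S <- rbind(0, S)
  Cr <- S[(r + 1L):(maxRow + 1L), , drop = FALSE] -
    S[1L:nAna, , drop = FALSE]
  rownames(Cr) <- as.character(seq_len(nAna))
  Cr
}

#' Per-window cross-correlation peak delays of a session
#'
#' The session's trials are concatenated (onset order) into a continuous
#' channel-average response; the stimulus template (with its repetition
#' count) is re-anchored at every action-window onset and cross-correlated
#' over the admissible delays of that window; the global-maximum delay per
#' analyzable window is returned. Windows too close to the end of the
#' recording to fit the template are skipped. The input is expected to be
#' band-passed (11-16 Hz) already; this function never looks at labels.
#'
#' @param x an \linkS4class{EpochSet} (preprocessed)
#' @param template a \linkS4class{StimulusTemplate}
#' @param channels channels averaged into the response (default O1, O2)
#' @param refine parabolic sub-sample refinement of each peak (default
#'   TRUE; at 125 Hz an integer-sample peak quantizes the implied phase to
#'   ~0.63 rad steps, so refinement matters for phase-lag estimation)
#' @return data.frame with `window` and `delayS`
#' @export
windowPeakDelays <- function(x, template, channels = c("O1", "O2"),
                             refine = TRUE) {
  stopifnot(is(x, "EpochSet"), is(template, "StimulusTemplate"))
  y <- .sessionResponse(x, channels)
  fs <- template@samplingRate
  W <- as.integer(round((template@activeS + template@offS) * fs))
  tpl1 <- template@samples[seq_len(W)]
  Cr <- .repCorrelograms(.sessionC1(y, tpl1, W), template@repetitions)
  if (is.null(Cr)) stop("no analyzable windows for this repetition count")
  peak <- .peakDelaysFromCr(Cr, fs, refine)
  data.frame(window = as.integer(rownames(Cr)), delayS = peak)
}

## global-maximum delay per correlogram row, optionally refined by a
## three-point parabolic fit around the peak
.peakDelaysFromCr <- function(Cr, fs, refine = TRUE) {
  idx <- apply(Cr, 1, which.max)
  delay <- (idx - 1L) / fs
  if (refine) {
    for (r in seq_along(idx)) {
      i <- idx[r]
      if (i > 1L && i < ncol(Cr)) {
        a <- Cr[r, i - 1L]; b <- Cr[r, i]; c <- Cr[r, i + 1L]
        den <- a - 2 * b + c
        if (den < 0) delay[r] <- delay[r] + (a - c) / (2 * den) / fs
      }
    }
  }
  delay
}
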