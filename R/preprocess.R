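## Filtering, channel-subset, artifact-rejection chain and the 9-cell
## spatio-spectral configuration grid.

.BANDS <- list(F1 = c(1, 40), F2 = c(10, 40), F3 = c(11, 16))
.ELECTRODES <- list(
  E1 = c("O1", "O2", "P3", "P4", "Pz", "C3", "C4", "Cz", "F3", "F4", "Fz", "Fpz"),
  E2 = c("C3", "C4", "Cz", "F3", "F4", "Fz", "Fpz"),
  E3 = c("O1", "O2", "P3", "P4", "Pz"))

#' Named band-pass configuration
#'
#' F1 = 1-40 Hz (broadband), F2 = 10-40 Hz (theta excluded), F3 = 11-16 Hz
#' (immediate neighborhood of the 12.5 Hz flicker).
#'
#' @param name one of `"F1"`, `"F2"`, `"F3"`
#' @return list with `name`, `lowHz`, `highHz`
#' @export
bandConfig <- function(name = c("F1", "F2", "F3")) {
  name <- match.arg(name)
  list(name = name, lowHz = .BANDS[[name]][1], highHz = .BANDS[[name]][2])
}

#' Named electrode-subset configuration
#'
#' E1 = all 12 channels, E2 = fronto-central, E3 = parieto-occipital.
#' E2 and E3 partition E1.
#'
#' @param name one of `"E1"`, `"E2"`, `"E3"`
#' @return list with `name` and `channels`
#' @export
electrodeConfig <- function(name = c("E1", "E2", "E3")) {
  name <- match.arg(name)
  list(name = name, channels = .ELECTRODES[[name]])
}

## zero-phase Butterworth band-pass of one series with reflection padding
.bpFilter <- function(x, filt, padLen) {
  padLen <- min(padLen, length(x) - 1L)
  padded <- c(2 * x[1] - rev(x[2:(padLen + 1L)]), x,
              2 * x[length(x)] - rev(x)[2:(padLen + 1L)])
  y <- signal::filtfilt(filt, padded)
  y[(padLen + 1L):(padLen + length(x))]
}

#' Zero-phase Butterworth band-pass filtering of epochs
#'
#' Each channel of each epoch is filtered forward-backward with a 4th-order
#' Butterworth band-pass (two-pass application doubles the effective
#' roll-off but leaves ERP latencies unshifted). Epochs are filtered
#' individually with reflection padding of one window length to suppress
#' edge transients.
#'
#' @param x an \linkS4class{EpochSet}
#' @param band a [bandConfig()] list (or any list with `lowHz`, `highHz`)
#' @param order filter order of the one-pass prototype
#' @param continuous when TRUE and the onsets form a contiguous grid, the
#'   trials are concatenated (onset order), filtered as one continuous
#'   recording and re-epoched — mirroring acquisition-side filtering and
#'   avoiding per-epoch boundary transients. Default FALSE (each epoch
#'   filtered individually).
#' @return the filtered \linkS4class{EpochSet}, shape preserved
#' @export
bandpassFilter <- function(x, band = bandConfig("F1"), order = 4,
                           continuous = FALSE) {
  stopifnot(is(x, "EpochSet"))
  nyq <- samplingRate(x) / 2
  if (band$highHz >= nyq || band$lowHz <= 0 || band$lowHz >= band$highHz)
    stop("band must satisfy 0 < low < high < samplingRate/2")
  filt <- signal::butter(order, c(band$lowHz, band$highHz) / nyq,
                         type = "pass")
  arr <- epochs(x)
  d <- dim(arr)
  ord <- order(onsets(x))
  contiguousGrid <- all(diff(sort(onsets(x))) == d[3])
  if (continuous && contiguousGrid && d[1] > 1L) {
    for (c in seq_len(d[2])) {
      y <- as.numeric(t(arr[ord, c, ]))
      y <- .bpFilter(y, filt, d[3])
      arr[ord, c, ] <- matrix(y, d[1], d[3], byrow = TRUE)
    }
  } else {
    for (i in seq_len(d[1]))
      for (c in seq_len(d[2]))
        arr[i, c, ] <- .bpFilter(arr[i, c, ], filt, d[3])
  }
  initialize(x, epochs = arr)
}

#' Select an ordered electrode subset
#'
#' @param x an \linkS4class{EpochSet}
#' @param config an [electrodeConfig()] list or a character vector of labels
#' @return an \linkS4class{EpochSet} restricted to the requested channels,
#'   in the requested order
#' @export
selectElectrodes <- function(x, config = electrodeConfig("E1")) {
  stopifnot(is(x, "EpochSet"))
  chans <- if (is.character(config)) config else config$channels
  missing <- setdiff(chans, channelNames(x))
  if (length(missing))
    stop("channel(s) not present in montage: ", paste(missing, collapse = ", "))
  idx <- match(chans, channelNames(x))
  new("EpochSet", epochs = x@epochs[, idx, , drop = FALSE],
      labels = x@labels, onsets = x@onsets, samplingRate = x@samplingRate,
      channels = chans, userId = x@userId, config = x@config)
}

#' Threshold-based artifact rejection
#'
#' A trial is flagged if on any channel the absolute deviation from that
#' channel's epoch mean exceeds `spikeUv`, or the peak-to-peak range
#' (max - min) exceeds `rangeUv`. Aggregation across channels is OR.
#'
#' @param x an \linkS4class{EpochSet}
#' @param spikeUv spike threshold in microvolts (default 75)
#' @param rangeUv peak-to-peak threshold in microvolts (default 125)
#' @return list with `kept` (surviving \linkS4class{EpochSet}) and `mask`
#'   (data.frame: trial, kept, reason)
#' @export
rejectArtifacts <- function(x, spikeUv = 75, rangeUv = 125) {
  stopifnot(is(x, "EpochSet"))
  if (spikeUv <= 0 || rangeUv <= 0) stop("thresholds must be positive")
  arr <- epochs(x)
  n <- nTrials(x)
  reason <- character(n)
  for (i in seq_len(n)) {
    ep <- arr[i, , , drop = TRUE]
    if (is.null(dim(ep))) ep <- matrix(ep, nrow = 1)
    dev <- abs(ep - rowMeans(ep))
    rng <- apply(ep, 1, max) - apply(ep, 1, min)
    if (any(dev > spikeUv)) reason[i] <- "spike"
    else if (any(rng > rangeUv)) reason[i] <- "range"
  }
  keep <- reason == ""
  list(kept = x[keep],
       mask = data.frame(trial = seq_len(n), kept = keep,
                         reason = ifelse(keep, "", reason)))
}

#' The 9-cell spatio-spectral configuration grid
#'
#' Cartesian product of the electrode subsets E1-E3 and bands F1-F3 in
#' fixed order E1F1, E1F2, ..., E3F3.
#'
#' @return named list of 9 `list(electrodes =, band =)` cells
#' @examples
#' names(spatioSpectralGrid())
#' @export
spatioSpectralGrid <- function() {
  cells <- list()
  for (e in c("E1", "E2", "E3"))
    for (f in c("F1", "F2", "F3"))
      cells[[paste0(e, f)]] <- list(electrodes = electrodeConfig(e),
                                    band = bandConfig(f))
  cells
}
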