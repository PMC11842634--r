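#' Accessors for EpochSet and friends
#'
#' `epochs()` returns the trials x channels x samples array, `trialLabels()`
#' the per-trial factor, `onsets()` the 0-based onset samples,
#' `channelNames()` the montage, `samplingRate()` the rate in Hz and
#' `nTrials()` the trial count.
#'
#' @param x an \linkS4class{EpochSet}
#' @return the corresponding slot value
#' @name EpochSet-accessors
#' @aliases epochs trialLabels onsets channelNames samplingRate nTrials
NULL

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("userId", function(x) standardGeneric("userId"))

#' @rdname EpochSet-accessors
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @rdname EpochSet-accessors
setMethod("trialLabels", "EpochSet", function(x) x@labels)
#' @rdname EpochSet-accessors
setMethod("onsets", "EpochSet", function(x) x@onsets)
#' @rdname EpochSet-accessors
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @rdname EpochSet-accessors
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
#' @rdname EpochSet-accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@epochs)[1])
#' @rdname EpochSet-accessors
setMethod("userId", "EpochSet", function(x) x@userId)

#' Subset trials of an EpochSet
#' @param x an \linkS4class{EpochSet}
#' @param i trial indices (numeric or logical)
#' @param j,...,drop ignored
#' @return an \linkS4class{EpochSet} with the selected trials
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nTrials(x))[i]
  new("EpochSet", epochs = x@epochs[idx, , , drop = FALSE],
      labels = x@labels[idx], onsets = x@onsets[idx],
      samplingRate = x@samplingRate, channels = x@channels,
      userId = x@userId, config = x@config)
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet '%s': %d trials x %d channels x %d samples @ %g Hz\n",
              object@userId, d[1], d[2], d[3], object@samplingRate))
  tab <- table(object@labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n  channels:", paste(object@channels, collapse = " "), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %g Hz, %d ch, window %.1fs ",
                     "(%.1fs flicker @ %.1f Hz + %.1fs off)\n"),
              object@samplingRate, length(object@channels), object@windowS,
              object@activeS, object@flickerHz, object@offS))
  cat(sprintf("  errorProb %.2f, phase lag %.2f rad, delay %.2fs, noise %.1f uV, seed %d\n",
              object@errorProb, object@phaseLagRad, object@responseDelayS,
              object@noiseSigma, object@seed))
})

setMethod("show", "StimulusTemplate", function(object) {
  cat(sprintf("StimulusTemplate: %d rep(s) of %.1fs sine @ %g Hz + %.1fs off (%d samples)\n",
              object@repetitions, object@activeS, object@f0, object@offS,
              length(object@samples)))
})

setMethod("show", "Correlogram", function(object) {
  cat(sprintf("Correlogram (window %d): %d delays in [%.3f, %.3f] s\n",
              object@windowId, length(object@values),
              min(object@delayS), max(object@delayS)))
})

setMethod("show", "DelayHistogram", function(object) {
  cat(sprintf("DelayHistogram: %d windows in %d bins, modal zone %.3f s\n",
              sum(object@counts), length(object@counts), object@modalZone))
})

setMethod("show", "PhaseLagEstimate", function(object) {
  cat(sprintf("PhaseLagEstimate: phiBar %.3f rad, delta %.4f s (F0 %g Hz, %d windows)\n",
              object@phiBar, object@delta, object@f0, object@nWindows))
})

setMethod("show", "XdawnModel", function(object) {
  cat(sprintf("XdawnModel: %d filters/class on %d channels (%s)\n",
              object@nFilters, length(object@channels),
              paste(object@classes, collapse = " vs ")))
})
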