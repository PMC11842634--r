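## Plain-text session interchange: one delimited epoch matrix per session
## (long layout: trial, channel, sample columns) plus a CSV event table
## and a YAML copy of the generating configuration.

#' Write a session to a directory of delimited files
#'
#' Produces `epochs.tsv` (rows = trial x channel, columns `trial`,
#' `channel`, `s0...s<n-1>` in microvolts), `events.csv` (columns `trial`,
#' `onset_sample`, `label`) and, when the session carries a
#' \linkS4class{SimConfig}, `config.yaml`.
#'
#' @param x an \linkS4class{EpochSet}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeSessionData <- function(x, dir) {
  stopifnot(is(x, "EpochSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- epochs(x)
  d <- dim(arr)
  flat <- matrix(aperm(arr, c(2, 1, 3)), d[1] * d[2], d[3])
  df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                   channel = rep(channelNames(x), d[1]), flat)
  names(df)[-(1:2)] <- paste0("s", seq_len(d[3]) - 1L)
  epochsPath <- file.path(dir, "epochs.tsv")
  utils::write.table(df, epochsPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  eventsPath <- file.path(dir, "events.csv")
  utils::write.csv(data.frame(trial = seq_len(d[1]),
                              onset_sample = onsets(x),
                              label = as.character(trialLabels(x))),
                   eventsPath, row.names = FALSE)
  paths <- c(epochsPath, eventsPath)
  if (is(x@config, "SimConfig")) {
    cfgPath <- file.path(dir, "config.yaml")
    writeSimConfig(x@config, cfgPath)
    paths <- c(paths, cfgPath)
  }
  invisible(paths)
}

#' Read a session written by [writeSessionData()]
#'
#' @param dir directory containing `epochs.tsv` and `events.csv`
#' @param samplingRate Hz (overridden by `config.yaml` when present)
#' @param userId identifier
#' @return an \linkS4class{EpochSet}
#' @export
readSessionData <- function(dir, samplingRate = 125, userId = basename(dir)) {
  df <- utils::read.delim(file.path(dir, "epochs.tsv"))
  events <- utils::read.csv(file.path(dir, "events.csv"))
  channels <- unique(df$channel)
  nTr <- max(df$trial)
  ns <- ncol(df) - 2L
  arr <- array(0, c(nTr, length(channels), ns),
               dimnames = list(NULL, channels, NULL))
  mat <- as.matrix(df[, -(1:2)])
  for (r in seq_len(nrow(df)))
    arr[df$trial[r], match(df$channel[r], channels), ] <- mat[r, ]
  config <- NULL
  cfgPath <- file.path(dir, "config.yaml")
  if (file.exists(cfgPath)) {
    config <- readSimConfig(cfgPath)
    samplingRate <- config@samplingRate
  }
  epochSet(arr, events$label[order(events$trial)],
           onsets = events$onset_sample[order(events$trial)],
           samplingRate = samplingRate, channels = channels,
           userId = userId, config = config)
}

#' Serialize a SimConfig to YAML / read it back
#'
#' Field names mirror the configuration slots, so a hand-written YAML file
#' with the same keys is accepted.
#'
#' @param config a \linkS4class{SimConfig}
#' @param path YAML file path
#' @return `writeSimConfig`: the path, invisibly; `readSimConfig`: a
#'   \linkS4class{SimConfig}
#' @export
writeSimConfig <- function(config, path) {
  fields <- slotNames(config)
  lst <- lapply(fields, function(f) {
    v <- slot(config, f)
    if (!is.null(names(v))) as.list(v) else v
  })
  names(lst) <- fields
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  for (f in c("ssvepGain", "errpGain"))
    if (is.list(lst[[f]])) lst[[f]] <- unlist(lst[[f]])
  do.call(simConfig, lst)
}

#' Basic spectrogram of a single series
#'
#' Short-time Fourier magnitude via `signal::specgram`, returned as a
#' plain list for programmatic use (no claims attached; a convenience for
#' inspecting the 12.5 Hz band and theta-band transients).
#'
#' @param x numeric series
#' @param samplingRate Hz
#' @param windowSamples STFT window length (default 64)
#' @param overlap fractional overlap (default 0.75)
#' @return list with `power` (freq x time), `freqHz`, `tS`
#' @export
epochSpectrogram <- function(x, samplingRate = 125, windowSamples = 64L,
                             overlap = 0.75) {
  sg <- signal::specgram(x, n = windowSamples, Fs = samplingRate,
                         overlap = floor(windowSamples * overlap))
  list(power = Mod(sg$S)^2, freqHz = as.numeric(sg$f),
       tS = as.numeric(sg$t))
}
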