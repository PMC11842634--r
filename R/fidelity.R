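## Unsupervised SSVEP fidelity score, its repetition sweep, and the
## correlation analysis against detection accuracy.
##
## The score contrasts observed cross-correlation peak latencies with the
## hypothetical ideal scenario in which every action window peaks at one
## fixed delay from the stimulus. It never reads trial labels.

.fidelityFromDelays <- function(delayS, modalZone, toleranceS, W, fs,
                                method) {
  if (method == "inzone") {
    mean(abs(delayS - modalZone) <= toleranceS + 1e-12)
  } else {                         # negative MAD from modal delay, rescaled
    maxDev <- max(modalZone, (W - 1) / fs - modalZone)
    1 - mean(abs(delayS - modalZone)) / maxDev
  }
}

#' Unsupervised SSVEP fidelity score
#'
#' Fraction of analyzable action windows whose global cross-correlation
#' maximum delay falls within `toleranceS` of the modal delay zone
#' (`method = "inzone"`, the default). The ideal scenario -- every window
#' peaking at the fixed modal delay -- scores 1. The alternative
#' `method = "mad"` returns one minus the mean absolute deviation from the
#' modal delay, rescaled by the largest possible deviation. Both are
#' interpretations of an expected-vs-observed peak-latency discrepancy;
#' neither reads trial labels.
#'
#' @param x an \linkS4class{EpochSet}, band-passed 11-16 Hz (see
#'   [bandpassFilter()]); the O1/O2 average is used as the response
#' @param template a \linkS4class{StimulusTemplate} (its repetition count
#'   sets how many windows each correlation integrates over)
#' @param modalZone modal delay in seconds; when `NULL`, estimated from
#'   this session's own peak-delay histogram
#' @param toleranceS half-width of the accepted zone in seconds (default
#'   0.04, half an SSVEP period at 12.5 Hz)
#' @param channels response channels (default O1, O2)
#' @param method `"inzone"` or `"mad"`
#' @return scalar score in [0, 1], with attributes `nWindows`, `modalZone`
#'   and `repetitions`
#' @export
fidelityScore <- function(x, template = makeStimulusTemplate(),
                          modalZone = NULL, toleranceS = 0.04,
                          channels = c("O1", "O2"),
                          method = c("inzone", "mad")) {
  method <- match.arg(method)
  pd <- windowPeakDelays(x, template, channels)
  if (!nrow(pd)) stop("zero analyzable windows")
  fs <- template@samplingRate
  W <- as.integer(round((template@activeS + template@offS) * fs))
  if (is.null(modalZone))
    modalZone <- peakDelayHistogram(pd$delayS)@modalZone
  s <- .fidelityFromDelays(pd$delayS, modalZone, toleranceS, W, fs, method)
  structure(s, nWindows = nrow(pd), modalZone = modalZone,
            repetitions = template@repetitions)
}

#' Fidelity scores across stimulus-template repetitions
#'
#' Evaluates [fidelityScore()] with an `r`-repetition template for every
#' requested `r` (1..150). The single-repetition per-window correlograms
#' are computed once and accumulated across windows, so the sweep costs
#' little more than one pass.
#'
#' @param x an \linkS4class{EpochSet}, band-passed 11-16 Hz
#' @param rValues integer repetition counts in [1, 150]
#' @param modalZone modal delay in seconds (`NULL`: per-r self-estimate)
#' @param toleranceS zone half-width in seconds
#' @param channels response channels
#' @param f0 flicker frequency in Hz
#' @param method score variant, see [fidelityScore()]
#' @return data.frame with `user`, `r`, `score`, `nWindows`
#' @export
fidelitySweep <- function(x, rValues = 1:150, modalZone = NULL,
                          toleranceS = 0.04, channels = c("O1", "O2"),
                          f0 = 12.5, method = c("inzone", "mad")) {
  method <- match.arg(method)
  if (any(rValues < 1 | rValues > 150))
    stop("rValues must lie in [1, 150]")
  tpl <- makeStimulusTemplate(f0 = f0, repetitions = 1L,
                              samplingRate = samplingRate(x))
  y <- .sessionResponse(x, channels)
  fs <- tpl@samplingRate
  W <- as.integer(round((tpl@activeS + tpl@offS) * fs))
  C1 <- .sessionC1(y, tpl@samples, W)
  out <- lapply(as.integer(rValues), function(r) {
    Cr <- .repCorrelograms(C1, r)
    if (is.null(Cr))
      return(data.frame(user = userId(x), r = r, score = NA_real_,
                        nWindows = 0L))
    peaks <- .peakDelaysFromCr(Cr, fs)
    mz <- if (is.null(modalZone)) peakDelayHistogram(peaks)@modalZone
          else modalZone
    data.frame(user = userId(x), r = r,
               score = .fidelityFromDelays(peaks, mz, toleranceS, W, fs,
                                           method),
               nWindows = nrow(Cr))
  })
  do.call(rbind, out)
}

#' Correlate fidelity curves with detection accuracy
#'
#' Pearson correlation (with two-sided t-test p-values) between per-user
#' fidelity scores and per-user balanced accuracy, at every repetition
#' count present in the curves. When either side has zero variance at some
#' `r`, the correlation there is reported as `NA`.
#'
#' @param curves data.frame with `user`, `r`, `score` (rbind of
#'   [fidelitySweep()] results over users)
#' @param accuracies data.frame with `user` and `accuracy` (percent)
#' @return data.frame with `r`, `pearsonR`, `p`, `nUsers`; attribute
#'   `bestR` holds the repetition count with the largest correlation
#' @export
correlateWithAccuracy <- function(curves, accuracies) {
  users <- intersect(unique(curves$user), accuracies$user)
  if (length(users) < 3)
    stop("at least 3 matched users are required")
  acc <- accuracies$accuracy[match(users, accuracies$user)]
  out <- lapply(sort(unique(curves$r)), function(r) {
    sub <- curves[curves$r == r & curves$user %in% users, ]
    sc <- sub$score[match(users, sub$user)]
    ok <- is.finite(sc)
    if (sum(ok) < 3 || stats::sd(sc[ok]) == 0 || stats::sd(acc[ok]) == 0)
      return(data.frame(r = r, pearsonR = NA_real_, p = NA_real_,
                        nUsers = sum(ok)))
    ct <- stats::cor.test(sc[ok], acc[ok], method = "pearson")
    data.frame(r = r, pearsonR = unname(ct$estimate), p = ct$p.value,
               nUsers = sum(ok))
  })
  rep <- do.call(rbind, out)
  best <- if (all(is.na(rep$pearsonR))) NA_integer_
          else rep$r[which.max(rep$pearsonR)]
  structure(rep, bestR = best)
}

#' Flag low-fidelity users for rejection
#'
#' Users whose fidelity score at repetition `r` falls below the requested
#' quantile of the cohort's scores are flagged. Entirely unsupervised:
#' only fidelity scores are consulted, never trial labels.
#'
#' @param curves data.frame with `user`, `r`, `score`
#' @param r repetition count at which to rank
#' @param quantile rejection quantile in [0, 1); 0 rejects nobody
#' @return list with `kept` and `rejected` user vectors and the `cutoff`
#' @export
rankAndRejectUsers <- function(curves, r, quantile = 0.1) {
  if (quantile < 0 || quantile >= 1) stop("quantile must lie in [0, 1)")
  sub <- curves[curves$r == r, ]
  if (!nrow(sub)) stop("no scores at the requested repetition count")
  cutoff <- stats::quantile(sub$score, quantile, na.rm = TRUE, names = FALSE)
  rejected <- sub$user[!is.na(sub$score) & sub$score < cutoff]
  list(kept = setdiff(sub$user, rejected), rejected = rejected,
       cutoff = cutoff)
}
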