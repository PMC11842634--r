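## xDAWN spatial filtering + Riemannian tangent-space features +
## elastic-net logistic head; balanced accuracy; evaluation protocols.

## ---- SPD helpers -----------------------------------------------------

.symEig <- function(M) eigen((M + t(M)) / 2, symmetric = TRUE)

.sqrtmSym <- function(M) {
  e <- .symEig(M)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

.invSqrtmSym <- function(M) {
  e <- .symEig(M)
  e$vectors %*% ((1 / sqrt(pmax(e$values, .Machine$double.eps))) *
                 t(e$vectors))
}

#' Matrix logarithm / exponential of a symmetric matrix
#'
#' Eigendecomposition-based `logm`/`expm` for symmetric (positive-definite
#' for the log) matrices, as used by the affine-invariant tangent-space
#' mapping.
#'
#' @param M symmetric (SPD for `logmSym`) matrix
#' @return symmetric matrix
#' @export
logmSym <- function(M) {
  e <- .symEig(M)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  e$vectors %*% (log(e$values) * t(e$vectors))
}

#' @rdname logmSym
#' @export
expmSym <- function(M) {
  e <- .symEig(M)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Shrunken sample covariance (OAS)
#'
#' Sample covariance of a channels x samples matrix, shrunk toward the
#' scaled identity with the closed-form oracle-approximating shrinkage
#' intensity. Guarantees positive-definiteness for the 12-17 dimensional
#' augmented epochs used by the detector.
#'
#' @param X channels x samples matrix (rows are variables)
#' @return SPD covariance matrix
#' @export
shrinkCov <- function(X) {
  n <- ncol(X)
  p <- nrow(X)
  Xc <- X - rowMeans(X)
  S <- tcrossprod(Xc) / n
  trS <- sum(diag(S))
  trS2 <- sum(S * S)
  num <- (1 - 2 / p) * trS2 + trS^2
  den <- (n + 1 - 2 / p) * (trS2 - trS^2 / p)
  rho <- if (den <= 0) 1 else min(1, max(0, num / den))
  (1 - rho) * S + rho * (trS / p) * diag(p)
}

#' Riemannian (affine-invariant) mean of SPD matrices
#'
#' Fixed-point iteration
#' `M <- M^{1/2} expm(mean_i logm(M^{-1/2} C_i M^{-1/2})) M^{1/2}`,
#' initialized at the arithmetic mean.
#'
#' @param covs list of SPD matrices
#' @param tol Frobenius-norm convergence tolerance
#' @param maxIter iteration cap
#' @return the SPD mean matrix
#' @export
riemannianMean <- function(covs, tol = 1e-9, maxIter = 60L) {
  M <- Reduce(`+`, covs) / length(covs)
  for (it in seq_len(maxIter)) {
    Mi <- .invSqrtmSym(M)
    Ms <- .sqrtmSym(M)
    L <- Reduce(`+`, lapply(covs, function(C) logmSym(Mi %*% C %*% Mi))) /
      length(covs)
    M <- Ms %*% expmSym(L) %*% Ms
    M <- (M + t(M)) / 2
    if (sqrt(sum(L * L)) < tol) break
  }
  M
}

#' Tangent-space coordinates of SPD matrices
#'
#' Projects each covariance onto the tangent space at `base` via
#' `upper(logm(base^{-1/2} C base^{-1/2}))`, off-diagonal entries weighted
#' by sqrt(2) so Euclidean distance matches the Riemannian metric at the
#' base point. The base point itself maps to the zero vector.
#'
#' @param covs list of SPD matrices
#' @param base SPD base point (typically the Riemannian mean of the
#'   training covariances)
#' @return matrix, one row of `p*(p+1)/2` coordinates per covariance
#' @export
tangentSpace <- function(covs, base) {
  Bi <- .invSqrtmSym(base)
  upper <- upper.tri(base, diag = TRUE)
  wts <- ifelse(row(base)[upper] == col(base)[upper], 1, sqrt(2))
  t(vapply(covs, function(C) {
    L <- logmSym(Bi %*% C %*% Bi)
    L[upper] * wts
  }, numeric(sum(upper))))
}

## ---- xDAWN -----------------------------------------------------------

#' Fit xDAWN spatial filters
#'
#' Per class, the evoked response is estimated by least squares over the
#' concatenated recording with a Toeplitz (time-locked indicator) design;
#' for non-overlapping action windows this reduces exactly to the class
#' average. Spatial filters solve the generalized eigenproblem maximizing
#' the ratio of evoked signal power to total signal power; the leading
#' `nFilters` unit-norm filters are kept per class.
#'
#' @param x an \linkS4class{EpochSet} containing both classes
#' @param nFilters filters retained per class (default 4, capped at the
#'   channel count)
#' @return an \linkS4class{XdawnModel}
#' @export
fitXdawn <- function(x, nFilters = 4L) {
  stopifnot(is(x, "EpochSet"))
  labs <- trialLabels(x)
  classes <- c("error", "non-error")
  if (any(table(labs)[classes] == 0) || any(is.na(table(labs)[classes])))
    stop("both classes must be present")
  arr <- epochs(x)
  nc <- dim(arr)[2]
  ns <- dim(arr)[3]
  nFilters <- as.integer(min(nFilters, nc))
  ## total covariance over the concatenated recording
  Sx <- matrix(0, nc, nc)
  for (i in seq_len(dim(arr)[1])) {
    E <- matrix(arr[i, , ], nc, ns)
    Sx <- Sx + tcrossprod(E)
  }
  Sx <- Sx / (dim(arr)[1] * ns)
  ## shrink if near-singular so the Cholesky whitening is stable
  ev <- eigen(Sx, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warning("rank-deficient signal covariance; applying shrinkage")
    Sx <- 0.99 * Sx + 0.01 * mean(diag(Sx)) * diag(nc)
  }
  R <- chol(Sx)
  Rinv <- backsolve(R, diag(nc))
  filters <- patterns <- prototypes <- evoked <- list()
  for (cl in classes) {
    idx <- which(labs == cl)
    A <- matrix(0, nc, ns)
    for (i in idx) A <- A + matrix(arr[i, , ], nc, ns)
    A <- A / length(idx)                       # Toeplitz LS == class mean
    Se <- tcrossprod(A) / ns
    Tm <- t(Rinv) %*% Se %*% Rinv
    e <- .symEig(Tm)
    W <- Rinv %*% e$vectors[, seq_len(nFilters), drop = FALSE]
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    filters[[cl]] <- W
    P <- Sx %*% W
    patterns[[cl]] <- sweep(P, 2, sqrt(colSums(P^2)), "/")
    prototypes[[cl]] <- t(W) %*% A
    evoked[[cl]] <- A
  }
  new("XdawnModel", filters = filters, patterns = patterns,
      prototypes = prototypes, evoked = evoked, classes = classes,
      nFilters = nFilters, channels = channelNames(x))
}

#' Augmented xDAWN covariance features in the tangent space
#'
#' Each epoch is augmented with the filtered class prototypes
#' (`[P_error; P_non; W' X]`), its shrunken covariance computed, and the
#' set mapped to the tangent space at the Riemannian mean of the supplied
#' reference covariances (the training set's mean when `base` is given).
#'
#' @param x an \linkS4class{EpochSet}
#' @param model a fitted \linkS4class{XdawnModel}
#' @param base optional SPD base point; when `NULL` the Riemannian mean of
#'   these covariances is used and returned as attribute `base`
#' @return feature matrix (one row per trial) with attribute `base`
#' @export
covarianceFeatures <- function(x, model, base = NULL) {
  stopifnot(is(x, "EpochSet"), is(model, "XdawnModel"))
  arr <- epochs(x)
  nc <- dim(arr)[2]
  ns <- dim(arr)[3]
  Wall <- do.call(cbind, model@filters)
  Proto <- do.call(rbind, model@prototypes)
  covs <- lapply(seq_len(dim(arr)[1]), function(i) {
    E <- matrix(arr[i, , ], nc, ns)
    shrinkCov(rbind(Proto, t(Wall) %*% E))
  })
  if (is.null(base)) base <- riemannianMean(covs)
  feats <- tangentSpace(covs, base)
  structure(feats, base = base)
}

#' Balanced accuracy
#'
#' `100 * (TPR + TNR) / 2` with the `error` class as positive; robust to
#' the ~4:1 non-error:error class imbalance of the paradigm.
#'
#' @param labels true labels (factor or character, `error`/`non-error`)
#' @param predictions predicted labels
#' @return percentage in [0, 100]
#' @export
balancedAccuracy <- function(labels, predictions) {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(unique(labels)) < 2)
    stop("both classes must be present in labels")
  tpr <- mean(predictions[labels == "error"] == "error")
  tnr <- mean(predictions[labels == "non-error"] == "non-error")
  100 * (tpr + tnr) / 2
}

## ---- detector head ---------------------------------------------------

#' Train the xDAWN + Riemannian tangent-space + elastic-net detector
#'
#' Fits xDAWN filters, computes tangent-space features at the training
#' set's Riemannian mean, and fits an elastic-net-penalized logistic
#' regression (mixing parameter `alpha`). The regularization strength is
#' chosen by inner cross-validation maximizing AUC with inverse-frequency
#' class weights, so model selection is aligned with balanced accuracy
#' under the paradigm's ~4:1 class imbalance.
#'
#' @param x training \linkS4class{EpochSet}
#' @param nFilters xDAWN filters per class
#' @param alpha elastic-net mixing parameter (default 0.5)
#' @param seed seed for the inner CV fold assignment
#' @param innerFolds inner CV folds (default 5, reduced if a class is
#'   too small)
#' @return detector object (list) for [predictDetector()]
#' @export
trainDetector <- function(x, nFilters = 4L, alpha = 0.5, seed = 1L,
                          innerFolds = 5L) {
  model <- fitXdawn(x, nFilters)
  feats <- covarianceFeatures(x, model)
  y <- factor(as.character(trialLabels(x)), levels = c("non-error", "error"))
  w <- ifelse(y == "error", 0.5 / mean(y == "error"),
              0.5 / mean(y == "non-error"))
  nf <- max(3L, min(innerFolds, min(table(y))))
  fit <- .localSeed(seed, suppressWarnings(glmnet::cv.glmnet(
    feats, y, family = "binomial", alpha = alpha, nfolds = nf,
    weights = w, type.measure = "auc")))
  structure(list(xdawn = model, base = attr(feats, "base"), fit = fit,
                 alpha = alpha),
            class = "ssvepDetector")
}

#' Predict trial labels with a trained detector
#'
#' @param detector result of [trainDetector()]
#' @param x an \linkS4class{EpochSet}
#' @return factor of predicted labels (`error`/`non-error`)
#' @export
predictDetector <- function(detector, x) {
  feats <- covarianceFeatures(x, detector$xdawn, base = detector$base)
  pred <- predict(detector$fit, feats, s = "lambda.min", type = "class")
  factor(ifelse(pred == "error", "error", "non-error"),
         levels = c("error", "non-error"))
}

## ---- evaluation protocols --------------------------------------------

#' Cross-validation protocol description
#'
#' Defaults follow the per-user protocol: stratified 5-fold CV, 4
#' repetitions per user (20 runs), the whole procedure repeated 10 times
#' for the dataset mean and standard deviation.
#'
#' @param folds folds per repetition
#' @param reps CV repetitions per user
#' @param outerRepeats whole-procedure repeats for mean +/- sd
#' @param nFilters,alpha detector hyperparameters
#' @param seed integer seed from which every fold assignment derives
#' @return a `cvProtocol` list
#' @export
cvProtocol <- function(folds = 5L, reps = 4L, outerRepeats = 10L,
                       nFilters = 4L, alpha = 0.5, seed = 1L) {
  structure(list(folds = as.integer(folds), reps = as.integer(reps),
                 outerRepeats = as.integer(outerRepeats),
                 nFilters = as.integer(nFilters), alpha = alpha,
                 seed = as.integer(seed)),
            class = "cvProtocol")
}

## stratified fold assignment: per-class shuffle, folds as balanced as the
## trial counts allow
.stratifiedFolds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  .localSeed(seed, for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

.cvRunAccuracies <- function(x, protocol, runSeed) {
  labs <- as.character(trialLabels(x))
  if (min(table(labs)) < protocol$folds)
    stop("too few trials in a class for ", protocol$folds, " folds")
  accs <- numeric(0)
  for (rep in seq_len(protocol$reps)) {
    fold <- .stratifiedFolds(labs, protocol$folds,
                             .deriveSeed(runSeed, rep))
    for (k in seq_len(protocol$folds)) {
      det <- trainDetector(x[fold != k], nFilters = protocol$nFilters,
                           alpha = protocol$alpha,
                           seed = .deriveSeed(runSeed, rep * 100L + k))
      pred <- predictDetector(det, x[fold == k])
      accs <- c(accs, balancedAccuracy(labs[fold == k], pred))
    }
  }
  accs
}

#' Per-user cross-validated balanced accuracy
#'
#' Stratified `folds`-fold CV repeated `reps` times (fold-level accuracies
#' averaged into one per-user accuracy), the whole procedure repeated
#' `outerRepeats` times with fresh fold assignments.
#'
#' @param x the user's \linkS4class{EpochSet}
#' @param protocol a [cvProtocol()]
#' @return list with `mean`, `sd` (over outer repeats) and `perRepeat`
#' @export
perUserCV <- function(x, protocol = cvProtocol()) {
  per <- vapply(seq_len(protocol$outerRepeats), function(o)
    mean(.cvRunAccuracies(x, protocol,
                          .deriveSeed(protocol$seed, o * 10000L))),
    numeric(1))
  list(mean = mean(per), sd = stats::sd(per), perRepeat = per)
}

#' Cohort-average cross-validated accuracy
#'
#' Runs the per-user protocol for every user within each outer repeat and
#' averages across users, yielding the dataset mean +/- sd across repeats.
#'
#' @param cohort list of \linkS4class{EpochSet}s
#' @param protocol a [cvProtocol()]
#' @return list with `mean`, `sd`, `perRepeat` and `perUser`
#' @export
cohortAccuracy <- function(cohort, protocol = cvProtocol()) {
  perRepeat <- numeric(protocol$outerRepeats)
  perUser <- matrix(0, length(cohort), protocol$outerRepeats,
                    dimnames = list(names(cohort), NULL))
  for (o in seq_len(protocol$outerRepeats)) {
    ua <- vapply(seq_along(cohort), function(u)
      mean(.cvRunAccuracies(cohort[[u]], protocol,
                            .deriveSeed(protocol$seed, o * 10000L + u))),
      numeric(1))
    perUser[, o] <- ua
    perRepeat[o] <- mean(ua)
  }
  list(mean = mean(perRepeat), sd = stats::sd(perRepeat),
       perRepeat = perRepeat, perUser = rowMeans(perUser))
}

#' Zero-shot cross-user generalization
#'
#' `one_v_one`: train on each user, test on every other user (all ordered
#' pairs). `one_v_rest`: for each user, train on all remaining users
#' pooled and test on that user. Evaluations are repeated
#' `protocol$outerRepeats` times (fresh detector seeds) for mean +/- sd.
#'
#' @param cohort list of \linkS4class{EpochSet}s (>= 2 users)
#' @param mode `"one_v_one"` or `"one_v_rest"`
#' @param protocol a [cvProtocol()]
#' @return list with `mean`, `sd`, `perRepeat`, `nEvaluations`
#' @export
zeroShotGeneralization <- function(cohort,
                                   mode = c("one_v_one", "one_v_rest"),
                                   protocol = cvProtocol()) {
  mode <- match.arg(mode)
  n <- length(cohort)
  if (n < 2) stop("at least two users are required")
  pairs <- if (mode == "one_v_one") {
    g <- expand.grid(train = seq_len(n), test = seq_len(n))
    g[g$train != g$test, ]
  } else data.frame(train = NA_integer_, test = seq_len(n))
  perRepeat <- vapply(seq_len(protocol$outerRepeats), function(o) {
    accs <- vapply(seq_len(nrow(pairs)), function(p) {
      testSet <- cohort[[pairs$test[p]]]
      trainSet <- if (mode == "one_v_one") cohort[[pairs$train[p]]]
                  else .poolSessions(cohort[-pairs$test[p]])
      det <- trainDetector(trainSet, nFilters = protocol$nFilters,
                           alpha = protocol$alpha,
                           seed = .deriveSeed(protocol$seed,
                                              o * 100000L + p))
      balancedAccuracy(trialLabels(testSet), predictDetector(det, testSet))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  list(mean = mean(perRepeat), sd = stats::sd(perRepeat),
       perRepeat = perRepeat, nEvaluations = nrow(pairs))
}

.poolSessions <- function(sessions) {
  arr <- do.call(abind3, lapply(sessions, epochs))
  labs <- unlist(lapply(sessions, function(s) as.character(trialLabels(s))))
  epochSet(arr, labs, samplingRate = samplingRate(sessions[[1]]),
           channels = channelNames(sessions[[1]]), userId = "pooled")
}

## rbind for 3-D arrays along the trial dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))),
                    d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  dimnames(out) <- list(NULL, dimnames(parts[[1]])[[2]], NULL)
  out
}

#' Balanced accuracy over the 9-cell spatio-spectral grid
#'
#' For every (electrode subset, band) cell: artifact rejection on the
#' broadband (F1) filtered data decides the kept trials, the raw kept
#' trials are band-passed with the cell's band and restricted to the
#' cell's electrodes, and the cohort-average CV accuracy is computed.
#'
#' @param cohort list of \linkS4class{EpochSet}s
#' @param protocol a [cvProtocol()]
#' @param grid cells from [spatioSpectralGrid()]
#' @param reject apply threshold artifact rejection first (default TRUE)
#' @return data.frame (one row per cell): `cell`, `electrodes`, `band`,
#'   `mean`, `sd`
#' @export
spatioSpectralSweep <- function(cohort, protocol = cvProtocol(),
                                grid = spatioSpectralGrid(),
                                reject = TRUE) {
  if (reject)
    cohort <- lapply(cohort, function(s)
      s[rejectArtifacts(bandpassFilter(s, bandConfig("F1")))$mask$kept])
  ## filter once per distinct band; cells then only subset channels
  bands <- unique(vapply(grid, function(cell) cell$band$name, character(1)))
  filtered <- lapply(bands, function(b)
    lapply(cohort, bandpassFilter, band = bandConfig(b)))
  names(filtered) <- bands
  rows <- lapply(names(grid), function(cellName) {
    cell <- grid[[cellName]]
    processed <- lapply(filtered[[cell$band$name]], selectElectrodes,
                        config = cell$electrodes)
    res <- cohortAccuracy(processed, protocol)
    data.frame(cell = cellName, electrodes = cell$electrodes$name,
               band = cell$band$name, mean = res$mean, sd = res$sd)
  })
  do.call(rbind, rows)
}
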