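spdMatrix <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(p)
}

test_that("balanced accuracy is (TPR + TNR)/2 in percent", {
  y <- c(rep("error", 10), rep("non-error", 40))
  expect_equal(balancedAccuracy(y, y), 100)
  expect_equal(balancedAccuracy(y, rep("non-error", 50)), 50)
  pred <- y
  pred[1:4] <- "non-error"                      # TPR 0.6
  pred[11:18] <- "error"                        # TNR 0.8
  expect_equal(balancedAccuracy(y, pred), 70)
  expect_error(balancedAccuracy(rep("error", 5), rep("error", 5)), "classes")
})

test_that("SPD helpers satisfy their defining identities", {
  C <- spdMatrix(6, 1)
  expect_equal(expmSym(logmSym(C)), C, tolerance = 1e-8)
  expect_error(logmSym(diag(c(1, -1))), "positive")
  ## shrunken covariance is SPD even for rank-deficient input
  X <- matrix(rnorm(5 * 3), 5, 3) %*% matrix(rnorm(3 * 50), 3, 50)
  ev <- eigen(shrinkCov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("the Riemannian mean solves the Karcher condition", {
  covs <- lapply(1:20, function(i) spdMatrix(5, i))
  M <- riemannianMean(covs)
  Mi <- solve(M)
  e <- eigen(Mi, symmetric = TRUE)
  MiH <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  grad <- Reduce(`+`, lapply(covs, function(C)
    logmSym(MiH %*% C %*% MiH))) / length(covs)
  expect_lt(sqrt(sum(grad^2)), 1e-6)
  ## two-matrix mean equals the closed-form geodesic midpoint
  A <- spdMatrix(4, 31); B <- spdMatrix(4, 32)
  eA <- eigen(A, symmetric = TRUE)
  Ah <- eA$vectors %*% (sqrt(eA$values) * t(eA$vectors))
  Aih <- eA$vectors %*% ((1 / sqrt(eA$values)) * t(eA$vectors))
  inner <- Aih %*% B %*% Aih
  eI <- eigen((inner + t(inner)) / 2, symmetric = TRUE)
  midpoint <- Ah %*% (eI$vectors %*% (sqrt(eI$values) * t(eI$vectors))) %*% Ah
  expect_equal(riemannianMean(list(A, B)), midpoint, tolerance = 1e-6)
})

test_that("tangent mapping is centered and injective at the base point", {
  covs <- lapply(1:8, function(i) spdMatrix(4, i + 10))
  M <- riemannianMean(covs)
  expect_equal(as.numeric(tangentSpace(list(M), M)), numeric(10),
               tolerance = 1e-9)
  V <- tangentSpace(covs, M)
  expect_identical(dim(V), c(8L, 10L))
  expect_equal(tangentSpace(covs[c(3, 3)], M)[1, ],
               tangentSpace(covs[c(3, 3)], M)[2, ])
})

test_that("xDAWN recovers planted evoked topographies", {
  set.seed(12)
  nTr <- 80; nc <- 5; ns <- 225
  v <- c(0.1, 0.2, 0.9, 0.3, -0.2); v <- v / sqrt(sum(v^2))
  s <- errpTemplate()                      # planted evoked waveform
  labs <- rep(c("error", "non-error"), nTr / 2)
  arr <- array(rnorm(nTr * nc * ns, sd = 0.5), c(nTr, nc, ns))
  for (i in which(labs == "error"))
    arr[i, , ] <- arr[i, , ] + 3 * v %o% s
  ses <- epochSet(arr, labs, channels = paste0("ch", 1:5))
  m <- fitXdawn(ses, nFilters = 2L)
  cosSim <- abs(sum(m@patterns[["error"]][, 1] * v))
  expect_gt(cosSim, 0.95)
  ## filters are unit norm and generalized-eigenvalue optimal
  W <- m@filters[["error"]]
  expect_equal(colSums(W^2), rep(1, 2), tolerance = 1e-9)
  arrM <- epochs(ses)
  Sx <- matrix(0, nc, nc)
  for (i in seq_len(nTr)) Sx <- Sx + tcrossprod(matrix(arrM[i, , ], nc, ns))
  Sx <- Sx / (nTr * ns)
  A <- apply(arrM[labs == "error", , , drop = FALSE], c(2, 3), mean)
  Se <- tcrossprod(A) / ns
  oracleVals <- sort(Re(eigen(solve(Sx) %*% Se)$values), decreasing = TRUE)
  quotients <- diag(t(W) %*% Se %*% W) / diag(t(W) %*% Sx %*% W)
  expect_equal(quotients, oracleVals[1:2], tolerance = 1e-6)
  expect_error(fitXdawn(ses[labs == "error"]), "classes")
})

test_that("single-channel xDAWN degenerates to the unit scalar", {
  set.seed(3)
  arr <- array(rnorm(40 * 1 * 225), c(40, 1, 225))
  ses <- epochSet(arr, rep(c("error", "non-error"), 20), channels = "Cz")
  m <- fitXdawn(ses, nFilters = 4L)
  expect_identical(m@nFilters, 1L)
  expect_equal(abs(as.numeric(m@filters[["error"]])), 1, tolerance = 1e-12)
})

test_that("xDAWN filters undo channel-wise scaling", {
  ses <- defaultSession()[1:60]
  scaled <- ses
  g <- c(2, rep(1, 10), 0.5)
  arr <- epochs(ses)
  for (c in 1:12) arr[, c, ] <- arr[, c, ] * g[c]
  scaled@epochs <- arr
  m1 <- fitXdawn(ses, nFilters = 1L)
  m2 <- fitXdawn(scaled, nFilters = 1L)
  w1 <- m1@filters[["error"]][, 1]
  w2 <- m2@filters[["error"]][, 1] * g      # filters carry D^{-1}: undo it
  w2 <- w2 / sqrt(sum(w2^2))
  expect_gt(abs(sum(w1 * w2)), 0.999)
})

test_that("identical epochs give identical tangent features", {
  ses <- defaultSession()[rep(1L, 6)]
  ses@labels <- factor(rep(c("error", "non-error"), 3),
                       levels = c("error", "non-error"))
  m <- fitXdawn(defaultSession()[1:60], nFilters = 2L)
  f <- covarianceFeatures(ses, m)
  expect_equal(max(apply(f, 2, function(col) diff(range(col)))), 0,
               tolerance = 1e-9)
})

test_that("stratified folds preserve the class ratio", {
  labs <- c(rep("error", 23), rep("non-error", 97))
  fold <- SSVEPcoupling:::.stratifiedFolds(labs, 5L, 42L)
  expect_identical(sort(unique(fold)), 1:5)
  for (k in 1:5) {
    nErr <- sum(labs[fold == k] == "error")
    expect_lte(abs(nErr - 23 / 5), 1)
  }
})

test_that("deterministic separable data is classified perfectly", {
  ses <- simulateSession(quietConfig(nEpisodes = 2L, actionsPerEpisode = 30L,
                                     errorProb = 0.2, seed = 17L))
  ## noiseless data is rank deficient: the fit must warn and shrink
  expect_warning(fitXdawn(ses), "rank-deficient")
  res <- suppressWarnings(
    perUserCV(ses, cvProtocol(folds = 5L, reps = 1L,
                              outerRepeats = 2L, seed = 5L)))
  expect_equal(res$mean, 100)
  expect_equal(res$sd, 0)
})

test_that("zero-shot protocols count ordered train/test permutations", {
  cfg <- quietConfig(nEpisodes = 2L, actionsPerEpisode = 30L,
                     errorProb = 0.2, seed = 19L)
  twin <- list(u1 = simulateSession(cfg, "u1"),
               u2 = simulateSession(cfg, "u2"),
               u3 = simulateSession(cfg, "u3"))
  proto <- cvProtocol(outerRepeats = 1L, seed = 2L)
  ovo <- suppressWarnings(zeroShotGeneralization(twin, "one_v_one", proto))
  expect_identical(ovo$nEvaluations, 6L)      # 3 x 2 ordered pairs
  expect_equal(ovo$mean, 100)                 # identical users transfer
  ovr <- suppressWarnings(zeroShotGeneralization(twin, "one_v_rest", proto))
  expect_identical(ovr$nEvaluations, 3L)
  expect_error(zeroShotGeneralization(twin[1], "one_v_one", proto), "two")
})
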