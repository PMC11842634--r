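test_that("noiseless phase-locked sessions score a perfect fidelity", {
  ses <- quietF3Session()
  for (r in c(1L, 3L)) {
    s <- fidelityScore(ses, makeStimulusTemplate(repetitions = r),
                       modalZone = 0.27)
    expect_equal(as.numeric(s), 1)
    expect_identical(attr(s, "repetitions"), r)
  }
  ## self-estimated modal zone gives the same verdict
  expect_equal(as.numeric(fidelityScore(ses)), 1)
  ## the alternative discrepancy variant is also maximal
  expect_gt(as.numeric(fidelityScore(ses, modalZone = 0.27,
                                     method = "mad")), 0.95)
})

test_that("a signal-free session scores at the chance level of the zone", {
  ses <- fixture("noiseOnlyF3", {
    cfg <- simConfig(nEpisodes = 4L, actionsPerEpisode = 30L,
                     ssvepGain = zeroGain(), errpGain = zeroGain(),
                     noiseSigma = 5, artifactRate = 0, seed = 1L)
    bandpassFilter(simulateSession(cfg), bandConfig("F3"),
                   continuous = TRUE)
  })
  ## tolerance of one SSVEP period: zone width / window = 0.16 / 1.8
  s <- as.numeric(fidelityScore(ses, modalZone = 0.27, toleranceS = 0.08))
  chance <- 0.16 / 1.8
  se <- sqrt(chance * (1 - chance) / 119)
  expect_lt(abs(s - chance), 4 * se)
})

test_that("fidelity decreases strictly along a noise ramp", {
  scores <- fixture("rampScores", {
    vapply(seq_along(c(0, 3, 6, 12, 20)), function(i) {
      ns <- c(0, 3, 6, 12, 20)[i]
      cfg <- simConfig(nEpisodes = 4L, actionsPerEpisode = 30L,
                       noiseSigma = ns, artifactRate = 0,
                       seed = 100L + i)
      f3 <- bandpassFilter(simulateSession(cfg), bandConfig("F3"),
                           continuous = TRUE)
      as.numeric(fidelityScore(f3, makeStimulusTemplate(repetitions = 3L),
                               modalZone = 0.27))
    }, numeric(1))
  })
  expect_equal(scores[1], 1)
  expect_true(all(diff(scores) < 0))
})

test_that("the repetition sweep reuses windows consistently", {
  ses <- quietF3Session()
  sw <- fidelitySweep(ses, rValues = c(1L, 2L, 5L), modalZone = 0.27)
  expect_identical(sw$r, c(1L, 2L, 5L))
  expect_equal(sw$score, rep(1, 3))
  expect_equal(sw$score[1],
               as.numeric(fidelityScore(ses, makeStimulusTemplate(),
                                        modalZone = 0.27)))
  ## fewer analyzable windows as the template grows
  expect_true(all(diff(sw$nWindows) < 0))
  expect_error(fidelitySweep(ses, rValues = c(1L, 200L)), "rValues")
})

test_that("across-user score variance shrinks at large repetition counts", {
  ## integrating more windows first spreads users apart, then pulls every
  ## score toward the ideal value; variance at saturation is below the
  ## single-repetition variance
  curves <- fixture("noisyCurves", {
    coh <- simulateCohort(4, c(4, 5, 6, 7),
                          simConfig(nEpisodes = 4L, actionsPerEpisode = 30L,
                                    artifactRate = 0),
                          seed = 55L)
    f3 <- lapply(coh, bandpassFilter, band = bandConfig("F3"),
                 continuous = TRUE)
    do.call(rbind, lapply(f3, fidelitySweep, rValues = c(1L, 50L),
                          modalZone = 0.27))
  })
  v1 <- var(curves$score[curves$r == 1])
  v50 <- var(curves$score[curves$r == 50])
  expect_lt(v50, v1)
  expect_gt(mean(curves$score[curves$r == 50]),
            mean(curves$score[curves$r == 1]))
})

test_that("fidelity-accuracy correlation machinery behaves", {
  curves <- data.frame(user = rep(paste0("u", 1:6), each = 2),
                       r = rep(c(1L, 5L), 6),
                       score = c(t(cbind(seq(0.9, 0.4, length.out = 6),
                                         seq(0.95, 0.2, length.out = 6)))))
  acc <- data.frame(user = paste0("u", 1:6),
                    accuracy = c(90, 82, 75, 68, 60, 52))
  rep_ <- correlateWithAccuracy(curves, acc)
  expect_true(all(rep_$pearsonR >= -1 & rep_$pearsonR <= 1))
  expect_gt(min(rep_$pearsonR), 0.95)
  expect_identical(attr(rep_, "bestR"), rep_$r[which.max(rep_$pearsonR)])
  ## zero accuracy variance -> undefined, reported as NA
  accFlat <- data.frame(user = paste0("u", 1:6), accuracy = rep(70, 6))
  expect_true(all(is.na(correlateWithAccuracy(curves, accFlat)$pearsonR)))
  expect_error(correlateWithAccuracy(curves[curves$user %in% c("u1", "u2"), ],
                                     acc), "3")
  ## permutation null: shuffling users kills the correlation on average
  set.seed(3)
  perms <- replicate(500, {
    sh <- curves
    map <- sample(unique(curves$user))
    sh$user <- map[match(sh$user, unique(curves$user))]
    correlateWithAccuracy(sh, acc)$pearsonR[1]
  })
  expect_lt(abs(mean(perms)), 0.15)
})

test_that("user rejection is quantile-based and never reads labels", {
  curves <- data.frame(user = paste0("u", 1:10), r = 1L,
                       score = c(0.9, 0.85, 0.8, 0.75, 0.7, 0.65, 0.6,
                                 0.55, 0.5, 0.05))
  expect_length(rankAndRejectUsers(curves, 1L, 0)$rejected, 0)
  out <- rankAndRejectUsers(curves, 1L, 0.1)
  expect_identical(out$rejected, "u10")
  expect_length(out$kept, 9)
  expect_error(rankAndRejectUsers(curves, 1L, 1), "quantile")
  ## unsupervised contract: permuting trial labels leaves scores untouched
  ses <- quietF3Session()
  permuted <- ses
  set.seed(2)
  permuted@labels <- sample(trialLabels(ses))
  expect_identical(as.numeric(fidelityScore(ses, modalZone = 0.27)),
                   as.numeric(fidelityScore(permuted, modalZone = 0.27)))
})
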