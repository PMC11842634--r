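test_that("the analytic signal matches closed forms and the DFT oracle", {
  t <- (0:199) / 125
  a <- hilbertAnalytic(cos(2 * pi * 12.5 * t))
  expect_equal(a@envelope, rep(1, 200), tolerance = 1e-9)
  ## interior phase advances at 2*pi*F0 per second
  dphi <- diff(a@phase[20:180]) %% (2 * pi)
  expect_equal(mean(dphi), 2 * pi * 12.5 / 125, tolerance = 1e-2)
  expect_equal(hilbertAnalytic(numeric(64))@envelope, numeric(64))
  expect_error(hilbertAnalytic(c(1, NA, rep(0, 10))), "finite")
  expect_error(hilbertAnalytic(1:4), "length")
  set.seed(42)
  for (i in 1:100) {
    n <- sample(c(32, 63, 64, 128), 1)
    x <- rnorm(n)
    expect_equal(hilbertAnalytic(x)@imag, hilbertOracleImag(x),
                 tolerance = 1e-9)
  }
})

test_that("instantaneous phase lag is the wrapped phase difference", {
  t <- (0:199) / 125
  s <- hilbertAnalytic(sin(2 * pi * 12.5 * t))
  r <- hilbertAnalytic(sin(2 * pi * 12.5 * t - pi / 2))
  expect_equal(instantaneousPhaseLag(s, s), rep(0, 200))
  lag <- instantaneousPhaseLag(r, s)
  expect_equal(mean(lag[30:170]), -pi / 2, tolerance = 1e-2)
  expect_error(instantaneousPhaseLag(s, hilbertAnalytic(t[1:100])), "length")
  set.seed(1)
  x <- hilbertAnalytic(rnorm(64)); y <- hilbertAnalytic(rnorm(64))
  expect_equal(instantaneousPhaseLag(x, y),
               Arg(exp(1i * x@phase) * exp(-1i * y@phase)),
               tolerance = 1e-12)
})

test_that("PLV is the mean-phasor modulus with the Rayleigh chance level", {
  expect_identical(plv(rep(0.7, 50)), 1)
  expect_equal(plv(rep(c(0, pi), 20)), 0, tolerance = 1e-12)
  expect_error(plv(numeric(0)), "nonempty")
  set.seed(5)
  draws <- replicate(1000, plv(runif(62, -pi, pi)))
  expect_true(all(draws >= 0 & draws <= 1))
  ## E[PLV] for uniform phases ~ sqrt(pi)/2 / sqrt(N)
  expect_equal(mean(draws), sqrt(pi) / 2 / sqrt(62), tolerance = 0.05)
  ## invariance to a global phase offset on both signals
  set.seed(6); dphi <- runif(200, -pi, pi)
  expect_equal(plv(dphi), plv(Arg(exp(1i * (dphi + 1.234)) *
                                    exp(-1i * 1.234))), tolerance = 1e-12)
})

test_that("sliding PLV uses 62-sample windows and tracks locking", {
  tpl <- makeStimulusTemplate(repetitions = 1L)
  t <- (0:224) / 125
  locked <- sin(2 * pi * 12.5 * t + 1.1)
  sp <- slidingPlv(locked, tpl)
  expect_identical(sp$windowSamples, 62L)
  ## interior windows fully inside the active flicker segment lock tightly
  inside <- sp$tS > 0.1 & sp$tS + 0.5 < 1.5
  expect_true(all(sp$values[inside] > 0.95))
  set.seed(8)
  spn <- slidingPlv(rnorm(225), tpl, stride = 10L)
  expect_lt(mean(spn$values), 0.3)
  expect_error(slidingPlv(rnorm(30), tpl), "window")
})

test_that("the stimulus template has 20 active cycles and a silent tail", {
  tpl <- makeStimulusTemplate(12.5, repetitions = 1L)
  active <- tpl@samples[1:200]
  ## DFT bin k holds k cycles per segment: all energy sits at bin 20
  spec <- Mod(fft(active))
  expect_identical(which.max(spec[2:101]), 20L)
  expect_lt(sum(spec[2:101]^2) - spec[21]^2, 1e-18 * spec[21]^2)
  expect_identical(tpl@samples[201:225], numeric(25))
  expect_length(makeStimulusTemplate(repetitions = 3L)@samples, 675)
  expect_identical(makeStimulusTemplate(a0 = 0)@samples, numeric(225))
  expect_error(makeStimulusTemplate(repetitions = 0), "repetitions")
  expect_error(makeStimulusTemplate(repetitions = 151), "repetitions")
})

test_that("cross-correlation matches the brute-force oracle and Eq-form", {
  tpl <- makeStimulusTemplate(repetitions = 1L)
  expect_true(all(crossCorrelate(numeric(500), tpl)@values == 0))
  expect_error(crossCorrelate(numeric(100), tpl), "longer")
  set.seed(9)
  resp <- rnorm(500)
  cg <- crossCorrelate(resp, tpl)
  expect_equal(cg@values, xcorrOracle(resp, tpl@samples, length(cg@values)),
               tolerance = 1e-9)
  ## noiseless lagged sinusoid: maxima on the tau = -delta + 0.08 n lattice
  phi <- 4.05
  t <- (0:449) / 125
  cg2 <- crossCorrelate(sin(2 * pi * 12.5 * t + phi), tpl)
  mx <- findCorrelationMaxima(cg2)
  expect_equal(unique(round(diff(sort(mx)), 10)), 0.08, tolerance = 1e-9)
  lattice <- latticeDelays(phi, 12.5, 1:30)
  lattice <- lattice[lattice >= 0 & lattice <= max(cg2@delayS)]
  for (m in mx) expect_lte(min(abs(m - lattice)), 1 / 125)
})

test_that("maxima detection keeps prominent peaks and endpoint extrema", {
  lobe <- new("Correlogram", delayS = (0:99) / 125,
              values = dnorm(0:99, 50, 8), windowId = 1L)
  expect_equal(findCorrelationMaxima(lobe), 50 / 125)
  mono <- new("Correlogram", delayS = (0:99) / 125,
              values = as.numeric(1:100), windowId = 1L)
  expect_equal(findCorrelationMaxima(mono), 99 / 125)
  zero <- new("Correlogram", delayS = (0:9) / 125, values = numeric(10),
              windowId = 1L)
  expect_length(findCorrelationMaxima(zero), 0)
})

test_that("peak-delay histograms resolve the lattice and locate the mode", {
  h <- peakDelayHistogram(rep(0.272, 25))
  expect_identical(sum(h@counts), 25)
  expect_identical(sum(h@counts > 0), 1L)
  expect_lt(abs(h@modalZone - 0.272), 0.008)
  set.seed(10)
  u <- runif(400, 0, 1.792)
  hu <- peakDelayHistogram(u, binS = 0.008)
  k <- length(hu@counts)
  ## max bin count consistent with uniform occupancy (Bonferroni bound)
  expect_lte(max(hu@counts), qbinom(1 - 0.001 / k, 400, 1 / k) + 1)
  expect_error(peakDelayHistogram(numeric(0)), "window")
})

test_that("phase-lag estimation inverts the maxima condition", {
  expect_equal(estimatePhaseLag((1:5) / 12.5, 12.5)@phiBar, 0,
               tolerance = 1e-9)
  est <- estimatePhaseLag(0.26843, 12.5)
  expect_equal(est@phiBar, 4.05, tolerance = 0.01)
  expect_equal(est@delta, est@phiBar / (2 * pi * 12.5))
  expect_error(estimatePhaseLag(numeric(0)), "nonempty")
})

test_that("session peak delays equal direct r-repetition correlation", {
  ses <- quietF3Session()
  pd3 <- windowPeakDelays(ses, makeStimulusTemplate(repetitions = 3L),
                          refine = FALSE)
  ## direct path: full 3-repetition template against the concatenated
  ## response, re-anchored at each onset
  arr <- epochs(selectElectrodes(ses, c("O1", "O2")))
  y <- as.numeric(t(apply(arr, c(1, 3), mean)))
  tpl3 <- makeStimulusTemplate(repetitions = 3L)
  for (i in pd3$window[c(1, 5, 10)]) {
    seg <- y[((i - 1) * 225 + 1):length(y)]
    cg <- crossCorrelate(seg, tpl3, nDelays = 225L)
    expect_equal(pd3$delayS[pd3$window == i],
                 cg@delayS[which.max(cg@values)])
  }
})

test_that("injected phase lags are recovered within 0.1 rad", {
  for (phi in c(0, pi / 2, pi, 3 * pi / 2, 4.05)) {
    cfg <- quietConfig(nEpisodes = 1L, actionsPerEpisode = 12L,
                       phaseLagRad = phi, seed = 31L)
    f3 <- bandpassFilter(simulateSession(cfg), bandConfig("F3"),
                         continuous = TRUE)
    pd <- windowPeakDelays(f3, makeStimulusTemplate())
    est <- estimatePhaseLag(pd$delayS, 12.5)
    err <- abs(Arg(exp(1i * (est@phiBar - phi))))
    expect_lt(err, 0.1)
  }
})

test_that("noiseless locking yields PLV of 1 to machine tolerance", {
  ## zero response delay keeps both series periodic on the analysis
  ## segment, where the FFT analytic construction is exact
  cfg <- quietConfig(nEpisodes = 1L, actionsPerEpisode = 1L,
                     responseDelayS = 0)
  ep <- synthEpoch(cfg, "non-error", 1L)
  stim <- makeStimulusTemplate(repetitions = 1L)
  seg <- 1:200
  lag <- instantaneousPhaseLag(hilbertAnalytic(ep["O1", seg]),
                               hilbertAnalytic(stim@samples[seg]))
  expect_equal(plv(lag), 1, tolerance = 1e-6)
})
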