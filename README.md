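# SSVEPcoupling

Single-trial detection of error-related potentials (ErrPs) in EEG is hard:
the transient is small, theta-band, fronto-central, and buried in noise.
*Response coupling* pairs the ErrP with an auxiliary signal — a steady-state
visual evoked potential (SSVEP) driven by a 12.5 Hz screen flicker that is
time-locked to each action of an observed agent — and exploits the
interaction between the two. Because the SSVEP is phase-locked to the
stimulus, it also provides something labels cannot: an unsupervised readout
of per-user data quality.

This package implements that analysis chain for researchers in EEG/BCI
signal processing:

* a seeded generator of response-coupled sessions (12-channel montage,
  125 Hz, 1.8 s action windows = 1.6 s flicker + 200 ms off, error
  probability 0.2, pink-noise background, spike/blink artifacts);
* preprocessing: zero-phase 4th-order Butterworth band-passes (1–40,
  10–40, 11–16 Hz), electrode subsets (all / fronto-central /
  parieto-occipital), threshold artifact rejection (75 µV spike, 125 µV
  peak-to-peak), and the 9-cell spatio-spectral evaluation grid;
* phase analysis: analytic signals via the Hilbert transform, sliding
  phase-locking values $\mathrm{PLV} = \frac{1}{N}|\sum_t
  e^{i\Delta\Phi(t)}|$, stimulus templates, and unnormalized
  cross-correlograms whose maxima sit on the lattice
  $\tau = n/F_0 - \bar\Phi/(2\pi F_0)$ — 80 ms apart at $F_0 = 12.5$ Hz —
  from which the mean stimulus–response phase lag $\bar\Phi$ is estimated
  by circular averaging;
* the unsupervised **fidelity score**: the fraction of action windows whose
  cross-correlation peak delay falls within ±40 ms of the cohort's modal
  delay zone, swept over 1–150 stimulus-template repetitions and correlated
  with detection accuracy;
* a classical detector — xDAWN spatial filters, Riemannian tangent-space
  covariance features, elastic-net logistic head — evaluated by stratified
  per-user cross-validation, zero-shot 1-v-1 / 1-v-rest transfer, and the
  full spatio-spectral sweep, all reported as balanced accuracy
  $(\mathrm{TPR}+\mathrm{TNR})/2$.

## Worked example

```r
library(SSVEPcoupling)

## a clean session and a noisy one (10 episodes x 30 actions each)
cfgA <- simConfig(noiseSigma = 2, seed = 1L)
cfgB <- simConfig(noiseSigma = 12, seed = 2L)
sesA <- simulateSession(cfgA, "clean")
sesB <- simulateSession(cfgB, "noisy")

## phase lag and modal delay from the band-passed O1/O2 response
f3 <- bandpassFilter(sesA, bandConfig("F3"), continuous = TRUE)
pd <- windowPeakDelays(f3, makeStimulusTemplate())
peakDelayHistogram(pd$delayS, binS = 0.008)
#> DelayHistogram: 299 windows in 206 bins, modal zone 0.268 s
estimatePhaseLag(pd$delayS, 12.5)
#> PhaseLagEstimate: phiBar 4.048 rad, delta 0.0515 s (F0 12.5 Hz, 299 windows)

## unsupervised data quality: clean vs noisy user
fidelityScore(f3, modalZone = 0.27)
#> [1] 0.5752508  (attributes: nWindows 299, modalZone 0.27, repetitions 1)
f3B <- bandpassFilter(sesB, bandConfig("F3"), continuous = TRUE)
fidelityScore(f3B, modalZone = 0.27)
#> [1] 0.06688963

## single-trial ErrP detection, within-user CV (balanced accuracy, %)
proto <- cvProtocol(folds = 5, reps = 1, outerRepeats = 2, seed = 3)
perUserCV(bandpassFilter(sesA, bandConfig("F1")), proto)$mean
#> [1] 99.50588
```

The delay histogram concentrates at 0.268 s — the $n = 4$ point of the
80 ms maxima lattice for the injected 4.05 rad phase lag — and the phase
estimate recovers that lag from peak delays alone. The fidelity score
separates the clean user (0.58) from the noisy one (0.07) without ever
reading a trial label — integrating more template repetitions
(`fidelitySweep()`) sharpens the contrast further — and the detector
confirms the clean session is highly decodable.

`runPipeline(pipelineConfig(...), outDir)` chains
simulate → preprocess → classify → phaselock → fidelity → report, writing
CSV artifacts, a text report and an md5 manifest; identical config and seed
reproduce identical checksums.

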