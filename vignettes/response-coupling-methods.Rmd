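---
title: "Response coupling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response coupling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(SSVEPcoupling)
```

## The paradigm

A subject watches an agent act in discrete steps. Each action opens a 1.8 s
window: the screen flickers at $F_0 = 12.5$ Hz for 1.6 s (20 cycles) and
then stops for 200 ms. The flicker drives a steady-state visual evoked
potential (SSVEP) over parieto-occipital cortex, phase-locked to the
stimulus; when the agent errs (probability 0.2 per action) the observer
additionally produces an error-related potential (ErrP), a theta-band
(4–8 Hz) fronto-central transient. Because the two signals coexist in every
error window, their interaction — *response coupling* — carries class
information even in channels and bands where the ErrP itself is absent.

This package provides the full analysis chain: a generative model of such
sessions, the preprocessing and 9-cell spatio-spectral evaluation grid, the
phase-locking and cross-correlation machinery, an unsupervised per-user
data-quality ("fidelity") score, and a classical single-trial detector
(xDAWN spatial filters, Riemannian tangent-space features, elastic-net
logistic head) with per-user and cross-user evaluation protocols.

## The phase model

Write the active stimulus as $S_0(t) = A_0 \sin(2\pi F_0 t)$ on
$[0, T_S]$, $T_S = 1.6$ s. The recorded response is analyzed through its
analytic signal $x(t) + i\,\mathcal{H}[x](t) = A(t) e^{i\Phi(t)}$
(`hilbertAnalytic()`, FFT construction). The instantaneous stimulus–response
phase lag is the wrapped difference of the two phase series and its
phase-locking value over $N$ samples is
$\mathrm{PLV} = \frac{1}{N}\left|\sum_t e^{i\Delta\Phi(t)}\right| \in [0,1]$.

Cross-correlating the response with a stimulus template gives, for a
phase-locked response with mean lag $\bar\Phi$, an unnormalized correlogram
proportional to $\cos(2\pi F_0 \tau + \bar\Phi)$ times a slowly varying
envelope. Its maxima therefore sit on the lattice

$$\tau_n = \frac{n}{F_0} - \frac{\bar\Phi}{2\pi F_0} = -\delta + 0.08\,n
\quad (n = 1, 2, \dots),$$

spaced one SSVEP period (80 ms) apart. `estimatePhaseLag()` inverts this:
each observed peak delay contributes the wrapped phase
$(-2\pi F_0 \tau) \bmod 2\pi$ and the estimate is their circular mean. A
delay of 0.26843 s maps back to $\bar\Phi \approx 4.05$ rad; with the
default envelope delay of 0.27 s the $n=4$ lattice point is the modal peak.

Two numerical details matter. First, at 125 Hz one sample quantizes the
implied phase to $2\pi F_0/f_s \approx 0.63$ rad, so peak delays are refined
by a three-point parabolic fit around the correlogram maximum
(`refine = TRUE`); without it noiseless recovery can be off by up to
0.31 rad. Second, the finite-window Hilbert transform of a *delayed*
truncated sinusoid carries edge leakage of order $10^{-3}$ in phase; the
noiseless PLV-equals-one check therefore uses a zero-delay configuration in
which both series are exactly periodic on the analysis segment and the FFT
construction is exact. Under the default 0.27 s delay the noiseless PLV is
≈ 0.999, not 1 − 10⁻⁶.

## The generator

`simConfig()` / `simulateSession()` compose, per trial and channel,

* **pink noise** — $1/f$-shaped Gaussian noise, `noiseSigma` µV (default 3;
  at the default O1/O2 SSVEP gain of 1.3 µV this puts the 11–16 Hz
  band-power SNR at occipital sites near 0 dB);
* **SSVEP** — carrier $\sin(2\pi F_0 t + \varphi)$ with the absolute phase
  lag `phaseLagRad` (default 4.05 rad) and an envelope active from
  `responseDelayS` (default 0.27 s) for `activeS` seconds. Because
  $0.27 + 1.6 > 1.8$, the lagged response persists ≈ 70 ms past the window
  edge; the generator emits that spill-over, phase-continuous, at the head
  of the following window. This is what makes the $n = 4$ lattice point
  structurally dominant — without it the $n=3$ and $n=4$ peaks are
  near-tied and the modal delay is decided by filtering transients;
* **ErrP** (error trials) — a Gaussian-windowed ≈ 7 Hz biphasic waveform
  (negative peak 250 ms, positive peak 320 ms post-action), amplitude map
  `errpGain` peaking at Cz/Fz. Only the theta-band dominance and rough
  peak latencies of ErrPs are well established; the concrete waveform is
  this package's assumption and tests treat it as such;
* **coupling** (error trials) — `couplingEffect` (default 0.2) attenuates
  the SSVEP amplitude by 20% and adds a small Gaussian phase jitter. The
  mechanism of the ErrP–SSVEP interaction is not settled; this knob is a
  deliberately simple surrogate that makes error and non-error windows
  separable from parieto-occipital 11–16 Hz data alone;
* **artifacts** — rectangular > 75 µV spikes on a random channel and
  blink-shaped ≈ 130 µV frontal transients at `artifactRate` (default
  0.02/trial), present solely to exercise the threshold rejection rule.

All randomness derives from integer seeds through a Lehmer step, so a
config is bit-reproducible. What the generator does **not** emulate:
attention drift and vigilance non-stationarity, inter-channel correlated
noise, alpha reactivity, eye-movement spectra, or any realistic ErrP
latency jitter. Passing tests therefore demonstrate internal consistency
of the analysis chain under the stated model, not performance on real EEG.

## Preprocessing

Band-passes are 4th-order Butterworth filters applied forward–backward
(zero phase; two passes double the effective roll-off), each epoch padded
by reflection over one window length. The three bands are F1 = 1–40 Hz,
F2 = 10–40 Hz (theta excluded), F3 = 11–16 Hz; the electrode sets are
E1 = all 12, E2 = fronto-central, E3 = parieto-occipital. For the
phase/fidelity path `bandpassFilter(..., continuous = TRUE)` concatenates
contiguous trials and filters the session as one recording — matching
acquisition-side filtering and preserving the window-boundary spill-over
that per-epoch filtering corrupts.

Artifact rejection flags a trial when any channel deviates more than 75 µV
from its epoch mean (spike rule; the mean-baseline makes the rule immune to
DC offsets) or spans more than 125 µV peak-to-peak, OR-aggregated across
channels. Rejection is applied after broadband (F1) filtering by default;
the order is configurable, as either convention is defensible.

## The fidelity score

For each action window the stimulus template (possibly `r` concatenated
repetitions, re-anchored at the window onset) is cross-correlated with the
band-passed (11–16 Hz) O1/O2-average response and the global-maximum delay
recorded. The score is the fraction of windows whose peak lies within
`toleranceS` (default ± 40 ms, half an SSVEP period) of the modal delay
zone; an ideal recording scores 1. An alternative reading of the
"expected-vs-observed discrepancy" — one minus the rescaled mean absolute
deviation from the modal delay — is available as `method = "mad"`. Both
are documented as interpretations of the expected-vs-observed discrepancy
idea, since no canonical functional form exists for it. The computation
never touches trial labels.

Because an `r`-repetition template is `r` concatenated single-window
templates, the `r`-repetition correlogram of window $i$ is the sum of the
single-repetition correlograms of windows $i, \dots, i+r-1$;
`fidelitySweep()` exploits this to sweep $r = 1..150$ at roughly the cost
of one pass. Windows too close to the end of the recording to fit the
template are excluded, so large `r` integrates more data per window but
analyzes fewer windows.

**Known limitation.** On this stationary generator the score at $r = 1$ is
already an average over ~120 windows, so its sampling error is small and
the fidelity–accuracy correlation *declines* monotonically with $r$
(from ≈ 0.9 at $r=1$). On human recordings, non-stationarities such as
attention drift can instead make intermediate repetition counts optimal;
the generator does not model those, and we document rather than engineer
the difference. The tests assert the properties that do hold (positive
correlation, decline at large $r$, variance compression across users).

## The detector

`fitXdawn()` estimates per-class evoked responses by least squares over the
concatenated recording (for non-overlapping windows this is exactly the
class mean) and solves the generalized eigenproblem maximizing evoked-to-
total power via Cholesky whitening; the top `nFilters = 4` unit-norm
filters per class are kept (the count is a package default).
Each epoch is augmented with the filtered class prototypes, its covariance
shrunk toward the scaled identity with the closed-form
oracle-approximating (OAS) intensity — guaranteeing SPD at the 16-
dimensional augmented size — and mapped to the tangent space at the
Riemannian (affine-invariant) mean of the training covariances, computed by
fixed-point iteration.

The head is an elastic-net logistic regression (mixing 0.5). The
regularization strength is chosen by inner cross-validation maximizing AUC
under inverse-frequency class weights: with the paradigm's ~4:1 imbalance
and ~100-trial training sets, unweighted misclassification selection
reliably degenerates to the majority-class model, which is useless under
the balanced-accuracy metric the protocols report
($100 \cdot (\mathrm{TPR} + \mathrm{TNR})/2$).

Protocols: `perUserCV()` (stratified 5-fold, 4 repetitions, outer repeats
for mean ± sd), `zeroShotGeneralization()` (all ordered 1-v-1 pairs, or
1-v-rest pooling), and `spatioSpectralSweep()` over the 9 (E, F) cells.

## Problem sizes and determinism

The package's own experiments run at desk scale, chosen once: sessions of
10 episodes × 30 actions (300 trials, 12 × 225 samples each); cohorts of
12 users on a 1–20 µV noise ramp; CV at 5 folds × 1 repetition × 1 outer
repeat for the end-to-end run and fidelity sweeps over
$r \in \{1, 5, 15, 50, 100, 150\}$. `runPipeline()` executes
simulate → preprocess → classify → phaselock → fidelity → report, writes
every artifact as CSV with an md5 manifest, and derives every stage seed
from the single global seed; identical config and seed give identical
checksums. The package's functions and `scripts/acceptance.R` are the
command-line surface; artifacts are plain text throughout.

## Degenerate inputs and tie-breaks

All-zero correlograms yield no maxima; ties between equal correlogram
values break toward the earliest delay; the modal histogram zone is the
center of the fullest bin (earliest on ties; bin width one sample, 8 ms,
fine enough to resolve the 80 ms lattice). Local maxima require at least
half the global maximum (`minProminence = 0.5`, a package default — no
criterion is stated in the source material). Fidelity with zero analyzable
windows, PLV of an empty series, single-class classification inputs and
out-of-range repetition counts all signal errors rather than returning
silent defaults. Phase estimates snap the $2\pi$ wrap-around boundary to 0.
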