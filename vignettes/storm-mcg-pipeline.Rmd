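---
title: "Denoising unshielded magnetocardiography: models and methods"
author: "stormmcg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising unshielded magnetocardiography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiac electrical activity produces magnetic fields of 50–100 pT at the
torso. Outside a magnetically shielded room those fields are buried
under environmental interference that reaches hundreds of pT/√Hz at
1 Hz — three to four orders of magnitude above the cardiac signal in the
low-frequency band. `stormmcg` implements the processing chain that
makes unshielded magnetocardiography (MCG) viable with a wide-dynamic-range
magnetoresistive sensor array: 42 uniaxial recording sensors on a 6 × 7
grid (4 cm pitch), 21 reference sensors surrounding the grid that see
the interference but essentially no cardiac field, and one simultaneous
ECG channel, sampled at 5000 Hz for 120 s.

The chain has a fixed order:

1. **Digital filters** — 0.3–40 Hz bandpass, 50 Hz notch.
2. **Adaptive noise cancellation (ANC)** — interference estimated from
   the reference channels and subtracted.
3. **R-peak synchronized averaging** — epochs aligned on ECG R waves
   and averaged, suppressing non-phase-locked noise by about √N.
4. **Bayesian signal-space projection (SSP)** — constrained factor
   analysis separating residual spatially-structured interference from
   the cardiac field, using an empty-room recording to pin down the
   interference subspace.
5. **Metrics and maps** — QRS signal-to-noise ratio and isomagnetic
   field maps.

## Models

### Measurement model

Per time sample the 42-channel measurement is modeled as

$$ y(t) = A\,x(t) + B\,u(t) + \varepsilon(t), $$

where $A$ ($42 \times p$) loads the cardiac signal factors $x(t)$, $B$
($42 \times q$) loads the interference factors $u(t)$, and
$\varepsilon$ is stationary sensor noise, uncorrelated across channels,
with diagonal covariance $\Psi$. $B$ is identified by maximum-likelihood
factor analysis (EM) of the empty-room noise (ERN) covariance,
$\Sigma_{\mathrm{ern}} \approx BB^\top + \Psi_{\mathrm{ern}}$. $A$ is
then fitted to the averaged MCG waveform by EM on the joint loading
matrix $[A\;B]$ with the $B$ block frozen; only $A$ and $\Psi$ are
updated (the M-step is exact for diagonal $\Psi$, so the observed-data
log-likelihood is non-decreasing — asserted in the tests). The
denoised signal is the posterior mean projection

$$ \hat{y}_S = A\,\hat{x}, \qquad
   [\hat{x};\hat{u}] = [A\;B]^\top (AA^\top + BB^\top + \Psi)^{-1} y. $$

Key assumption: the empty-room interference shares its *spatial*
structure with the in-session interference (recorded daily in the
hardware protocol, regenerated with an independent realization in the
simulator). When sudden, spatially novel interference appears during a
session, the frozen $B$ cannot represent it — a known limitation of the
approach, shared by the hardware system.

### Covariance scaling of the interference model

The ERN is recorded at raw scale but SSP is applied to the R-averaged
waveform, whose non-phase-locked noise covariance is the raw covariance
divided by the number of averaged epochs N. `fit_interference_model()`
therefore takes a `cov_scale` argument and the pipeline passes `1/N`,
so that $BB^\top$ and the data covariance live on the same scale and
the posterior weighting is calibrated. Whether $\Psi$ should be carried
over from the ERN fit or re-estimated during the joint fit is an open
modeling choice; we re-estimate it (with the $B$ block frozen), which
lets the averaged data speak for its own residual noise level.

### Factor counts

Neither $p$ nor $q$ is identifiable from first principles here. Default
$q$ is chosen per session by a scree rule on the (ANC-cleaned,
averaged-scale) ERN covariance — eigenvalues above twice the median
eigenvalue, capped at 8 — because ANC leaves a low-rank interference
residual by construction.

The signal factor count $p$ is chosen by **evoked-variance dominance**:
eigenvalues of the averaged-waveform covariance of at least 1% of the
leading eigenvalue, floor 1, cap 4. The rationale comes from an
observed failure mode of a fixed $p$: the ANC stage injects
reference-sensor noise into the recording channels (the cancellation
weights applied to the references' own white noise), which is
channel-correlated, specific to the session, and representable by
neither the frozen $B$ (it was not present in the empty room) nor the
diagonal $\Psi$. When $p$ exceeds the true rank of the averaged cardiac
field — rank 1 for a fixed-orientation dipole — the surplus factors
latch onto exactly that residual structure and the projection
reconstructs baseline noise, occasionally cancelling the denoising
gain. Since R-synchronized averaging concentrates the phase-locked
field into components orders of magnitude above the residual noise,
a relative-dominance threshold separates the two scales cleanly.
Both counts are configurable, and a fixed $p$ can still be passed.

### Filters

The hardware-motivated defaults are a 0.3–40 Hz bandpass and 50 Hz
notch, applied forward–backward (zero phase) so the R-peak latency used
for epoch alignment is untouched. The order/family are our choices
(classical biosignal practice): 4th-order Butterworth edges and an RBJ
biquad notch with Q = 30. At 5 kHz the 0.3 Hz edge corresponds to a
normalized frequency of 1.2 × 10⁻⁴, where single-polynomial IIR
realizations are numerically unstable; the package designs and applies
all filters as cascaded second-order sections (biquads), which are
exact there. Edge effects are handled by odd-reflection padding, and
the first/last 2 s are flagged as transient and excluded from model
fitting and spectral metrics.

### ANC

The default adaptation is offline regularized least squares over the
whole (non-transient) recording: seated-session interference is
quasi-stationary, and the offline projection makes the residual exactly
orthogonal to the lagged reference regressors. Three taps per reference
(centered lags) absorb small phase mismatch; magnetic coupling itself
is instantaneous. A normalized-LMS mode (step 0.01) is provided for
streaming use and converges to within ~10% of the offline residual
power on stationary interference. Whether the original system adapted
per sample or per block is not public; both modes are provided.

### R detection and averaging

The detector is the classic filtered-derivative-energy chain: 5–25 Hz
zero-phase bandpass, squaring, 150 ms moving integration, adaptive
threshold at 0.4 × a rolling 95th percentile, 200 ms refractory,
polarity-robust by construction. The epoch window is (−300, +600) ms —
covering P through T at resting heart rates — with baseline correction
over the first 100 ms of the window. Epoch rejection is off by default
(an optional peak-to-peak threshold exists).

### SNR and maps

SNR is `20·log10(QRS amplitude / baseline amplitude)` with the baseline
being the 100 ms window ending at P onset. P onset is a configured
latency (default −250 ms relative to R): automatic onset detection on
noisy unshielded data is unreliable, and the hardware workflow
determined it manually. Amplitude conventions default to peak absolute
deviation (QRS) and RMS about the mean (baseline); peak-to-peak
variants are selectable. The reporting channel maximizes QRS amplitude
and is selected on the final processing stage, then held fixed across
stages so per-stage SNRs are comparable. Isofield maps interpolate the
42 sensor values with separable piecewise-cubic splines — an
interpolant, exact at the sensor nodes, with no extrapolation beyond
the grid hull — at 10× upsampling.

## The synthetic-session simulator

No public recording exists for this system, so validation rests on a
simulator that reproduces the statistical structure the pipeline
assumes:

* **Cardiac source** — a single current dipole 12 cm in front of the
  array center, oriented in-plane (producing the classic two-pole
  isofield pattern), with a sum-of-five-Gaussians PQRST time course
  (relative amplitudes 0.08, −0.12, 1.0, −0.25, 0.35 at −200, −25, 0,
  +30, +250 ms; widths 25, 8, 12, 12, 50 ms). P and T are an order of
  magnitude below R, so resolving P genuinely requires the later
  denoising stages. Beats are placed at 60 bpm with 30 ms RR jitter;
  the moment is scaled so the peak field at the array is 100 pT.
* **Interference** — rank-4: fixed uniform/gradient far-field spatial
  patterns (what distant sources produce at a compact array) driven by
  a 50 + 150 Hz powerline course, two 1/f-amplitude drift courses, and
  one broadband AR(1) course. Drift amplitude is calibrated so a
  central channel sees ≈ 345 pT/√Hz at 1 Hz before cancellation — the
  regime unshielded hardware reports.
* **Sensor noise** — white, 3.1 pT/√Hz per channel.
* **References** — see the interference and noise; cardiac leakage
  keeps the forward-law spatial pattern but its gain is bounded so the
  mean reference cardiac energy is 5 × 10⁻⁵ of the mean recording-channel
  cardiac energy (≥ 100× amplitude attenuation). At the documented ring
  geometry the bare forward law would leak more; real reference modules
  are placed and oriented to reject the near-field source, and ANC's
  signal-preservation guarantee rests on that rejection, so the
  attenuation contract takes precedence over raw distance scaling.
* **Empty room** — same spatial patterns, independent time-course
  realization, no cardiac source.

The exact reference-sensor geometry of the hardware is unpublished; the
deterministic ring used here (21 sensors, 6 cm outside the grid, axes
cycling through three orthogonal directions) is a documented stand-in
that spans the interference field directions.

What the simulator does *not* model: torso volume-conductor effects,
multi-dipole or arrhythmic activity, motion artifacts, sensor
calibration drift, or non-stationary interference whose spatial
structure changes mid-session. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
clinical performance on real recordings.

## Numerical choices

* EM: relative log-likelihood tolerance 10⁻⁶, max 500 iterations, Ψ
  floored at 10⁻¹² of the mean channel variance (Heywood guard; the
  floor is a box constraint, so monotonicity survives).
* Loading sign convention: each column's largest-magnitude entry is
  made positive; tests compare subspaces (largest principal angle), not
  raw matrices.
* A numerically singular model covariance in `denoise()` is solved via
  a symmetric regularized inverse and flagged.
* ANC ridge default 10⁻³ relative to mean regressor power; zero-λ mode
  available where exact orthogonality is wanted.
* Ties in channel selection break deterministically to the lowest
  channel index.

## Problem sizes used in validation

The test suite exercises unit-level properties on compact sessions
(10–30 s at 500 Hz) and the end-to-end scientific checks at the study
scale the defaults encode: 120 s sessions at 5000 Hz across 10 seeds
for the stage-ordering property (SNR strictly increasing across
filters → ANC → SSP, median post-SSP ≥ 30 dB), a full-scale session for
the ANC suppression/distortion contract (≥ 20 dB interference
suppression, ≤ 5% cardiac distortion against simulator ground truth),
and 20 seeded replicates for factor-subspace recovery (median principal
angle < 5° for the interference subspace, < 10° for the signal
subspace, template correlation ≥ 0.98).

## Worked example

```{r example}
library(stormmcg)

ses <- generate_session(seed = 1)     # 120 s, 5 kHz, with ground truth
res <- run_pipeline(ses)
res$snr                                # filters / anc / ssp / ecg, dB
plot(res$maps$r)                       # isofield map at the R latency

# cohort benchmark reference
tb <- cohort_snr_reference()
summarize_cohort(tb$bayesian_ssp_db)$label
```

## Known limitations

* R-triggered averaging presumes sinus rhythm; arrhythmia is out of
  scope by construction.
* The frozen interference subspace cannot represent interference that
  appears only during the session.
* The SNR depends on the configured P-onset latency; the automatic
  alternative is heuristic.
* The simulator's interference spectra are plausible stand-ins for an
  unshielded hospital environment, not reconstructions of any specific
  site.
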