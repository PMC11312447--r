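---
title: "Modeling brain-body arousal coupling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling brain-body arousal coupling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arousalwave)
```

## The problem

Resting-state fMRI is dominated by a widespread low-frequency (0.01–0.1 Hz)
fluctuation — the *global signal* — that co-varies with autonomic
physiology: heart rate rises, peripheral vascular tone drops (smaller PPG
pulse amplitude), respiratory volume and EEG power increase, skin
conductance and pupil diameter follow. `arousalwave` implements the
quantitative machinery for characterizing these co-fluctuations: component
models of the global signal and its traveling-wave structure, lagged
pairwise and joint coupling statistics with permutation inference,
event-related responses, and multi-echo decay modeling that separates
BOLD-like (T2\*) from non-BOLD (S0) effects.

Because the multimodal recordings such analyses require are large and
access-restricted, the package ships a *synthetic generator* whose ground
truth supports oracle testing of every stage. This vignette documents the
models, the tunable parameters, and the choices made where the design was
genuinely open.

## The models

### Global signal and its phase structure

The global signal is the first principal component (PC1) of the demeaned
frames × voxels matrix, computed by SVD (exact LAPACK by default; a
randomized range-finder solver is available and agrees to 1e-8 on
desk-scale matrices). Its sign is fixed so the mean weight over
gray-labeled voxels is positive: positive scores then mean positive
cortical signal and negative CSF signal.

Time-lag structure is modeled by complex PCA: each voxel series is replaced
by its analytic signal (FFT Hilbert transform), and the complex SVD's first
right singular vector gives complex weights whose angles form the
*phase-delay map* on [0, 2π). For a narrowband latent at frequency *f*, a
voxel lagging by δ seconds acquires phase 2π·f·δ, so the map is a lag map
up to a global rotation and scale. The global phase is arbitrary; we rotate
so the gray-voxel mean weight is real and positive. When a reference series
is supplied (e.g. PPG amplitude), the rotation can instead anchor phase
zero to the reference's troughs, mirroring the convention of anchoring the
pattern's onset at peripheral vasoconstriction events.

The *movie* reconstruction sorts frames into 30 equal phase bins of the
component scores and averages the real part of the rank-1 complex
reconstruction within each bin. Degenerate inputs matter here: a carrier
with an integer number of samples per cycle visits only that many distinct
phases, leaving bins empty; the function reports bin occupancy in its error
message so the caller can reduce the bin count.

### Pairwise and joint coupling

Cross-correlation curves are product-moment correlations
r(i) = cor(x[t+i], y[t]) at integer frame lags over the overlapping
segment, splined onto a 1 s grid spanning ±30 s. With x the global signal
and y a physiological signal, a peak at positive lag means the global
signal *follows* the physiology.

Impulse responses solve g(t) = Σ_τ h(τ) p(t−τ) + ε under a zero-mean
Gaussian-process prior on h with squared-exponential covariance (length
scale 3 lag samples, variance 1, both configurable; the lag grid defaults
to −10…+30 s, with negative lags capturing response components that precede
the input). The estimate is the posterior mean K Aᵀ(A K Aᵀ + σ²I)⁻¹ g with
A the lagged design matrix; σ² is selected by maximizing the exact GP
marginal likelihood over a 20-point log-spaced grid. In the diagonal-kernel
limit the estimator reduces to ridge regression, which the tests verify
against the closed form. One caveat documented by the tests: for a
noiseless identity system the MAP correctly approaches the true delta
response, which *cannot* correlate highly with a kernel-smoothed impulse
(the exact delta's correlation with a length-scale-3 Gaussian bump is
~0.61); the identity test therefore asserts peak location and
concentration, not resemblance to the smoothed impulse.

### Multi-set CCA with a distributed-lag basis

Each signal contributes a "set" of three columns: lagged copies over 0–10 s
combined through a natural cubic spline basis (boundary knots at 0 and
10 s, one interior knot at 5 s, intercept included — three basis
functions). This distributed-lag compression avoids the collinearity of
using every lag as a predictor. The first canonical component solves the
SUMCOR generalized eigenproblem C w = λ D w, with C the covariance of all
concatenated columns and D its block-diagonal within-set part; a ridge
proportional to each column's own variance (default 1e-6) conditions D and
keeps the solution exactly invariant to per-column rescaling. The reported
statistic is r̄, the mean off-diagonal correlation of the unit-variance
canonical variates. With two sets the solution coincides with classical
CCA (verified against `stats::cancor`).

Inference permutes the *subject assignment* of each signal independently
before temporal concatenation: signal A from subject 1 may be paired with
signal B from subject 7. This removes cross-signal coupling while leaving
each series — and hence its autocorrelation — byte-identical to some
subject's original. The p-value uses the add-one correction
(1 + #{null ≥ observed}) / (n_perm + 1); the default is 1000 permutations
(tests and the acceptance script scale down to 199 to fit their time
budget, which changes only the resolution of the p-value).

The global-signal (PC1) set is lag-expanded identically to the
physiological sets by default; an unlagged option exists.

### Events and multi-echo

Event-related averages z-score each run, linearly interpolate each trial's
segment onto a 0–29 s grid at the TR, and average over trials; uncertainty
comes from resampling *subjects* with replacement (cluster bootstrap,
default 500 replicates — a methods/figure discrepancy in the source
material lists both 100 and 500; we default to the larger). Trials closer
than 30 s to a neighbor are removed pairwise. EEG power is normalized as
10·log10(P/P̄_baseline) with a 1 s pre-onset baseline.

Multi-echo volumes are fit per frame and voxel by ordinary least squares of
ln S on echo time: T2* = −1/slope, S0 = exp(intercept). Nonpositive
samples or nonphysical slopes flag the fit invalid rather than being
imputed. RETROICOR cardiac regressors are cos(mφ), sin(mφ) for m = 1..2
(order configurable) of the linear intra-beat phase, evaluated at each
slice's acquisition times; per voxel the maximum R² across slice-specific
regressor sets is reported.

## The synthetic world

`synth_config()` fixes the stated world: a 600 s run at TR 1 s, 1000
voxels (60% gray / 25% white / 15% CSF), 250 Hz peripheral recordings,
echo times 13.7/30/47 ms, and sparse cues with ~60–131 s jittered
inter-stimulus intervals. The latent arousal process is white noise passed
through the same fifth-order zero-phase 0.01–0.1 Hz bandpass used in
preprocessing, then standardized — its power is in the analysis band by
construction. Voxels are sign-flipped (CSF negative), lag-shifted
(uniform 0–6 s, edge-padded interpolation — never circular) copies of the
latent plus iid noise with SD 0.5 (amplitude SNR 2).

Couplings are free parameters; the source material reports correlation
magnitudes, not gains. Defaults (gain, lag, sign): heart rate (0.10, 1 s,
+), PPG amplitude (0.40, 2 s, −), respiration (0.30, 0.5 s, +), skin
conductance (1.0, 4 s, +), pupil (1.0, 0.5 s, +), EEG envelope (0.5, 0 s,
+), chosen once to put extracted-feature correlations in the 0.2–0.4 range
at default noise on typical draws. Amplitude-like quantities (beat
amplitude, breathing rate/depth) are modulated multiplicatively,
`exp(gain · sign · latent)`: additive gains of this size would drive them
to zero, which is both unphysical and makes systoles undetectable. The PPG
waveform is a fixed two-bump template resampled per inter-beat interval;
the recorded ground-truth beat time is the template's systolic peak
(0.15 cycles into the beat), not the cycle origin. The evoked response is
a difference of gamma densities with a unit peak at ~4 s and a 1.5× deeper
undershoot at ~14 s.

What the generator does *not* emulate — and hence what a green test does
not establish: scanner artifacts (motion, spin history), hemodynamic
differential equations, CO2 dynamics, EEG gradient/ballistocardiogram
artifacts, spatial autocorrelation of real anatomy (tissue labels are
block assignments; the lattice exists to exercise NIfTI I/O). Spatial
smoothing therefore defaults to 0 mm in the synthetic pipeline
(conventional 5 mm for real data): smoothing a spatially random lag map
would destroy the very structure being recovered.

## Numerical choices

- **IIR filters are second-order-section cascades.** A tenth-order 0.75 Hz
  lowpass at 250 Hz (normalized cutoff 0.006) is unstable in expanded
  transfer-function form; SOS biquads are stable and match an external
  reference implementation to ~1e-8. Zero-phase filtering runs
  forward-backward over an odd-reflected extension whose length is the
  larger of 3× the filter length and two cycles of the lowest passband
  frequency — 3× the order alone is far shorter than the transient at
  extreme rate/cutoff ratios. Inputs are demeaned before bandpass
  filtering so constants map exactly to zero.
- **Resampling** anti-aliases with a zero-phase frequency-domain lowpass
  (raised-cosine rolloff to the target Nyquist) before cubic
  interpolation; single-stage IIR decimation is unstable at the 250:1
  ratios involved, and the choice of algorithm was explicitly open.
- **Monotone cubic interpolation** uses the Fritsch–Carlson construction
  (`splinefun(method = "monoH.FC")`), cross-checked in the tests against
  an independent implementation of the published algorithm; extrapolation
  beyond the first/last beat holds the boundary value.
- **Respiratory phase monotonization** removes both endpoints of every
  decreasing phase step before linear re-interpolation each iteration
  (cap 50); removing only the trailing point can stall when a slip touches
  the record boundary.
- **Per-run z-scoring before concatenation** (PCA/CPCA) prevents
  high-variance runs from dominating the group component; the source
  material is silent on this, and the flag can be disabled.
- **Ties and degenerate inputs**: constant voxels get R² = 0 with a flag;
  empty phase bins are an error listing occupancy; fewer than two usable
  echoes flags the fit invalid rather than erroring the whole volume.

## Known limitations

- The NIfTI-1 reader/writer covers exactly what the pipeline emits
  (single-file little-endian, float32/float64/int16, identity
  orientation); it is not a general-purpose implementation.
- Volume-wise T2*/S0 fits are noisy at realistic noise levels — a property
  of the method, not the implementation; the acceptance checks use median
  statistics for this reason.
- The permutation test requires equal frame counts across subjects.
- MCCA extracts only the first canonical component.
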