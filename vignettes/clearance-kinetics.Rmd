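---
title: "Modeling brain solute clearance from DCE-MRI time signal curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling brain solute clearance from DCE-MRI time signal curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitcm)
```

## The problem

After infusion of a gadolinium-based contrast agent into the cisterna
magna, T1-weighted signal enhancement tracks the tracer as it spreads
through CSF spaces, enters brain tissue and is cleared again. Region-wise
**time signal curves** (TSCs) — percent signal change from the pre-contrast
baseline, `100·(S(t) − S_BL)/S_BL` — show a delayed rise, a peak, and a slow
decay over a 6-h acquisition (40 frames in the default grid). The package
quantifies these curves and derives a mechanism-independent measure of how
efficiently a region clears solutes.

## Curve parameterization

Four descriptors are computed per curve:

* **Arrival time `t_a`** — the earliest sample followed by three successive
  strict increases. "Increase" is strictly greater; no noise band is
  applied, because monotone runs of length three are already rare under
  pure noise. On a constant or non-arriving curve `t_a` is undefined (`NA`),
  which is a legal outcome, not an error.
* **Peak** — global maximum and its time; ties resolve to the earliest
  time, so a plateau reports its onset.
* **AUC** — trapezoidal integral over `[0, 360]` min on the native,
  possibly non-uniform grid. The trapezoid rule is exact for the
  piecewise-linear curves the sampling defines, which the tests exploit.
* **Decay rate `b`** — least-squares fit of `a·e^{−b·t}` to samples at
  `t ≥ t_max + 90` min. Absolute acquisition time is used, so `a` depends
  on the window while `b` does not. Fits are discarded when the peak falls
  within 90 min of the end, fewer than 3 samples remain, or `b ≤ 0`.
  Because the model is linear in `a` for fixed `b`, the amplitude is
  profiled out in closed form and the fit is a 1-D minimization over `b`
  (searched over `[-0.2, 1]` min⁻¹ so rising tails are detected rather
  than clipped); this is exact on noise-free exponentials to ~1e-10 and
  strictly scale-equivariant.

## The two-compartment exchange model

A brain region is split into a closed **outer envelope** of uniform
thickness `s` voxels and the enclosed **inner** rest. The envelope is the
region minus its `s`-fold 6-connected erosion: face-connectivity gives a
uniform thickness along the axes, and out-of-volume voxels count as
background so surfaces at the image border peel too (18/26-connectivity is
a switch). These compartments are geometric, not anatomical — at MRI
resolution they cannot be assigned to tissue layers.

Compartment curves `I_out`, `I_in` are **sums** of per-voxel percent-change
signals (sums, not means, so the curves carry volume information into the
exchanged-volume identities below; means remain available for region-style
curves). The model is first-order exchange with constant rates:

$$\frac{dI_{in}}{dt} = k_1 I_{out}(t) - k_2 I_{in}(t), \qquad I_{in}(0)=0,$$

whose unique causal solution is the convolution
$I_{in}(t) = k_1 \int_0^t e^{-k_2 (t-l)} I_{out}(l)\,dl$.

**Quadrature.** The convolution is evaluated segment by segment treating
`I_out` as piecewise linear and integrating against the exponential kernel
in closed form (an exponential-integrator recursion). Naive trapezoid
quadrature of the kernel would carry a relative error of order
`(k₂·Δt)²/12` — several percent at 9-min frame spacing and `k₂ = 0.1`
min⁻¹ — whereas the chosen scheme is exact for piecewise-linear inputs;
against refined Runge-Kutta integration of the ODE it agrees to ~1e-9
relative L2. For small `k₂·Δt` the coefficients switch to series form to
avoid cancellation.

**Estimation.** `(k₁, k₂)` minimize the Euclidean norm of
`I_in − Ĩ_in(k₁, k₂)` over the sampled time points (no time weighting on
non-uniform grids; a trapezoid-weighted objective would change little at
near-uniform spacing and is deliberately not the default). A 12×12
log-spaced grid over `[1e-5, 1]` min⁻¹ locates the basin; Nelder-Mead on
log-rates polishes it. Rates are constrained nonnegative: negative rates
are unphysical and make the sign of the net exchange ratio
uninterpretable. A flat-zero `I_in` with active `I_out` is a degenerate
direction (`k₁ = 0` optimal, `k₂` unidentified) and is flagged unusable
rather than reported.

**Volumes and NER.** `V_out` and `V_in` are trapezoidal integrals of the
curves from the time origin to the last acquired frame ("end of
experiment"). With constant rates the exchanged volumes are
`V_out→in = k₁ V_out` and `V_in→out = k₂ V_in`, and

$$\mathrm{NER} = \frac{V_{in\to out}}{V_{out\to in}}
             = 1 - \frac{I_{in}(T)}{k_1 V_{out}}.$$

The second identity (integrate the ODE) shows what NER measures: the
fraction of tracer that entered the inner compartment and has already left
it again by the end of the experiment. NER → 1 as the washout completes;
NER < 1 quantifies net retention. Units of `V` are signal·time and are
reported as arbitrary units — the mapping to physical tracer volume is not
defined by the data.

**Thickness search.** The split–aggregate–fit procedure runs for
`s = 1…17` (upper bound configurable) and the misfit
`‖I_in − I_in^{sol}‖₂` is recorded both absolutely and as percent of
`‖I_in‖₂`. The **percent** misfit is what the search minimizes: because
compartment curves are voxel sums, the absolute misfit shrinks trivially
as the inner compartment shrinks, which would bias the argmin toward the
thickest envelope; the relative misfit makes thicknesses comparable. Ties
resolve to the smallest `s`.

**Quality control.** Fits whose `V_out` or `V_in` fall below 5% of the
cohort median (per quantity) are flagged unusable — small tracer volumes do
not constrain the rates. Thresholds only ever change flags, never fitted
values.

## The synthetic world

The generator emulates the phenomenology the pipeline must handle, not MRI
physics:

* **Input curves** are gamma variates
  `A·((t−t₀)/(ατ))^α e^{α−(t−t₀)/τ}` — the standard delayed-rise /
  peak / slow-decay tracer-input shape; the peak equals `A` at
  `t₀ + ατ` exactly, which pins the amplitude parameter to an observable.
  The data themselves suggest no specific input family; this is the
  module's documented convention.
* **Inner curves** integrate the exchange ODE (classical RK4 on a ≥10×
  refined grid) from the noise-free outer curve with planted `(k₁, k₂)`.
* **Noise** is additive Gaussian on percent-change values — magnitude MRI
  noise at the SNR of these acquisitions is near-Gaussian; a Rician option
  is deliberately deferred. Default `noise_sd = 0.5`% is of the order of
  the baseline variability visible in such recordings.
* **Per-animal jitter** is lognormal (σ = 0.05 on the log scale) on
  amplitude and rates, so cohorts have realistic between-animal spread
  while staying centered on their preset.
* **Condition presets** mirror the qualitative ordering of the anesthetic
  regimens: MED arrives early with high amplitude and fast exchange
  (planted NER ≈ 0.964 on the default grid), ISO+MED similar with smaller
  `k₂` (≈ 0.943), ISO and the acetazolamide variants late, low-amplitude
  and low-volume (these are the cohorts the QC gate tends to exclude).
  The preset numbers are the generator's own stated world — illustrative,
  not measured data.
* **Shell phantoms** place a cube (edge > 2·thickness) in a padded
  background at baseline intensity 100, with the envelope carrying
  `100 + I_out(t)` and the core `100 + I_in(t)`, so percent-change
  normalization recovers the planted curves exactly and the planted
  thickness is recoverable by the search.

A green test on this world establishes that the estimators recover planted
kinetics under Gaussian noise and ideal geometry. It does **not**
establish robustness to motion, registration error, partial-volume
effects, B1 inhomogeneity, or non-Gaussian noise — real data carry all of
these.

## Calcium band power

The recorded filter description for the 2-kHz fluorescence traces is
internally inconsistent (a 200-Hz bound cannot apply at a 60-Hz sampling
rate), so the implementation adopts the only self-consistent reading:
filter at the native rate with passband edge 20 Hz and stopband edge
40 Hz, then resample to 60 Hz. The filter is a zero-phase frequency-domain
lowpass with a raised-cosine transition; the trace is reflection-padded by
1 s with a taper to the trace mean so the circular FFT boundary is
continuous (an untapered boundary jump leaks low-frequency power through
the passband — this was caught by the 100-Hz-tone test). As with any
zero-phase filter, the first and last second can carry a boundary
transient.

Segments of 2 min are cropped every 12 min — the only periodicity
consistent with 30 spectra in 6 h. Spectra are plain mean-removed
periodograms (no taper, matching the original analysis's minimal
description; Welch averaging is a flag), and band powers sum one-sided
spectral values with bin centers in `[lo, hi)`, so the bands 0.1–1, 1–4
and 1–20 Hz partition cleanly and total power satisfies Parseval against
the signal variance. The linear mixed-effects model of time dependence is
out of scope; only group comparisons are provided.

## ADC and ROI changes

ADC fitting uses log-domain linear regression weighted by `S²` — the
standard linearization whose weights make it agree with nonlinear least
squares to first order; it is exact on noise-free mono-exponentials and
reduces to `ln(S₁/S₂)/(b₂−b₁)` for two b-values. The unweighted `nls`
route is a flag. The aqueductal single-shell value
`ln(S_ref/S_b)/b` is labeled a flow-sensitized magnitude surrogate: in
flowing CSF the attenuation mixes flow dephasing with diffusion and
carries no directional information. ROI percent changes divide by the
initial (ISO-condition) value.

## Statistics

The decision tree mirrors the study design: a parameter is "normal" only
if **no** group (across all conditions and regions supplied) rejects a
Kolmogorov–Smirnov test with estimated mean/SD. Estimated parameters make
plain KS anti-conservative, so Lilliefors-corrected critical values are
used (Stephens' approximation `c_α/(√n − 0.01 + 0.85/√n)`); the Monte-Carlo
level of this gate is verified in the tests. The verdict selects ANOVA vs
Kruskal–Wallis for the omnibus and equal-variance t-test vs Mann–Whitney
for all unordered post-hoc pairs — one branch per table, never mixed. No
multiplicity correction is applied by default (matching the study's
reporting; a `p_adjust` argument exists). Post-hocs are not gated on
omnibus significance by default, since the study reports both side by
side. Boxplot summaries use type-7 (linear interpolation) quantiles,
fixed for reproducibility; significance annotation is `*`/`**`/`***` at
0.05/0.01/0.001.

## Numerical and design choices, collected

* Time origin `t = 0` is the pre-contrast baseline frame; all integrals
  start there. Frame times are arbitrary strictly increasing stamps — no
  uniform spacing is assumed, since the acquisition timing is only
  approximately regular.
* Percent-change convention `(S − BL)/BL·100`: an unchanged region has
  AUC exactly 0.
* Erosion connectivity 6 by default; "thickness" is plain erosion depth,
  not geodesic depth within the region.
* Exchange-rate search space `[1e-5, 1]` min⁻¹, log-spaced; refinement in
  log coordinates keeps rates positive without explicit constraints.
* Configs are JSON (`jsonlite`); all randomness flows from one root seed,
  split deterministically per cohort and animal, so runs are byte-identical
  under a fixed seed.
* NIfTI support is a minimal built-in NIfTI-1 subset (3D/4D, common
  datatypes, both endians) — sufficient for label volumes, dynamics and
  masks; headers beyond voxel size are not interpreted, and no resampling
  or registration is performed.

## Known limitations

* The two-compartment model is deliberately mechanism-free: it cannot
  attribute transport to diffusion vs advection or to anatomical pathways.
* Constant rates over 6 h are an approximation; state changes during the
  experiment violate it.
* The QC volume threshold (5% of cohort median) is a pragmatic default,
  not an estimated operating point.
* The synthetic generator omits MRI physics and spatially correlated
  noise; phantom geometry is cubic.
* With strongly non-uniform grids the unweighted discrete L2 objective
  weights densely sampled epochs more — the trapezoid-weighted objective
  flag addresses this if needed.
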