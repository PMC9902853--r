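---
title: "SRTM quantification and the flow sensitivity of SUVr: models, calibration and design choices"
author: "srtmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SRTM quantification and the flow sensitivity of SUVr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtmsim)
```

## The model

The simplified reference tissue model (SRTM) expresses a target-region
time-activity curve (TAC) through the reference-region curve with three
parameters — relative delivery $R_1$, target efflux $k_2$ (1/min) and
binding potential $BP_{ND}$:

$$C_T(t) = R_1\,C_R(t) + \left(k_2 - R_1 k_{2a}\right)
  \left[C_R \otimes e^{-k_{2a} t}\right](t),
  \qquad k_{2a} = \frac{k_2}{1 + BP_{ND}}.$$

Its assumptions: both regions are well approximated by one-tissue
kinetics, the reference region is devoid of specific binding, and both
share the nondisplaceable distribution volume.  The distribution volume
ratio is $DVR = BP_{ND} + 1$; $R_1$ tracks relative cerebral blood flow.
SUVr is the duration-weighted activity ratio over a late static window
(80–100 min by convention).  Because SUVr is read out before true
equilibrium, it overestimates DVR and inherits a flow sensitivity that
DVR, by construction, does not have — the central phenomenon this package
quantifies.

A flow change of fraction $\delta$ is modelled as
$R_1 \to R_1(1+\delta)$, $k_2 \to k_2(1+\delta)$ with $BP_{ND}$ fixed:
delivery and efflux scale together, so the true DVR is invariant and any
SUVr response to $\delta$ is pure perfusion artefact.  The default scope
perturbs the target region only ("regional" flow change); a global scope
that also rescales the reference kinetics is available.

## Fitting: basis-function RPM

`fit_srtm()` linearizes SRTM over a grid of $k_{2a}$ values (receptor
parametric mapping): for each grid point the model is linear in
$(\theta_1, \theta_2) = (R_1,\; k_2 - R_1 k_{2a})$ and solved by weighted
least squares; the grid point minimizing the weighted residual sum of
squares is selected and mapped back to $(R_1, k_2, BP_{ND})$.

Numerical choices, and why:

* **Grid**: 64 log-spaced points on $[0.006, 0.6]$ min$^{-1}$,
  configurable.  The range spans physiological tau-tracer kinetics; the
  density is set by the recovery requirement below.
* **Continuous polish**: pure grid selection quantizes $k_{2a}$ (about
  7.6% spacing at 64 points), which propagates into a few-percent error
  in $k_2$.  After selection, the WRSS — locally parabolic in
  $\log k_{2a}$ — is interpolated through the selected point and its two
  neighbours and refit once at the vertex.  One extra basis evaluation
  buys noiseless round-trip recovery of all three parameters to a few
  parts in $10^3$ (the test suite enforces 1%).
* **Convolution**: the exponential-kernel convolution is evaluated on a
  uniform fine grid (default $\Delta t = 0.05$ min) treating the curve as
  piecewise linear; the per-step integral and the frame means of the
  convolution are computed in closed form, so the only discretization
  error is the piecewise-linear representation itself.  Halving the fine
  step changes frame values by $<0.05\%$.
* **Frame means**: SUVr and all frame averages weight partial overlaps by
  overlap duration (half-open intervals), making results independent of
  where frame boundaries fall within a window.
* **Weights**: `fit_srtm()` defaults to uniform weights, keeping the
  linear algebra transparent.  The noise model (below) has frame variance
  $\propto C^2/\Delta t$, so the pipeline-level default is the matching
  inverse-variance weighting `"ivar"` ($w_i = \Delta t_i / C_{R,i}^2$,
  floored at 5% of the reference peak); plain `"duration"` weights are
  also available.  Inverse-variance weighting materially improves the
  precision of $R_1$, whose information sits in the short early frames.
* **Degeneracy and flags**: boundary-of-grid selections and negative
  fitted $BP_{ND}$ are flagged, never clamped — clamping would bias
  cohort means.  Rank-deficient design at every grid point is an error.

## The simulator and its calibration

The plasma input is a linear rise to a peak at 1 min followed by a
tri-exponential decay; the reference region follows one-tissue kinetics
($K_1^{ref} = 0.35$ mL·cm$^{-3}$·min$^{-1}$, $k_2' = 0.05$ min$^{-1}$).
Four binding conditions span the cohort range: $BP_{ND}$ = 0.05 (no
binding), 0.25 (low), 0.6 (medium), 1.2 (high), with baseline
$R_1 = 0.9$ and $k_2 = R_1 k_2'$.

The input-function tail is the one genuinely free setting, and it
controls how far from equilibrium the 80–100 min window sits — hence the
SUVr-vs-DVR offset.  It was calibrated once against the six observed
group × ROI baseline pairs (model SUVr at each cell's DVR and $R_1$
versus the cell's observed SUVr), giving amplitudes (800, 80, 30) kBq/mL
and decay constants (3, 0.08, 0.005) min$^{-1}$; the calibrated model
reproduces all six baseline SUVr means to about 0.005.  The calibration
was frozen before any longitudinal quantity was evaluated and not
revisited.

**Noise.** Frames receive independent Gaussian perturbations with
$SD_i = \mathrm{cov} \cdot C(t_i)\sqrt{\bar{\Delta t}/\Delta t_i}$ —
proportional noise inflated in short frames, emulating count statistics.
COV 5% represents realistic ROI noise, COV 0.05% near-noiseless curves.
Noise is applied to target and reference independently (symmetric
measurement error); noisy frames may go negative and are flagged, not
clipped.  Everything is reproducible from a seed.

**Frame schedule.** Continuous 0–130 min sampling (6×10 s, 2×30 s,
3×60 s, 2×150 s, then 5-min frames; 37 frames).  Dual-time-window
protocols with a mid-scan gap are deliberately not simulated.

## The synthetic cohort

`sample_cohort()` draws, per subject and ROI: baseline DVR from a normal
truncated at 1 (truth cannot have negative binding), a subject-level DVR
percentage change (guarded so follow-up DVR stays $\ge 1$), baseline
$R_1$ truncated at 0.3 with its own percentage change, and a scan
interval truncated at 0.5 y.  All truncations draw from the exact
truncated distribution by inverse-CDF sampling — equivalent to rejection
re-sampling but loop-free even when a subject's shared random effect
pushes the bound far into the tail.  Baseline DVRs across the three ROIs
share a subject random effect with intra-subject correlation 0.7
(configurable): Braak regions are biologically coupled, and pooled-ROI
agreement statistics are sensitive to this coupling, for which no
published value exists.

Two consequences of the truncation design are worth knowing.  First, in
low-binding groups the baseline mean sits close to the bound, so the
realized baseline-DVR mean exceeds the nominal normal mean — percentage
changes, the quantities of interest, are unaffected beyond a small
upward shift (well under half a percentage point; tested).  Second, at a
*null* change distribution the follow-up guard preferentially rejects
negative changes for subjects near the bound, so type-I-error
calibration of the pipeline's paired test is performed with the baseline
placed away from the bound.

`run_cohort_pipeline()` realizes every subject-visit as noisy TACs (one
shared reference per visit serving all three ROI fits), fits RPM,
computes SUVr, and aggregates per-subject percentage changes, group ×
ROI × parameter summaries with paired t tests, annualized changes, and
pooled-ROI Pearson and Bland–Altman agreement between DVR and SUVr
changes (differences taken quantitative-minus-semiquantitative).  Truth
records are carried unchanged next to the estimates.  A
`measure = "truth"` passthrough skips TAC realization for large-scale
statistical calibration.

What the generator does **not** emulate: off-target binding (a known
source of cortical signal variability for this tracer class),
partial-volume effects, scanner resolution, attrition, and the true
inter-ROI / baseline-change covariance structure — pooled-ROI correlation
magnitudes therefore depend on the chosen random-effect strength and are
demonstrations, not targets.  Passing tests show the pipeline recovers
the distributions it simulates; they cannot certify those features of
real data.

## Bias experiments

`run_bias_grid()` crosses binding conditions with flow deltas (default
$\{-0.3, \dots, +0.3\}$ in steps of 0.1), SUVr windows (default
40–60 through 110–130 min), noise levels and replicates, reporting the
mean and SD of $(\mathrm{SUVr}/DVR_{true} - 1)\times 100$ and
$(DVR_{fit}/DVR_{true} - 1)\times 100$ per cell.  The structural
behaviour under the calibrated kinetics: fitted DVR is flow-invariant
(sub-percent across the grid); SUVr bias decreases with increasing flow
at no/low binding and flattens at high binding; the bias depends on the
scan window, and its flow sensitivity shrinks as binding grows.

One boundary case deserves honesty: with the simulator calibrated to the
observed baseline SUVr offsets, the no-binding condition carries only a
~3.5% SUVr-vs-DVR offset at zero flow change, and a regional flow
*increase* of 20–30% drives its late-window SUVr slightly *below* true
DVR.  Universal late-window positivity of the bias and a ±30% regional
flow grid are not jointly satisfiable under these calibrated kinetics;
the package keeps the calibrated conditions and reports the sign change
rather than restricting the grid.

## Statistics layer

Percentage change is $(\mathrm{FU}/\mathrm{BL} - 1)\times 100$;
annualization divides by the per-subject interval in years.  Paired t
and Pearson delegate to base R (`t.test`, `cor.test`), with one
convention: identical vectors return $t = 0, p = 1$ rather than erroring
on zero variance.  All tests are two-sided at $\alpha = 0.05$; no
multiple-testing correction is applied (per-region raw p-values), though
users can adjust externally.  Bland–Altman reports mean difference and
$\pm 1.96\,SD$ limits of agreement.

Power and sample size for the paired t use the exact noncentral-t
distribution (`pt` with noncentrality $d_z\sqrt{n}$, $n-1$ df), scanning
$n$ upward from a normal-approximation start; effects are specified as a
mean and SD of percentage change, the natural units for "expected change
in tracer retention".  `sample_size_curve()` spans the conventional
0.5%–10% grid.  The tests cross-check against `power.t.test` and
brute-force scans, and validate the paired t against exhaustive
sign-flip permutation.

## Problem sizes and determinism

The shipped tests and the acceptance script size their simulations for a
single CPU: bias grids use 3–200 replicates per cell depending on the
noise level under test; cohort recovery averages 30 (tests) or 80
(script) cohort replicates of the relevant group × ROI cells; type-I
calibration uses 500 truth-level cohorts.  Every stochastic stage takes
an explicit seed, child seeds are drawn from a single parent stream, and
seeded helpers restore the caller's RNG state.

## Known limitations

* SRTM's one-tissue approximation is both the generative and the fitting
  model here; real-tissue violations (vascular fraction, two-tissue
  behaviour) are out of scope, so fit biases are lower bounds.
* Fitted $R_1$ carries a small noise-induced attenuation (errors in the
  noisy reference regressor) of order 1–3% per visit at COV 5%; it
  largely cancels in percentage change but leaves a fraction-of-a-point
  positive residual in group mean $R_1$ change.
* The SUVr-vs-DVR amplification along a subject's trajectory is a model
  property of transient equilibrium; calibrating baseline offsets does
  not pin it independently, so simulated SUVr changes run slightly above
  the DVR changes that generate them.
* ROI-level analysis only: no voxelwise parametric images, no
  plasma-input modelling, no partial-volume correction.
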