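# srtmsim

Reference-tissue kinetic modelling and flow-bias simulation for
longitudinal tau-PET quantification.

## The problem

Longitudinal tau-PET studies (e.g. ^18F-flortaucipir in subjective
cognitive decline and Alzheimer disease) can quantify tracer binding two
ways:

* **SUVr** — the target-to-reference activity ratio over a late static
  window (here 80–100 min): simple and practical, but sensitive to
  cerebral blood flow, because it is measured before true equilibrium.
* **DVR = BPND + 1** — the distribution volume ratio from kinetic
  modelling of the full dynamic scan: quantitative and flow-insensitive,
  but demanding to acquire.

Whether flow changes over time (disease progression, drug effects) bias
SUVr-based change estimates is a design question for observational studies
and trials.  This package provides the machinery to study it:

1. **Kinetic core** — the simplified reference tissue model (SRTM),

   `C_T(t) = R1·C_R(t) + (k2 − R1·k2a)·(C_R ⊗ e^(−k2a·t))(t)`,
   `k2a = k2/(1 + BPND)`,

   fitted by basis-function receptor parametric mapping (RPM): a
   log-spaced grid of `k2a` values, a 2-parameter weighted linear
   least-squares solve per grid point, WRSS minimization, and a continuous
   parabolic polish of `k2a`.  Yields `R1` (relative delivery, a proxy for
   relative cerebral blood flow), `k2`, `BPND`/`DVR`, plus `suvr()` on the
   same curves.
2. **TAC simulator** — plasma input (linear rise, tri-exponential decay),
   one-tissue reference region, forward-SRTM targets for named binding
   conditions, fractional flow perturbations that scale `R1` and `k2`
   jointly (leaving true DVR fixed), and proportional frame noise.
3. **Bias experiments** — percentage bias of SUVr and fitted DVR relative
   to true DVR over binding × flow × window × noise grids
   (`run_bias_grid()`, `window_sensitivity()`, `compare_noise_levels()`).
4. **Cohort synthesis** — a two-timepoint, two-group (n = 38 / n = 24),
   three-ROI (Braak I/II, III/IV, V/VI) synthetic cohort whose truth
   distributions are parameterized from published group statistics
   (`cohort_spec()`, `sample_cohort()`, `run_cohort_pipeline()`).
5. **Longitudinal statistics** — percentage change, annualization, paired
   t, Pearson, Bland–Altman agreement, and exact noncentral-t power and
   sample-size curves (`sample_size_paired()`, `sample_size_curve()`).

## Worked example

```r
library(srtmsim)

sch   <- default_schedule()                      # 0-130 min, 37 frames
cr    <- reference_tac(sch)                      # one-tissue reference TAC
truth <- srtm_params(R1 = 0.85, k2 = 0.0425, BPND = 0.6)
ct    <- add_noise(srtm_tac(truth, cr), cov = 0.05, seed = 42)

fit <- fit_srtm(ct, cr, weights = "ivar")
fit
#> SRTM fit (basis-function RPM)
#>   R1   = 0.8683
#>   k2   = 0.03978 min^-1
#>   BPND = 0.5976  (DVR = 1.598 )
#>   WRSS = 0.823  at k2a = 0.0249 min^-1 (grid point 20 of 64 )
suvr(ct, cr, c(80, 100))
#> [1] 1.7686
```

A 5%-noise scan of a region with true `DVR = 1.6` is recovered at
`DVR = 1.598` and `R1 = 0.868` (truth 0.85), while the 80–100 min SUVr of
the same curves reads 1.77 — the systematic late-window overestimation of
DVR that the bias experiments quantify.  Sample-size planning for a
longitudinal design:

```r
sample_size_paired(2.82, 2.54)   # expected %change (SD) of DVR
#> Paired-t sample size: n = 9 for 2.82 % expected change (SD 2.54 %,
#>   dz = 1.11 ), alpha = 0.05 , power >= 0.8 (achieved 0.83 )
```

The full cohort pipeline — sample truth, realize noisy TACs, fit RPM,
compute SUVr, aggregate longitudinal statistics — is one call:

```r
run <- run_cohort_pipeline(cohort_spec(), cov = 0.05, seed = 7)
run            # group x ROI x parameter %changes, paired tests,
               # pooled-ROI Pearson and Bland-Altman
```

## Layout

```
R/                  implementation (kinetic core, simulator, bias grids,
                    cohort synthesis, statistics, I/O)
inst/extdata/       packaged cohort distribution table (CSV)
tests/testthat/     unit, property and end-to-end acceptance tests
scripts/acceptance.R
vignettes/          methods vignette (model, calibration, design choices)
```
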