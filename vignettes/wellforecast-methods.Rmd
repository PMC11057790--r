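---
title: "Modelling and forecasting chemotherapy response in well plates: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and forecasting chemotherapy response in well plates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellforecast)
```

## The system and the data

`wellforecast` models in-vitro cancer cell colonies (the canonical system is
MCF7 breast cancer cells) grown in multi-well plates, treated once with
doxorubicin, and imaged by time-resolved microscopy every few hours for up
to six weeks. The observable is a *cell-density map*: cell centroids from
each image are binned into a square pixel grid (by default 15 × 15 pixels
of 430 µm over a 6450 µm field of view), giving one matrix of cell counts
per imaging time. A *well series* is the ordered stack of these maps with
the dose and the treatment time.

## The two-phenotype reaction-diffusion model

Before the drug is applied (at $t_{dox} = 48$ h after seeding), the
population is treated as homogeneous and grows exponentially while
spreading by Fickian diffusion:

$$\partial_t N_{tot} = \nabla\!\cdot\!(D_0 \nabla N_{tot}) + g_0 N_{tot},$$

with a spatially uniform proliferation rate $g_0$ (1/h) and diffusion
coefficient $D_0$ (mm²/h). The low pre-treatment density justifies the
exponential (rather than logistic) form.

At $t_{dox}$ the population is split pixelwise into a *surviving* fraction
$f_s$ and an *irreversibly damaged* fraction $1 - f_s$:
$N_s = f_s N_{tot}$, $N_d = (1-f_s) N_{tot}$, and $N_{tot} = N_s + N_d$
thereafter. The surviving cells follow logistic reaction-diffusion growth,

$$\partial_t N_s = \nabla\!\cdot\!(D_s \nabla N_s)
  + g_s(\bar{x})\, N_s \left(1 - \frac{N_{tot}}{\theta}\right),$$

while the damaged cells start out proliferating and progressively
transition into drug-induced death with delay rate $\gamma_d$:

$$\partial_t N_d = \nabla\!\cdot\!(D_d \nabla N_d)
  + \left[g_d + k_d e^{-\gamma_d (t - t_{dox})} - k_d\right]
  N_d \left(1 - \frac{N_{tot}}{\theta}\right).$$

The bracketed net rate starts at $g_d$ and decays towards $g_d - k_d < 0$:
continued drug uptake takes time to translate into cell death. Diffusion
is assumed phenotype-independent, $D_s = D_d = D_0$, so it is calibrated
once in the pre-treatment phase and frozen.

The surviving proliferation rate $g_s(\bar{x})$ is the only *local*
parameter (one value per pixel); everything else is *global* (one value
per well). This split is motivated by the variance-based sensitivity
screening below and is what lets the model express the clustered,
spatially heterogeneous relapse seen at intermediate doses without
overfitting hundreds of parameters.

One modelling note: the surviving-population reaction term is implemented
as $g_s N_s (1 - N_{tot}/\theta)$ — the standard logistic form with an
explicit $N_s$ factor — for dimensional consistency.

### Parameters, units and bounds

| parameter | meaning | unit | calibration range |
|---|---|---|---|
| $g_0$ | untreated proliferation rate | 1/h | [0.02, 0.035] |
| $D_0$ | diffusion coefficient | mm²/h | [0, 0.005] |
| $g_s$ | surviving proliferation rate (per pixel) | 1/h | [0.0001, 0.035] |
| $f_s$ | surviving fraction at $t_{dox}$ | — | [0, 1] |
| $k_d$ | drug-induced death rate | 1/h | [0.0001, 0.01] |
| $g_d$ | damaged proliferation rate | 1/h | [0.001, 0.05] |
| $\gamma_d$ | death-delay rate | 1/h | [1/120, 1/10] |
| $\theta$ | carrying capacity | cells | [88000, 90000] |

The carrying capacity is read as a *well-level* physical quantity (the
maximum cell count the well supports); the per-pixel logistic factor
uses $\theta / n_{pixels}$. A `theta_scope = "pixel"` switch in
[solver_config()] supports the per-pixel reading instead. $\theta$'s
calibration range is deliberately narrow: it is a property of the assay
geometry, not of the treatment.

## Numerical scheme

The PDEs are solved by finite differences on the pixel grid itself:
fully explicit forward-Euler time stepping with $\Delta t = 1$ h, a
5-point central-difference Laplacian, and no-flux boundaries implemented
by mirrored ghost nodes (so pure diffusion conserves the total count to
machine precision — the discrete Laplacian sums to zero exactly). The 2D
explicit stability condition $D \Delta t / \Delta x^2 \le 1/4$ is checked
on every step; with the largest admissible $D_0 = 0.005$ mm²/h and 0.43 mm
pixels the CFL number is ≈ 0.027, comfortably stable. Negative densities
produced by the explicit update are clipped to zero (counts are physical);
measurement times are snapped to the nearest internal step, never
interpolated. The forward solver is implemented in compiled code
(Rcpp) because calibration requires tens of thousands of forward runs;
the exported R step functions (`step_pretreatment()`,
`step_posttreatment()`) are the reference implementation and the test
suite checks the two paths against each other and against an independent
scalar recurrence.

## The synthetic-experiment generator

`generate_experiment()` emulates the canonical experiment: nine doses
(10–300 nM) × 6 replicates plus 6 untreated controls, 2000 cells seeded
per well, treatment at 48 h, imaging every 4 h, and dose-dependent
durations (277 h at 10 nM up to 963 h at 300 nM). Ground-truth parameters
are deterministic functions of dose chosen to reproduce the three observed
regimes:

* **low dose (≤ 35 nM)** — survival fraction near 1, spatially uniform
  $g_s$: homogeneous growth, negligible treatment effect;
* **medium dose (50–150 nM)** — intermediate $f_s$, low background $g_s$
  with 2–5 randomly placed Gaussian foci of high $g_s$ (peak
  0.018–0.026/h, ~1 pixel wide at the default grid): the well declines
  for roughly two weeks and then relapses in localized clusters, each
  replicate with its own cluster placement;
* **high dose (300 nM)** — survival fraction near zero, uniformly low
  $g_s$: homogeneous decay.

Both sigmoidal dose-response curves ($f_s$ falling, $k_d$ rising) share a
45 nM midpoint; damaged cells barely proliferate ($g_d = 0.0015$/h) and
transition to death with a one-day delay scale ($\gamma_d = 1/24$ h⁻¹),
keeping truths well inside the calibration bounds. Measurement noise is
additive Gaussian per pixel with standard deviation 5% of the pixel's own
count (floored at 1 cell), reflecting segmentation noise that scales with
local density; seeding is multinomial, so pre-treatment maps are
homogeneous in expectation. Each well draws from its own RNG stream keyed
by (master seed, dose, replicate).

What the generator does *not* emulate: raw fluorescence images and their
segmentation artifacts, stage-vibration correlated noise, single-cell
motility, or any mechanism *causing* the relapse foci (they are imposed on
the $g_s$ field, not emergent). Passing tests on synthetic data therefore
demonstrate the pipeline's correctness and internal consistency, not its
accuracy on real microscopy.

## Calibration

Calibration is two-phase, matching the experiment's structure:

1. **Pre-treatment:** $(g_0, D_0)$ are fitted jointly to all pixel
   courses before $t_{dox}$ by bounded least squares; $D_0$ is then
   frozen.
2. **Post-treatment:** the per-pixel $g_s$ field plus the five globals
   $(f_s, k_d, g_d, \gamma_d, \theta)$ are fitted to the total-count maps
   at every time after $t_{dox}$, starting the model from the measured
   map at the treatment time split by $f_s$. Only $N_{tot}$ enters the
   objective — the phenotype split is latent. Pixels with all-zero
   courses have $g_s$ pinned at the lower bound and are excluded from
   pixel-level scoring.

The optimizer is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
unit-scaled parameters (every parameter mapped to [0, 1] so the narrow
$\theta$ range and the wide rate ranges are treated evenhandedly), with
tolerances $10^{-8}$ and a 500-iteration cap. Two non-standard stages
bracket it, both motivated by the shape of this least-squares surface:

* **Stage A, a deterministic global screen.** The surface has a broad
  degenerate basin at $f_s = 1$ (attribute everything to surviving cells
  and tune $g_s$ down) which captures local optimizers started from
  midpoint guesses. The screen evaluates a fixed grid over
  $(f_s, k_d, \gamma_d, g_d)$; for each candidate the $g_s$ field is
  composed pixel-by-pixel from a ladder of uniform-$g_s$ forward runs
  (pixels decouple at this system's small diffusion coefficients), the
  best few candidates are refined by block-coordinate descent
  (globals-only LM alternating with multiplicative per-pixel $g_s$
  refinement), and the top two seed the joint fit. Ties are broken
  towards the largest $f_s$, so untreated wells — where the damaged
  compartment can mimic the surviving one exactly — calibrate to the
  parsimonious all-surviving solution.
* **A coordinate-profile polish.** The damaged-compartment parameters
  $(g_d, k_d, \gamma_d)$ ride a curved compensation ridge on which LM
  (and other box-constrained local methods) stall at false stationary
  points, often with a parameter pinned at a bound. The polish sweeps
  each global over a small bracket with *all other parameters re-fitted
  warm* — following the valley floor rather than cutting across it. On
  noiseless synthetic wells this recovers the generating parameters to
  machine precision. The polish is on by default for cold fits and off
  for warm restarts (bootstrap replicates, weekly assimilation refits),
  where locality is the point.

### Identifiability

The model is *sloppy* in the damaged direction: at realistic noise
levels the early-decay amplitude $(1 - f_s)\cdot\text{rate}$ and the
relapse anchor ($\ln f_s$ traded against $g_s t$ within its bounds) are
nearly exactly compensable, so $f_s$ and the damaged-rate parameters sit
on a flat likelihood valley. Profile evaluation on a representative
noisy medium-dose well shows the relative RSS varying by only ~$10^{-4}$
as $f_s$ moves across a ±60% range. Point recovery of those parameters
from a single noisy well is therefore poor *by the nature of the model*,
while $\theta$, the $g_s$ field and the fitted trajectories themselves
are robust. This is the same phenomenon visible in the bootstrap: the
spread (NSD) of $k_d$, $g_d$ and $\gamma_d$ is one to two orders of
magnitude larger than that of $g_s$, $f_s$ and $\theta$ — and it is a
large part of why the assimilation pipeline blends replicate-specific
estimates with a population prior instead of trusting either alone.

### Residual bootstrap

`bootstrap_calibration()` estimates a single pooled residual standard
deviation, adds fresh Gaussian noise to the *fitted* curves, refits
(warm-started, capped iterations), and summarizes each parameter's
bootstrap distribution by mean, interquartile range and NSD (sd/mean);
the local field is tracked through its spatial mean and the full
per-pixel samples. 100 samples is the canonical setting; the test suite
uses 25 for speed.

## Sensitivity screening

`total_effect_indices()` computes Sobol total-effect indices with the
Jansen estimator on a Saltelli-style design (matrices A, B and the six
hybrids $AB_i$; $n_{base} = 625$ gives the canonical 5000-evaluation
budget). The scalar output is the terminal total cell count of a well
run with all parameters spatially uniform — uniform fields make
diffusion a no-op, so each evaluation collapses to a scalar recurrence
and the whole design vectorizes through one time loop. The estimator is
validated in the tests against a closed-form additive-variance oracle.

For the screening, $\theta$ is sampled over a wide range
([10000, 90000]); this reproduces the finding that $g_s$ and $\theta$
dominate the output variance, which motivated calibrating $g_s$ locally
and — since $\theta$ is physically constrained by the assay — restricting
$\theta$ to its narrow range rather than calibrating it locally too.
With $\theta$ restricted to [88000, 90000] its total effect collapses
towards zero, consistent with that restriction being harmless.

## The assimilation-prediction pipeline

`run_pipeline()` implements the leave-one-out weekly scheme for one dose
group of six replicates:

1. The five training replicates are fully calibrated; their parameter
   grids ($g_s$ local, globals broadcast) are averaged pixelwise into the
   population prior $P_{training}$, which forecasts the held-out
   replicate's first post-treatment week from its measured map at
   $t_{dox}$.
2. Each later week $w$: the test replicate is recalibrated on
   $(t_{dox}, t_w]$ (warm-started at the previous week's fit), giving
   $P_{measure}$; every training pixel's course over the same window is
   ranked against each test pixel's course by Lin's concordance
   correlation coefficient; the top 25% (ceiling — 282 of the 1125
   training pixels at full scale) are averaged with CCC-proportional
   weights into $P_{training,p}$; the two grids are blended,
   $P_{prediction} = \omega P_{training} + (1-\omega) P_{measure}$, with
   the quadratic schedule $\omega(\hat t) = 0.6\hat t^2 - 1.2\hat t + 1$
   evaluated at the segment's start time normalized by the 963 h
   reference horizon; the measured boundary map is run forward one week.
   In this prediction stage all six parameters vary pixelwise, and the
   death-delay clock stays anchored at $t_{dox}$ across restarts.

   How to split the measured boundary map into surviving and damaged
   compartments deserves a note. $f_s$ is defined as the split *at the
   treatment time*; by a later boundary the damaged share has decayed
   well below $1 - f_s$, so re-splitting the map by $f_s$ literally
   would hand the forecast a state inconsistent with the dynamics (in
   self-consistency experiments it destroys otherwise exact forecasts).
   The pipeline therefore takes the *phenotype ratio* from the weekly
   calibration's own model state at the boundary and the *amplitude*
   from the measurement: $N_s = r_s(x)\,M$, $N_d = (1-r_s)\,M$, where
   $r_s$ is the calibrated run's per-pixel surviving share and $M$ the
   measured map. `predict_week()` exposes this through its
   `split_ratio` argument; without it the grid's $f_s$ field performs
   the split, which is exactly right at $t_{dox}$.
3. With bootstrap distributions available, forecast bands are built by
   drawing one bootstrap parameter set per training replicate (combined
   with the point-estimate similarity weights), pairing it with a draw
   from the weekly calibration's bootstrap, blending through the same
   $\omega$, simulating, and taking the per-pixel mean and 25th–75th
   percentile across draws (1000 canonically).

Design choices where the procedure was genuinely open, all isolated
behind arguments: $\hat t$ is evaluated at the start of each predicted
segment and held constant within it; week boundaries sit at
$t_{dox} + 168k$ h with a final partial week; ranking ties break stably
by training-pixel order (replicate, then row, then column); if a test
pixel's course has zero variance, or the selected CCCs sum to a
non-positive value, the ranking falls back to uniform weights; weekly
recalibration always refits from $t_{dox}$ to the current boundary;
the blended $f_s$ (not the measured-only or prior-only one) performs the
weekly re-split; similarity uses raw counts, not normalized courses.

## Concordance metrics

`ccc()` is Lin's concordance correlation coefficient with population
(1/n) moments — $2\,\mathrm{cov}(x,y) / (\sigma_x^2 + \sigma_y^2 +
(\bar x - \bar y)^2)$ — symmetric, bounded by the Pearson correlation in
absolute value. `ccc_well()` applies it to grid-summed total counts;
`ccc_pixel()` averages per-pixel CCCs, excluding pixels where both
courses are constant (the exclusion count is always reported, and
excluded-plus-included equals the grid size).

## Problem sizes and test design

The full 15 × 15 grid is the analysis default. The test suite and the
acceptance script run calibrations on a coarse 5 × 5 grid over the same
field of view (and 4 × 4 for some pipeline checks) with shortened
time courses — these keep a laptop-scale run while preserving the
physics, since the solver, objective and pipeline are
resolution-agnostic. Monte-Carlo settings are likewise scaled: 25
bootstrap samples and 4–8 band draws in tests versus the canonical
100/1000.

## Known limitations

* Forward Euler is first-order; halving $\Delta t$ roughly halves the
  terminal-count error. The default $\Delta t = 1$ h is part of the
  method's definition here, not a converged limit.
* Single dose only: no re-treatment, no phenotype switching back.
* The damaged-compartment parameters are practically unidentifiable from
  a single noisy well (see *Identifiability*); treat their point
  estimates as trajectory descriptors, not biology, and read the
  bootstrap NSDs before interpreting any of them.
* The generator's dose-response curves are plausible emulations, not
  fits to real dose-response data.
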