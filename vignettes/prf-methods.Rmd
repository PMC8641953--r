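---
title: "Population receptive field modeling across recording modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population receptive field modeling across recording modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, numerical choices, and design decisions
behind `prfmap`, and what the package's synthetic-data validation does and
does not establish about real recordings.

## The forward model

A population receptive field (pRF) summarizes the region of visual space
that drives the aggregate response of the neural population sampled by one
fMRI voxel or one electrode. The forward model multiplies a binary
"effective stimulus" movie `S(x, y)` — which pixels the mapping bar occupies
in each frame — with a Gaussian pRF profile, sums over space, and applies a
static nonlinearity:

    Resp_pred = g * [ sum_xy S(x, y) * G(x, y) ] ^ n,
    G(x, y)   = exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2)).

The Gaussian is deliberately unit-peak (unnormalized); the gain `g` absorbs
all scaling, so `sigma` and `n` are interpretable independently of the
response units. The pixel sum is divided by `pixels_per_dva^2`, which makes
predictions — and therefore fitted gains — independent of the rendering
resolution; refitting after re-rendering at a different resolution changes
nothing but discretization error.

Four model variants share this core:

* **P-LIN** — linear summation (`n = 1`), gain constrained positive.
* **U-LIN** — linear, gain free; negative gains model stimulus-driven
  suppression ("negative pRFs").
* **DoG** — an excitatory center minus a broader suppressive surround,
  `G1 - a * G2` with `sigma2 > sigma1`, `a >= 0`, linear summation. We keep
  the exponent fixed at 1 for DoG; the compressive exponent is treated as
  the distinguishing feature of the CSS model, consistent with the model
  lineage. The "normalized suppressive amplitude" reported in summaries is
  the surround/center volume ratio `a * (sigma2 / sigma1)^2`, chosen so that
  values above 1 mean net suppression; no standard formula exists for this
  quantity, so ours is stated here.
* **CSS** — compressive spatial summation, `0 < n` free. `n < 1` makes
  responses subadditive: two bars together drive less than the sum of each
  alone.

Because `sigma` and `n` interact, the pRF **size** reported everywhere is
`sigma / sqrt(n)`: the SD of the predicted response profile to a point
stimulus. For `n = 1` this is `sigma`; for the DoG the center SD `sigma1`
is the size and `sigma2` is reported separately.

## Stimuli

`make_protocol()` encodes two presets. The fMRI variant sweeps a 2-dva bar
across a 16-dva circular aperture in 20 steps of one TR (2.5 s; 50 s per
sweep) in eight directions (order 270, 315, 180, 225, 90, 135, 0, 45
degrees), with 37.5 s of uniform background before and after the sweep
series and 25 s after every horizontal or vertical sweep. The
electrophysiology variant covers 28 dva in 30 steps of 500 ms with 2.5 s
blanks. Effective stimuli are rendered at 10 px/dva by default.

Coordinates: x rightward, y upward, fixation at the origin; pixel centers
sit at half-integer offsets so the grid is symmetric about fixation, which
makes opposite sweep directions exact mirror sequences (tested bit-exactly).
Bar centers span the aperture diameter with first/last centers flush with
the rim — the paper-style "bar behind a virtual aperture" convention; the
alternative (first bar fully inside) is not used, and this choice is the
one genuinely open rendering decision. Only the binary aperture is rendered;
the checkerboard carrier inside the bar is irrelevant to the fitting method.

## Hemodynamics

BOLD predictions are convolved with an HRF at half-TR resolution and then
averaged to TR samples. Kernels are double-gamma shapes whose two free
timing properties are solved by 1-D root finding: the positive lobe's mode
is pinned at the time-to-peak, and its width is adjusted until the kernel
first returns to within 5% of baseline exactly peak-to-fall seconds after
the peak. Targets: monkey 4.2 s / 6.2 s, human 4.8 s / 12.6 s. "Fall" has no
standard operationalization, so the 5%-of-baseline criterion is configurable
(`fall_frac`); the undershoot is fixed at 10% of peak, a conventional value,
peaking 2 s after the fall point. The monkey kernel's FWHM (5.2 s) is
strictly below the human's (9.3 s), the "narrower" property that matters
for fit quality.

## Fitting

Fitting is two-stage per data half:

1. **Coarse grid.** Centers on an 8 x 8 lattice spanning 1.5 x the aperture
   radius (pRF centers may lie outside the stimulated field), six log-spaced
   sigmas from 0.1 dva to the aperture diameter, and for CSS a small
   exponent set. At every grid point the gain — and for DoG the surround
   amplitude — is profiled out in closed form by least squares, so the grid
   scan only scores shapes. Grid predictions depend on the stimulus alone
   and are cached and shared across units and folds.
2. **Refinement.** The top seeds start a bounded quasi-Newton (L-BFGS-B)
   search over the nonlinear parameters (center, log sigma, exponent or
   log surround increment) with the linear parameters still profiled.
   Bounds: sigma in [0.05, 2 x aperture], n in [0.05, 1.5], |x0|, |y0| <=
   1.5 x aperture radius, DoG a in [0, 3], sigma2 in (sigma1, 4 x aperture].

Cross-validation splits by odd/even repeats: each fold's best solution is
scored on the complementary half (R² about the held-out mean, so a flat
prediction scores 0 and values may be negative), and the two fold R² values
are averaged — the model-selection statistic. Final parameters come from a
refinement on the mean of the two halves seeded from the better fold.
Everything is deterministic given the data, so refits are bit-reproducible.

Model comparison applies the field's convention: an R² inclusion threshold
(5% for BOLD, 25% or 50% for electrophysiology — configurable), a
Kruskal–Wallis test across models, Tukey-HSD-style comparisons of pooled
mean ranks, and pairwise Wilcoxon signed-rank tests.

## Electrophysiology preprocessing

The MUA envelope is band-pass 500 Hz–9 kHz, full-wave rectification,
200 Hz low-pass, resampled to 1 kHz. LFP band power uses a multitaper
spectrogram: 500 ms windows, 50 ms steps, time–bandwidth product 5, 9
Slepian tapers, averaged in five bands — theta 4–8, alpha 8–16, beta 16–30,
low gamma 30–60, high gamma 60–120 Hz. The Slepian tapers are computed from
the standard symmetric tridiagonal eigenproblem (verified orthonormal and
against an independent implementation to ~1e-15). Responses are the mean
over 50–500 ms after each bar-position onset minus a 1000 ms pre-sweep
baseline, averaged over repeats. The printed cutoffs come with no filter
family attached, so all filters are zero-phase forward–backward 4th-order
Butterworth — zero-phase so that cRF timing is not distorted; the baseline
is per sweep (per run would also be defensible; the window is an argument).

The conventional RF estimator (`estimate_crf`) requires opposite horizontal
and vertical sweep pairs. Units must exceed SNR 3 (peak response over the
SD of spontaneous activity, estimated from inter-sweep blanks) and a 25%
Gaussian-fit R² floor. The Gaussian (plus offset) is fitted to each
direction's averaged trace by Levenberg–Marquardt least squares; onset and
offset are mean ± SD, mapped through the bar trajectory, and opposite-sweep
borders are averaged, which cancels response latency exactly for a constant
latency (tested with a 60 ms shift). Size is the half-diagonal
`sqrt(width² + height²)/2` — note this equals `sqrt(2) * sigma` for a
circular Gaussian RF, as the width and height spans are each 2 SD — and the
conventional diameter is `3.3 * SD`.

## Population statistics

`ecc_size_relation()` regresses size on eccentricity per unit (unbinned)
and reports 2-dva half-open binned means ± SEM for display.
`compare_slopes()` fits `size ~ ecc * signal` and F-tests the interaction,
with reference-vs-signal pairwise contrasts. The original analysis used
linear mixed models; the random-effects structure is not recoverable from
the published description, so the default here is the fixed-effects linear
model, with a `fitter` hook accepting any `anova`-compatible replacement
(e.g. `lme4::lmer` wrappers). The separation index between two pRFs is
center distance over summed sizes (< 1 means overlap); it is symmetric and
scale-invariant. Negative pRFs are classified by the sign of the U-LIN gain;
sizes default to CSS-model estimates in cross-signal summaries.

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of parameters and a seed. `sample_population`
mimics implant coverage of the lower-right visual quadrant: eccentricity
limits 8 dva (V1) and 14 dva (V4), eccentricity–size slopes 0.1 and 0.3
dva/dva with intercept 0.5 dva and lognormal jitter, exponents
truncated-normal with mean 0.35 in (0, 1], positive gains (an optional
fraction negative). The DoG variant uses a surround 2.5 x the center SD with
amplitude 0.18 (normalized suppressive amplitude 1.125, in the empirically
reported range). Noise is additive Gaussian on BOLD samples and position
responses — real measurement noise is neither white nor Gaussian
(physiological drift, burst firing, line noise), so passing recovery here
validates the estimator's correctness, not its robustness to structured
artifacts. Raw LFP synthesis modulates the power of a band-limited Gaussian
carrier by the unit's normalized pRF drive; it contains no 1/f background,
phase-amplitude structure, or cross-band leakage.

## Validation conditions and known limitations

The recovery study runs at desk scale: a 16-dva aperture with 2-dva bar,
32 steps of 0.5 s in all eight directions, rendered at 2 px/dva; 100 units
per model with eccentricity at most 4 dva, so every RF (center + 3 SD) is
fully covered by the aperture — mirroring the role of the larger
electrophysiology display in the original setup; 8 repeats with noise at
1.3 x each unit's noise-free response SD, which lands the per-fold training
R² near 70%, the middle of the intended 60–80% regime.

Under these conditions the linear and DoG models recover centers to well
under 0.1 dva median error and sigma to ~5% median relative error, and
noise-free fits are essentially exact for all models. The CSS model behaves
differently, and deliberately so is documented: at realistic noise the bar
protocol leaves a ridge in the (sigma, n) likelihood — many
(sigma, n) pairs with similar `sigma / sqrt(n)` predict nearly identical
bar responses. The fitter demonstrably reaches the global optimum (its
residual is below the one at the generating parameters), yet the ML estimate
drifts along the ridge: pRF *size* is recovered to ~5–6% median error while
sigma alone can err by ~20–25% and the exponent by ~0.1. This is a property
of the measurement design, not of the optimizer; per-unit exponent scatter
of similar magnitude is visible in empirical CSS fits. Conclusions about
CSS pRFs should therefore be drawn on size, not on sigma or n separately —
the same practice the pRF literature follows.

Other limitations worth knowing: the DoG surround amplitude is weakly
identified when sigma2 is much larger than the stimulated field; fits with
the gain clamped at zero (P-LIN/CSS on anti-correlated data) signal an
unfittable unit rather than a negative pRF — use U-LIN for those; and the
fixed-effects slope comparison understates uncertainty if strong per-array
or per-subject structure exists, which is what the mixed-model hook is for.

## Problem sizes

Unit tests run on reduced geometries (4–10 bar steps, 1–5 px/dva) where
brute-force oracles are exact and fast; the acceptance suite uses the
conditions above (100 units per model; 60 in the standalone acceptance
script) so the whole validation completes in minutes on one CPU.
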