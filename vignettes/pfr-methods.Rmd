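---
title: "Measuring the left-ventricular peak filling rate: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the left-ventricular peak filling rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfrkit)
```

## The measurement problem

The peak filling rate (PFR, mL/s) is the maximum rate of left-ventricular
volume increase during early diastole and serves as an index of diastolic
function. Two cine-MR routes lead to it. The volumetric route segments the
LV cavity on a short-axis SSFP stack at several phases around peak filling,
differentiates the time–volume curve, and smooths the noisy derivative with
a fitted parabola. The flow route measures trans-mitral inflow directly with
phase-contrast (PC) velocity mapping on a single slice at the valve orifice.
Both are limited by *true temporal resolution* — the data-acquisition window
per reconstructed phase, TR × VPS × 2 for PC and TR × VPS for SSFP — which
behaves like a moving average applied to the filling-rate signal: the E-wave
peak lasts only ~200 ms, so a 40–100 ms window clips it. Retrospective
gating can reconstruct phases on an arbitrarily fine grid (the *apparent*
resolution, RR/N), but interpolated phases cannot restore what the
acquisition window averaged away. `pfrkit` implements both estimation
pathways, the timing calculators, the method-comparison statistics, and a
phantom with analytically known PFR to quantify each pathway's deficit.

## The phantom's volume waveform

`make_volume_waveform()` builds a periodic V(t): a half-cosine ejection from
EDV to ESV over systole, flat diastasis segments, and two raised-cosine
filling-*rate* lobes — the early E wave (asymmetric about its peak) and the
atrial A wave. Lobe amplitudes follow from conservation: E and A volumes
together equal the stroke volume, split by the E:A volume ratio, and a
raised-cosine lobe of width w and peak P carries volume P·w/2. Hence the
true PFR is available in closed form, `2000 · Vol_E / w_E` mL/s, which is
what makes the phantom usable as an oracle; `true_pfr()` re-derives it by
dense grid search plus local refinement so the oracle does not assume the
waveform family.

Defaults were chosen once to represent a healthy adult volunteer cohort:
heart rate 62 beats/min, EDV 150 mL, ESV 65 mL; ejection ending at 0.38 RR;
E wave from 0.40 to 0.625 RR peaking at 0.49 RR; A wave from 0.78 to
0.98 RR; E:A volume ratio 1.5. These give a true PFR of 468.4 mL/s and a
peak filling time of 474 ms — both in the range reported for such cohorts —
and an E:A *peak-velocity* ratio of about 1.3. The mitral orifice is 4 cm²,
so the peak inflow velocity (~113 cm/s after blurring) stays below the
VENC of 150 cm/s; aliasing therefore never occurs at the defaults, though a
wrap mode exists for studying it deliberately.

## What the acquisition model does and does not emulate

Rendering is idealised retrospective gating: phase j is reconstructed at
time (j−1)·RR/N exactly, and the entire effect of finite true temporal
resolution is modelled as a centred boxcar average (`temporal_blur()`,
composite-Simpson quadrature with 512 subintervals) of the velocity or
volume signal. The PC series paints the blurred inflow velocity uniformly
over a disc ROI whose pixel count matches the orifice area (chosen as the N
grid pixels nearest the centre, so pixel-count area and nominal area agree
to a fraction of a percent); per-pixel Gaussian velocity noise (default SD
2 cm/s) is added and values are stored as signed integers with full scale
4096 ↔ VENC — scanners scale stored phase differently, and 4096 is simply a
12-bit convention. The SSFP stack slices a prolate spheroid whose short
axis is solved per phase so the sliced-disc volume sum equals the (blurred)
phase volume *exactly* in exact-area mode; raster mode fills pixel masks and
carries ordinary rasterisation error (~1–2 % at 1 mm pixels).

Not emulated: k-space acquisition, coil sensitivities, SSFP banding, beat-to-
beat RR variability, respiratory motion, papillary muscles, and the long-axis
landmark geometry that clinical software uses to split the basal slice
between ventricle and atrium. The last is exposed instead as an optional
`basal_fraction` scalar on `stack_volume()`. Passing tests on this phantom
therefore shows that the *estimation chain* is correct and that temporal
blurring alone reproduces the characteristic peak underestimation; it does
not validate segmentation quality or flow-profile effects in real data
(the spatial velocity profile is uniform by default precisely so that
ROI-mean × area is exact; a parabolic profile would bias a too-small ROI).

## The two pathways

**PC.** `decode_velocity()` maps stored phase to cm/s; `roi_flow()`
implements Q = area × |mean velocity| (the absolute value makes the result
independent of velocity-axis orientation); `find_visual_peak()` automates
the operator's choice as the flow argmax over an early-filling index window
(earliest phase on ties); `pfr_from_three_phases()` evaluates the phases
k−1, k, k+1 and takes the maximum, breaking ties toward the centre phase.
Boundary indices are refused rather than wrapped: early filling never abuts
the cycle boundary physiologically, so wraparound would only ever mask an
upstream error.

**SSFP.** `phase_window_from_pc_peak()` encodes the odd/even
correspondence rule between 64 PC phases and 32 SSFP phases (odd PC phase
2n−1 → five SSFP phases n−2…n+2; even 2n → six phases n−2…n+3). A window
that would cross the first or last SSFP phase is an error — clamping would
shorten one side of the fit window and bias the vertex. `derivative_curve()`
plots ΔV/Δt at interval midpoints; `fit_parabola()` solves the quadratic
least-squares problem with times centred at their mean (mathematically
identical to the raw fit, numerically far better conditioned) and reports
the vertex only for a concave fit; curvature ≥ 0, or curvature so small
that it moves the fitted curve by less than ~1e−9 of the rate scale across
the window, raises a "no concave peak" error rather than returning a
meaningless vertex.

On the default noise-free phantom the chain recovers: temporal PC (43.2 ms
blur) −3.6 %, SSFP (40 ms blur + finite differencing + parabola) −5.1 %,
spatial PC (100.8 ms) −15.9 % relative to truth. The deficit is monotone in
blur width within each pathway; the package deliberately does not assert an
ordering *between* the SSFP and temporal-PC estimates, which sit within a
few percent of each other and can swap under noise.

## Statistics

`bland_altman()` uses the sample SD (n−1) and limits of agreement at
exactly bias ± 1.96 SD; confidence intervals use the large-sample standard
errors SE(bias) = SD/√n and SE(limit) = SD·√(3/n) with the t(n−1) quantile,
which is the convention that reproduces published small-cohort intervals.
A summary mode (`bland_altman_summary()`) reconstructs limits from a
reported bias and SD when per-subject data are unavailable. `pearson_ci()`
uses the Fisher z transform with SE 1/√(n−3) and a normal quantile.
`icc()` computes single-measure ICC from the two-way mean-square
decomposition; ICC(2,1) (absolute agreement) is the default because
method/observer comparisons care about agreement, with ICC(3,1)
(consistency) exposed and labelled. `one_way_anova()` delegates to the
classical equal-variance F test and refuses the degenerate
zero-within-variance case. Degenerate regression inputs follow documented
conventions: constant y gives slope 0 and r 0; constant x is an error.

## Numerical and design notes

* All user-facing phase indices are 1-based; conversion happens only at
  boundaries.
* Units are fixed throughout: ms, mL, mL/s, cm/s, mm, cm², m². BSA uses the
  Du Bois formula 0.007184·H^0.725·W^0.425 (H cm, W kg), which matches
  published BSA-indexed volumes to ~1 %.
* Rendering is seeded (`phantom_spec(seed = )`) and restores the caller's
  RNG state; identical spec + seed gives bit-identical series.
* Problem sizes: the default phantom uses a 96×96 matrix, 64 PC / 32 SSFP
  phases and 10 slices — small enough that the full pipeline, the test
  suite and the acceptance script each run in seconds while preserving the
  sub-quantisation-step round-trip behaviour the tests assert.
* Known limitations: no LV mass (epicardial contours are out of scope), no
  valve tracking, no automated orifice or endocardial segmentation (masks
  and ROIs are inputs), and peak-filling-*time* means of a real cohort are
  not reproducible from summary statistics alone.
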