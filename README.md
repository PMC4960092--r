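# pfrkit

Estimation of the left-ventricular **peak filling rate (PFR)** — the maximum
rate of LV volume increase during early diastole, in mL/s — from cine
cardiovascular MR, and the statistics needed to compare the two clinical ways
of measuring it:

- the **phase-contrast (PC) pathway**: through-plane velocity mapping at the
  mitral valve orifice, where pixel phase is proportional to velocity
  (full scale = VENC). The mitral flow at a phase is
  `Q = A · |v̄|` (ROI area in cm² times absolute mean velocity in cm/s, giving
  mL/s), and PFR is the maximum flow over the three consecutive phases
  centred on the visually determined peak filling phase;
- the **SSFP volumetric pathway**: short-axis slice-stack volumetry
  (`V = Σ A_s · Δz`) at the five or six phases centred on the PC peak (odd PC
  phase 2n−1 → SSFP phases n−2…n+2; even phase 2n → n−2…n+3), the
  first-derivative curve `ΔV/Δt` plotted at interval midpoints, and a
  least-squares parabola whose vertex gives PFR and the peak filling time.

Because finite *true* temporal resolution (TR × VPS × 2 for PC, TR × VPS for
SSFP) averages the rapidly changing filling rate over each acquisition
window, both pathways underestimate the instantaneous peak; the package ships
a **synthetic cine phantom** whose filling waveform has a closed-form peak, so
the size and ordering of that underestimation can be measured against known
truth. Method agreement is quantified by least-squares regression, Pearson r
with Fisher-z confidence intervals, Bland–Altman limits of agreement
(bias ± 1.96 SD), ICC(2,1)/ICC(3,1), and one-way ANOVA.

## Worked example

```r
library(pfrkit)
spec <- phantom_spec()            # EDV 150 mL, ESV 65 mL, 62 bpm, seed 1
report <- run_pipeline(spec)
report$truth$pfr                  # 468.4 mL/s  (closed-form ground truth)
report$results$ssfp$pfr           # 444.8 mL/s  (40 ms blur, parabolic fit)
report$results$temporal_pc$pfr    # 451.7 mL/s  (43.2 ms blur)
report$results$spatial_pc$pfr     # 393.9 mL/s  (100.8 ms blur)
```

The temporal-PC estimate sits ~3.6 % below truth and the spatial-PC estimate
~15.9 % below: lower true temporal resolution deepens the deficit, while the
finer *apparent* resolution (RR/64 for both PC series) cannot compensate.

The `analysis/` drivers run the full study in order:

```sh
Rscript analysis/01_simulate_phantom.R    # phantom + image bundles
Rscript analysis/02_pc_pfr.R              # PC flow curves and three-phase PFR
Rscript analysis/03_ssfp_pfr.R            # SSFP window, parabola, EDV/ESV/EF
Rscript analysis/04_method_comparison.R   # published arithmetic + mini-cohort
```

writing their tables and reports under `results/` (images under `scratch/`).

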