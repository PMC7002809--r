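---
title: "Kinetic and textural DCE-MRI response analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic and textural DCE-MRI response analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sisdce)
```

## The problem

In breast-cancer neoadjuvant therapy, a pathological complete response
(pCR; Miller-Payne grade 5 at surgery) predicts long-term benefit, but it
is only known after months of treatment. DCE-MRI acquired before
treatment and again after the first cycle can reveal response much
earlier: responding tumours lose contrast uptake, flatten their washout,
become more spatially homogeneous, and begin to shrink. `sisdce`
quantifies these changes per patient and asks, for each derived measure,
how well its pre-to-post percentage change separates pCR from non-pCR
patients.

## The piecewise-linear TIC model

A voxel's time-intensity curve `s(t)` is modelled as three linear
regions: a constant baseline until contrast arrival at `t_onset`, a
linear washin up to the peak at `t_peak`, and a linear washout
afterwards. The fit is an exhaustive search over all breakpoint pairs
`(i, j)` on the acquired time grid with at least two samples per segment
(so curves need at least six frames). Segment 1 is fitted as its mean,
segments 2 and 3 as unconstrained ordinary-least-squares lines; the pair
minimising the total SSE wins. Three choices deserve comment:

* **No continuity constraint.** Each segment is fitted independently.
  This keeps the per-candidate fit linear and closed-form; on noiseless
  in-model curves the unconstrained fit is exact anyway (the tests pin
  this to machine precision), and on noisy curves the discontinuities at
  the breakpoints are of the order of the noise.
* **Deterministic tie-breaking.** Among equal-SSE pairs the smallest
  `(t_onset, t_peak)` wins (strict-improvement updates during the scan in
  ascending order), so constant curves yield a stable degenerate fit:
  baseline at the mean, zero slopes, MSD 0, flagged `degenerate`.
* **Breakpoint samples belong to both adjacent segments**, matching the
  physiology (the onset sample is both the last baseline and the first
  washin point).

Derived parameters: MSD is the *fitted* washin value at `t_peak` minus
the baseline level, floored at zero — using the fitted rather than the
raw peak makes the measure robust to single-frame spikes. TTP is
`t_peak`; WIS/WOS and the intercepts come from the fitted lines. The
areas under the curve integrate the *observed* signal minus the fitted
baseline with the trapezoidal rule on the acquired grid over
`[t_onset, t_peak]`, `[t_peak, t_end]` and their union, which makes
`auc_total = auc_washin + auc_washout` an exact identity. At the typical
16–20 s frame spacing the trapezoid rule is the natural quadrature.

Per-patient values are the voxelwise **medians** over the VOI (SD and
max-minus-min range reported alongside). Fitting one average curve per
VOI instead is possible with the same functions (`fit_piecewise` on a
mean TIC) but is not the default: medians of per-voxel fits are robust
to intratumoural heterogeneity, which is exactly what the texture panel
shows these tumours have.

## The Standardised Index of Shape

For any representative value, the pre-to-post change is
`Δ = (v₁ − v₂)/v₁ × 100`, so a post-treatment *decrease* gives a
*positive* change. The SIS is the fixed linear combination
`0.7780·ΔMSD + 0.6157·ΔWOS`. The weights originate from earlier work on
rectal cancer and are treated here as constants (configurable in
`compute_sis`, defaulted exactly as printed). ΔWOS is applied to the
signed slope — no absolute value — so a washout that flattens from
−0.2 to −0.12 a.u./s gives ΔWOS = +40%. Denominators within `1e-9` of
zero make the change undefined; undefined values are flagged, excluded
feature-wise from cohort statistics, and counted in the run report
rather than silently dropped.

## The texture panel

Texture is computed on the arterial-phase frame restricted to the VOI.
Because dynamic series do not label an "arterial" frame, the package
defines it as the first frame whose VOI-mean enhancement over the
baseline (mean of the first two frames) reaches 50% of the maximum — an
early post-contrast frame by construction; a flat series falls back to
the last frame with a warning.

The VOI is quantised to `n_levels = 32` equal-width bins between its own
minimum and maximum (the most common radiomics default; configurable).
All matrix families are 3-D with direction pooling: GLCM and GLRLM
accumulate over the 13 unique grid directions at distance 1 before
normalisation, GLSZM zones and NGTDM neighbourhoods use 26-connectivity.
The panel is frozen at 50 names (`texture_panel_names()`): 9 first-order
+ 9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM + VOI volume. "Entropy" means
GLCM entropy (bits, `0·log 0 = 0`); a first-order histogram entropy is
available as an auxiliary `hist_entropy` output for users who prefer
that reading. Run percentage is normalised by `13 × N` so it stays in
(0, 1] for the pooled matrix. Degenerate cases carry explicit flags: a
single-level VOI has entropy 0, one run per direction per voxel line,
busyness 0 (flagged — its denominator vanishes), and undefined
skewness/kurtosis/correlation are `NA`-flagged and excluded from group
statistics.

Every matrix family is validated against literal-definition brute-force
enumerators (explicit loops over voxels, neighbours, runs and flood
fills) on dozens of random small volumes, to `1e-10`.

## Group comparison and diagnostics

Percentage changes are compared with the two-group Kruskal-Wallis test
(`stats::kruskal.test`: tie-corrected H, chi-square p with 1 df) — note
that at very small samples (n ≤ 8) the chi-square p can differ from the
exact permutation p by up to ≈ 0.2; the test suite compares the H
statistic exactly and bounds that gap. Bonferroni significance uses
`p < α/m` with `m` the number of features actually tested in the run
(logged in the report).

ROC-AUC is the tie-corrected Mann-Whitney probability with the
orientation fixed a priori: higher change ⇒ pCR, the direction of every
significant feature's group medians. The operating point maximises the
Youden index `J = sensitivity + specificity − 1` over *observed* score
values with the rule "positive if score ≥ cutoff" (printed cutoffs in
clinical tables look like observed values, and observed-value candidates
make reports reproducible); ties on J break towards higher specificity,
then the smaller cutoff. Printed table columns round half away from
zero, the convention of clinical tables (R's `round()` would turn
10/16 = 0.625 into 0.62 rather than the printed 0.63); machine outputs
keep full precision.

## The synthetic cohort generator

The generator emulates the structure of public breast DCE-MRI
therapy-response collections: 25 frames at 16 s (configurable within
10–30 s), two-plus baseline frames before onset (default onset 48 s,
peaks on the grid at frames 7–10), an ellipsoidal VOI (semi-axes
6.5 × 6.5 × 4.5 voxels in a 24 × 24 × 12 grid, ≈ 770 voxels), additive
i.i.d. Gaussian noise (default SD 2 a.u. against a baseline of 100 and
median MSD of 150 — high but realistic SNR for modern 3-T breast
protocols), and lognormal patient-level kinetics (MSD median 150 a.u.,
sdlog 0.25; washout slope −0.2 a.u./s, sdlog 0.3). Keeping the generated
breakpoints on the time grid means the noiseless pipeline must recover
the ground truth to machine precision, which the tests exploit.

Spatial heterogeneity multiplies each voxel's MSD and WOS by
`max(0, 1 + 0.35·Z)` where `Z` is a unit-variance Gaussian random field
(white noise smoothed at a 1-voxel lengthscale; `Inf` gives the
homogeneous limit). Treatment scales each patient's field by group
effect factors with lognormal jitter (sdlog 0.1, clamped to (0.01, 2]):
defaults 0.10/0.11 (pCR) versus 0.92/0.94 (non-pCR) for MSD/WOS, i.e.
ground-truth median changes of ≈ 90%/89% versus 8%/6% and ground-truth
median SIS near 125 versus 10. Factors above 1 (paradoxical increases)
are permitted up to 2.

Two further effects, both with direct clinical counterparts, complete
the treatment model:

* **Shrinkage.** The post-treatment VOI semi-axes scale by 0.50 (pCR)
  versus 0.95 (non-pCR). Early concentric shrinkage is a hallmark of
  response; analytically it is also what drives two of the three
  significant texture changes. NGTDM busyness scales with the voxel
  count (its `s_i` terms are unnormalised sums over voxels), and runs
  are truncated by the smaller VOI, so busyness and long-run emphasis
  fall sharply in shrinking tumours.
* **Residual foci.** In pCR patients, 4% of VOI voxels respond with a
  weaker factor (0.25) instead of the group factor, modelling scattered
  residual enhancing foci. The foci stretch the post-treatment intensity
  range so the re-quantised bulk concentrates into few gray levels,
  lowering GLCM entropy. The fraction is small enough to leave the VOI
  median — and hence the ground-truth percentage changes — untouched.

This design is deliberate. A pure smoothed-field heterogeneity model
cannot reproduce the observed direction of all three significant texture
changes at once: with per-examination min-max quantisation at fixed
`n_levels`, entropy, long-run emphasis and busyness all track the
concentration of the level histogram, so any single-field change in
amplitude or lengthscale moves entropy and long-run emphasis in opposite
directions. Shrinkage and partial-response foci decouple them, and with
the defaults above the pCR-versus-non-pCR ordering of all seven
significant feature changes reproduces across seeds (the end-to-end test
checks exactly this). Within a cohort the post-treatment examination
reuses the patient's pre-treatment field (scaled), so pre and post share
spatial structure as real paired examinations do; the separate post
lengthscale applies only to standalone phantoms.

What the generator does **not** emulate: DICOM specifics, coil profiles
and fat-saturation artefacts, motion and misregistration between
examinations, pharmacokinetic (Tofts-type) contrast physics,
rim-enhancement geometry, and inter-scanner intensity scale differences.
Passing tests on these phantoms therefore demonstrate the correctness of
the computational pipeline and the internal consistency of its
statistics — not clinical performance on real data, where effect sizes
are far smaller and segmentation variability matters.

## Numerical and interface choices

* All randomness flows from a single integer seed; identical seed and
  configuration reproduce cohorts bit for bit, and re-running the
  analysis yields byte-identical CSVs.
* Examinations are stored as NIfTI-1 volumes and masks with frame times
  in a JSON sidecar (`frame_times_s`) — NIfTI-1 has no reliable 4-D
  timing convention, and explicit beats header heuristics. Masks
  binarise at strictly greater than 0 to tolerate probabilistic masks.
* Per-patient failures in a cohort run are logged and skipped; the run
  aborts if more than 20% fail, so statistics are never computed on a
  silently shrunken sample.
* Problem sizes in the shipped tests — 45-patient cohorts on
  24 × 24 × 12 grids, 25 frames, ≤ 6³ oracle volumes, 100-replicate
  noise studies — were chosen so each stage's validation is
  statistically meaningful while the whole suite runs in about a minute.

## Known limitations

* The piecewise search is O(n²) in the frame count per voxel
  (vectorised across voxels); very long dynamic series (hundreds of
  frames) would want a smarter search.
* The Youden cutoff uses observed values only; interpolated (midpoint)
  cutoffs are not offered.
* The Bonferroni family is whatever set of features the run tests —
  there is no hierarchy or pre-selection step.
* The texture panel composition (9+9+13+13+5+1) is this package's
  frozen definition of a 50-feature panel; other radiomics toolboxes
  partition their families differently, and wavelet or resampled
  variants are out of scope.
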