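---
title: "Quantifying periaortic fat in paired native and contrast-enhanced CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying periaortic fat in paired native and contrast-enhanced CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paftr)
```

## The measurement problem

Periaortic fat tissue (PaFT) — the adipose compartment within a few
millimetres of the abdominal aortic wall — is of interest for abdominal
aortic aneurysm (AAA) research because periadventitial adipocytes secrete
vasoactive and pro-inflammatory mediators. PaFT is conventionally quantified
on *unenhanced* CT by counting voxels in the adipose Hounsfield-unit range,
but AAA patients are usually imaged with contrast-enhanced CT angiography
(arterial phase) only. Intraluminal contrast changes the attenuation of
voxels at the aortic boundary, so fat volumes measured on the arterial phase
systematically underestimate the native value by roughly 10%. `paftr`
implements the full workflow for measuring PaFT in both phases, deriving a
multiplicative arterial-to-native conversion factor, and validating the
corrected measurements — together with a synthetic phantom generator so that
every stage can be exercised and calibrated without patient data.

## Geometry

For each axial slice between the most distal renal artery and the aortic
bifurcation an *aortic* region of interest is supplied as an ellipse traced
on the outer aortic wall (`ellipse_roi()`; automatic wall segmentation is
out of scope — contours are operator- or phantom-supplied). The *periaortic*
ROI extends each full axis by 10 mm — i.e. each semi-axis by exactly 5 mm,
same centre and rotation — producing a 5 mm-wide coaxial ring once the
aortic region is subtracted. The periaortic ROIs are built once, on the
native series, and the identical masks are applied to the arterial series,
so the periaortic volume is equal in both phases by construction.

Rasterisation uses boundary-inclusive voxel-centre containment: a voxel
belongs to an ROI iff its centre satisfies the ellipse inequality. This rule
is deterministic, convergent under grid refinement, and directly checkable
against an exhaustive point-in-ellipse scan (the test suite does exactly
that). A periaortic ellipse that exceeds the image bounds is clipped at the
edge and the slice flagged.

Reported volumes follow
`volume = n_voxels × pixel_area × slice_increment / 1000` (cm³). The
*reconstruction increment*, not the slice thickness, is the inter-slice
step; using the thickness would double-count overlapping 3 mm / 2 mm
reconstructions. The quantities per phase are the aortic volume (AVol),
periaortic volume (PaVol), ring volume (PaRVol = PaVol − AVol, computed as
that exact difference), fat volume (PaFTVol), and the size-adjusted ratio
PaFTVol/PaRVol. The maximum aortic diameter is defined as twice the shorter
semi-axis of the largest aortic disc (ties broken by cranio-caudal order).

## Fat segmentation

Fat-containing voxels are those with attenuation between −195 and −45 HU
(inclusive at both ends — the interval is read as closed, and the bounds are
asserted in the tests) inside the periaortic ROI. The search deliberately
includes the aortic disc: on unenhanced scans the lumen almost never
contains fat-range voxels, and `audit_intraluminal_fat_voxels()` counts the
exceptions per study so that the assumption is checked rather than taken on
faith. The audit refuses arterial input, where the contrast-filled lumen
makes the count meaningless.

The PaFT mean HU and SD are computed over the pooled selected voxels of the
whole stack (not as a mean of per-slice means), and the SD is the sample SD.
Both conventions were genuinely open choices; pooling matches how a
volume-level statistic is usually defined and is what the implementation
freezes and documents.

## Contrast quality control

Intraluminal contrast is sampled with a circular ROI (8, 10 or 12 mm
diameter; shrunk with a warning when the aorta is too small) centred on the
aortic ellipse at three longitudinal levels. The level proxies are
deterministic: first ROI slice (infrarenal), middle slice (mid-aortic), last
slice (bifurcation). Longitudinal variability is
`(max − min) / mean` of the three level means — scale-invariant and
permutation-invariant. Studies whose arterial intraluminal SD exceeds 35 HU
(strict inequality) are flagged as very-high-noise and excluded from
agreement analyses.

Aortic wall calcification is scored on the unenhanced series with a
modified Agatston score: per-slice 8-connected components of voxels at or
above 130 HU, lesions of at least 1 mm² scored as area × weight (weight
1–4 by lesion peak HU at the 130/200/300/400 cut-points), summed over slices
without merging lesions across slices and without the historical 3 mm slice
renormalisation — the classic per-slice rule applied to the reconstruction
as given. All of these choices are configurable; the 130 HU threshold is the
only externally fixed value, the rest is the canonical weighting.

## Derivation: conversion factors

On a paired cohort the native value is regressed on the arterial value
through the origin; the slope is the conversion factor. `Σxy/Σx²` with the
standard no-intercept standard error on n−1 degrees of freedom gives the
t-based confidence interval; the no-intercept R² is reported but flagged as
not comparable with intercept models. Pearson correlation (Fisher-z CI)
accompanies the fit, and a sensitivity filter can exclude large aneurysms
(> 55 mm).

The multivariate confounder screen is a *single full* ordinary
least-squares model — native value on arterial value plus calcification
score, mean intraluminal contrast, maximum diameter, slice thickness, tube
voltage, arterial image noise and longitudinal contrast variability —
flagging covariates with p < 0.05. A stepwise procedure would have been an
equally defensible reading of the workflow; the single full model is chosen
because it is reproducible in one pass and conveys the same decision through
the flags. Perfectly collinear covariates are dropped with a warning rather
than silently aliased.

The default correction factors carried by `paft_config()` are 1.1057 for
PaFT volume and 1.0011 for PaFT mean HU, applied as plain multiplication by
`apply_correction()`.

## Validation: agreement statistics

Agreement between native and corrected arterial values is assessed with:

* **Bland–Altman** — differences oriented native − corrected arterial;
  mean difference with t-based CI; limits of agreement mean ± 1.96 SD with
  CIs via `sd·sqrt(1/n + z²/(2(n−1)))`; one-sample t-test of zero mean
  difference. Zero-variance differences are reported as perfect agreement
  with the test marked degenerate rather than a fabricated p-value.
* **Passing–Bablok** — the shifted median of all pairwise slopes (slopes of
  exactly −1 discarded, offset K = #{S < −1}), rank-based CI with
  `w = z·sqrt(n(n−1)(2n+5)/18)`, intercept as `median(b − slope·a)` with its
  CI evaluated at the slope CI endpoints. The estimator is invariant under
  method exchange (exact reciprocal slope when the pairwise-slope count is
  odd).
* **Cusum linearity** — residual signs scored ±sqrt(counts ratio), ordered
  along the fitted line, cumulatively summed; the normalised maximum is
  referred to the Kolmogorov–Smirnov distribution.
* **Mann–Whitney** — exact two-sided p for 20 or fewer pooled observations
  without ties, normal approximation with tie correction otherwise; used for
  the AAA vs non-AAA group comparison.
* **ICC(2,1)** — two-way random-effects, absolute-agreement, single-measures
  intraclass correlation with the McGraw–Wong F-based CI. Absolute agreement
  is the appropriate variant for measurement reproducibility (a systematic
  offset between observers *should* lower it); a consistency variant would
  hide such offsets. Exact duplicate ratings return ICC 1 with a degenerate
  interval.

Passing–Bablok, the Cusum test, Bland–Altman and the ICC are implemented in
the package (no installed dependency provides them); Pearson/Spearman,
Wilcoxon and all linear models delegate to stats.

## The phantom generator

`phantom_spec()` / `generate_phantom_pair()` build paired native/arterial
volumes of a synthetic infrarenal aorta: a contrast-filled lumen
(native ~N(40, 5) HU; arterial ~N(316, 22) HU with an optional cranio-caudal
gradient and per-study mean attenuation drawn around 316 ± 82 HU), a 2 mm
soft-tissue wall (~N(45, 10) HU), a periaortic ring whose voxels contain fat
with probability `fat_fraction` (fat ~N(−77, 9.7) HU) on a soft-tissue
background (~N(20, 15) HU), optional calcified wall lesions (130–600 HU) and
rare fat-range artifact voxels in the native lumen. Both phases share
identical geometry, fat placement and tissue noise draws; *only*
contrast-dependent effects differ.

The enhancement effect is a boundary-shell partial-volume surrogate: a
calibrated number of fat voxels within 2.5 mm of the aortic wall have their
arterial HU raised above −45 (clamped so they cannot fall back into the fat
window). The systematic count is `round(n_fat × (1 − 1/ratio))` with the
study's true native/arterial volume ratio defaulting to 1.1057, so interior
fat HU is untouched — reproducing the twin empirical findings that the
volume shrinks by ~10% while the mean fat HU is essentially unchanged
(conversion slope ≈ 1).

Study-level measurement variability enters as an *additive* perturbation of
the lost-voxel count, drawn with constant SD in cm³ (default 1.5% of a
nominal 22 mm study's fat volume) and clipped symmetrically to the feasible
range. The additive (homoscedastic-in-volume) structure is deliberate: paired
fat-volume differences in such workflows show roughly constant limits of
agreement across aorta sizes, and under a heavy-tailed size distribution any
size-proportional noise would make ordinary through-origin inference
miscalibrated. With the additive structure the regression CI has nominal
coverage, which the calibration tests verify. The default SD is kept small
enough that the symmetric clipping is rare; as a consequence the generator is
*under-dispersed* relative to the per-study percentage differences of a real
cohort — a stated limitation, not an accident.

`generate_cohort_specs()` draws cohort composition: ~14% aneurysmal studies
(fusiform diameter bulge, 31–110 mm), non-AAA diameters ~N(22.3, 2.7) mm,
tube voltage 100/120/130 kV at roughly 14:86:1, slice thickness/increment
3/2 mm with a ~5% 5/4 mm minority, Beta(1.91, 2.19) fat fractions (moment-
matched to a mean ratio of 0.467 with SD 0.22), Poisson calcification counts
and a zero-inflated geometric artifact-count distribution (about 55% of
studies have none). Covariates are independent of the enhancement effect by
default (null confounding); a `confounded_kv_effect` switch injects a
voltage-dependent ratio shift for power studies of the confounder screen.

Replicate cohorts are seeded by drawing sub-seeds from one master seed with
`sample.int()`; consecutive `set.seed()` values produce correlated streams
at matching offsets and are avoided.

### What the phantom does not emulate

No organs, bones, streak artifacts, reconstruction kernels or dose/noise
physics; artifact voxels are injected point-wise. Aortic contours are exact
ellipses, so operator tracing variability is absent (reproducibility
statistics exercised on phantoms reflect only sampling noise). Passing tests
therefore demonstrate the correctness and calibration of the *measurement
and statistical machinery*, not the anatomical realism of the images.

## Problem sizes and numerical choices

Default desk-scale sizes, chosen once: 10 axial slices per study, 0.7 mm
pixels, grid sized adaptively to the aortic diameter plus ring and margin;
derivation cohorts of 100 studies and validation cohorts of 47; 20 replicate
cohorts for the recovery simulations in the acceptance script. At these
sizes a full 20-cohort derivation run completes in about two minutes on one
CPU. Threshold comparisons are exact on stored values (no epsilon), ring
volume converges to the analytic annulus within 2% at 0.7 mm pixels, and
degenerate inputs (vanishing lumen, no boundary shell, zero ring volume,
zero-variance inputs to the statistics) raise errors rather than returning
silent numbers.

## A worked run

```{r, eval = FALSE}
library(paftr)

cohort <- quantify_cohort(generate_cohort_specs(100, seed = 1))
derivation <- run_derivation(cohort)
tidy(derivation)

validation <- quantify_cohort(generate_cohort_specs(47, seed = 2)) |>
  run_validation(paft_config(volume_factor = derivation$volume_factor,
                             hu_factor = derivation$hu_factor))
tidy(validation)
autoplot(validation$volume$bland_altman)
```

## Known limitations

* Only elliptical aortic contours are supported; irregular hand-drawn
  contours and alternative treatments of non-circular discs are out of
  scope.
* The conversion factors are multiplicative by design; no robust or
  errors-in-variables alternatives are fitted.
* The generator's per-study dispersion is smaller than a real cohort's (see
  above), and its artifact-count tail is lighter than real scans with
  metal hardware.
* DICOM support is read-only and limited to uncompressed little-endian
  single-frame CT series; NIfTI (with a JSON sidecar for slice thickness
  and phase) is the canonical interchange format.
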