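---
title: "Calcium scoring on phantom images: models, simulator and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium scoring on phantom images: models, simulator and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calscore)
library(dplyr)
library(tidyr)
```

## The problem

Calcific aortic valve disease is graded in the clinic by CT (the Agatston
score), but echocardiography is the routine first-line exam. A gray-scale
ultrasound calcium score — computed from ordinary B-mode images — would make
calcium quantification available wherever an echo probe is, if it can be
shown to track the true calcium amount and the CT reference. The natural
test bed is a tissue-mimicking agar phantom loaded with known masses of
hydroxyapatite, imaged by both modalities under controlled geometry.

This package implements the three scores, a synthetic phantom image
simulator with exact ground truth, and the statistics used to validate
score against mass.

## The three scores

**Ultrasound calcium score.** Each exported RGB frame is collapsed to gray
(ITU-R BT.601 luma, rescaled to the 0–250 ultrasound pixel-value range).
Inside a wide manual ROI, everything outside which has been zeroed, all
pixels with PV ≥ 130 are selected as calcium — a global threshold chosen
above the maximum gray-scale density of agar, with no connectivity or
minimum-size filtering. Per slice, the score is
`area_calcium × PV_max`; per sweep it is the sum over slices; the speck's US
calcium score is the mean of the short-axis and long-axis sweep totals. The
US calcium volume is the summed area (numerically mm³ at the 1 mm stepping
used throughout; a spacing-corrected `total_volume_mm3` is also reported).

**CT calcium score.** Micro-CT stacks store raw 16-bit pixel values; the
Hounsfield scale is anchored by water and air references,
`HU = (PV − PV_water)/(PV_water − PV_air) × 1000`, so water maps to 0 HU
and air to −1000 HU by construction. Calcium is selected at 700 HU — the
clinical 130 HU Agatston threshold would select agar at micro-CT
resolution — after converting the HU threshold to a PV threshold with a
ceiling, so no sub-threshold pixel is ever admitted. Per slice, the maximal
selected PV is converted back to `HU_max` and a weighting factor assigned:
0 below 700 HU, 1 for 700–999, 2 for 1000–1999, 3 for 2000–2999, 4 from
3000 HU up. The conventional table leaves exactly 3000 HU unassigned
(between "2000–2999" and "> 3000"); we close the gap upward, which keeps
the factor monotone, and the table is a configurable `wf_table()`. The
slice calcification score is `wf × area`; totals are summed over slices.
ROIs are drawn on the first and last slice of a speck only and linearly
interpolated in between (`interpolate_rois()`), as in the manual workflow.

**cIB calcium score.** Integrated backscatter is read per slice inside an
ellipse delineating the calcium (treated as a 2-D ellipse per image), with
an agar reference ROI above the speck:
`cIB = (IB_calcium − IB_agar) × area`, summed per axis and averaged across
axes. Subtracting the agar reference removes global gain, so the score is
invariant to a uniform dB shift — a property the tests check. Readings are
consumed from CSV (or simulated); raw radio-frequency processing is out of
scope.

Two unit conventions differ deliberately from typical 0-based image
toolkits: pixel and slice coordinates are 1-based and rectangle bounds
inclusive, the R idiom.

## The phantom simulator

`phantom_scene()` describes the physical phantom: a 100 × 100 × 25 mm agar
block with nine 15 × 3 × 5 mm holes, tops 10 mm deep, loaded with 2, 4, 6,
8, 10, 20, 30, 40 and 50 mg of hydroxyapatite. (Nine 3 mm holes with the
nominal 1 cm interspace would span 107 mm; the simulator uses 9 mm gaps so
the ladder fits the block. Speck placement does not affect any score, since
each speck is rendered and scored independently.)

**Density model.** Dry powder spread into a hole does not fill it: it
settles as a bottom layer. We model a layer of fixed packing density
ρ_pack = 0.25 mg/mm³ (a loose 20 µm powder) spread uniformly over the
15 × 3 mm footprint, so mass *m* gives layer height `h = m / (0.25 · 45)`
mm — 0.18 mm at 2 mg up to 4.4 mm at 50 mg, always inside the 5 mm hole.
Layer height, not in-layer density, carries the mass signal; this is what
makes calcium *area* grow with mass in every modality and keeps both scores
strictly increasing. The column (areal) density seen along the beam is
ρ_a = ρ_pack · h = m/45 mg/mm².

**Ultrasound render** (`render_us()`): one slice per mm along the chosen
axis (probe across the speck for the short axis, along it for the long
axis), 0.1 mm pixels (not a measured quantity; chosen so the 3 mm speck
width spans 30 pixels). Agar is Rayleigh speckle (scale 35 PV) clipped
below the 130 PV threshold — mirroring the fact that the threshold was
chosen above the brightest agar — and calcium pixels are drawn around a
mean intensity

μ(ρ_a) = 130 + (250 − 130) · (1 − exp(−ρ_a / ρ_sat)),  ρ_sat = 40/45 mg/mm²,

which starts at the selection threshold and saturates toward the 250 PV
ceiling. ρ_sat is set to the areal density of the 40 mg speck so that
saturation becomes visible only above 40 mg, reproducing the plateau
observed there, while the score remains near-linear below it. Optional
acoustic shadowing attenuates pixels beneath the calcium column by a
configurable dB/mm; it is off by default so that deterministic renders
reflect geometry alone.

**CT render** (`render_ct()`): 83 µm in-plane pixels, stepped along the
speck long axis at 1 mm (one `wf × area` term per step keeps the volume
index comparable with the ultrasound convention). Agar sits in a
configurable 0–60 HU near-water band. A calcium layer's apparent peak
density is

HU(ρ_a) = 700 + 3300 · (1 − exp(−ρ_a / 0.25)),

rising from just above the selection threshold for the thinnest layers
toward the ~4000 HU of dense hydroxyapatite. A strictly linear
density→HU map was considered and rejected: with a single wide ROI per
slice the slice score is `wf × area` with an *integer* wf, and a linear map
walks the nine masses through the bins so coarsely that the score–mass
relation cannot reach R² ≥ 0.99 (it caps near 0.983 — an analytic
property of the bin structure, computable before rendering a single
pixel). The saturating map is also the physically expected behaviour:
partial-volume averaging dilutes the apparent HU of layers thinner than
the point-spread scale, and thick layers approach pure-mineral density.
Gaussian HU noise and a Gaussian boundary blur are available and on by
default; the `*_off()` noise constructors disable every stochastic term.

**IB render** (`render_ib()`): per-slice readings with contrast
`8 · log1p(ρ_a)` dB over a −55 dB agar baseline and ellipse diameters from
the calcium cross-section (an operator would not draw an ellipse thinner
than ~0.5 mm, so the short diameter is floored there).

**Ground truth and mass conservation.** Each render returns binary calcium
masks built by pixel-center sampling — the same rule the renderer uses to
paint calcium, so with noise off the thresholded mask equals the ground
truth *exactly*, on every slice of every speck, for both modalities. The
rasterizer also reports an exact-overlap volume (fractional pixel
coverage); multiplied by ρ_pack it recovers the input mass to floating
point precision. The binary mask volume is pixel-quantized instead (a 2 mg
layer is 1.8 pixels tall at 0.1 mm), which is why conservation is asserted
on the exact-overlap volume.

**What the simulator does not emulate.** Speckle correlation, beam-width
and depth-dependent resolution, refraction, reverberation, CT
reconstruction artifacts (rings, beam hardening), and operator variability
in ROI placement. Passing recovery tests therefore demonstrates that the
scoring pipeline is correct and monotone on images whose contrast model is
known — not that the scores are accurate on clinical images.

## Validation statistics

`pearson_r2()` reports Pearson's r, R² = r² (the convention used for
score-versus-mass figures of merit) and a two-tailed t-based p value.

`roc_analysis()` builds the empirical ROC with the positive-at-high-values
convention. Candidate cutoffs are midpoints between consecutive distinct
scores, so a reported cutoff always separates two observed values. AUC is
the trapezoidal area, identical to the Mann–Whitney concordance
probability — a test asserts this by full pair enumeration. The operating
point maximizes Youden's J, ties broken toward the higher cutoff (higher
specificity); the criterion is not uniquely determined by the reported
sensitivity/specificity patterns in this field, but Youden is consistent
with them. `tertile_labels()` builds the "low tertile (≤ 10 mg) versus
higher (> 10 mg)" task, with a strict inequality at the boundary.

`icc_agreement()` computes the single-measures, two-way, absolute-agreement
ICC — McGraw & Wong's ICC(A,1), the standard model for intra-observer and
inter-study designs; reproducibility reports rarely name their ICC model,
so the choice is documented here and the mean squares are exposed to
F-based 95% confidence limits with Satterthwaite degrees of freedom. The
implementation computes the two-way sums of squares directly and is tested
against an independent `aov()` decomposition and against externally
computed reference values.

## Numerical choices and edge cases

- Threshold comparisons are inclusive (≥) everywhere.
- Grayscale conversion rounds half *up* (R's `round()` is banker's
  rounding, which would map 98.5 and 97.5 both to 98).
- `pv_from_hu(..., discrete = TRUE)` uses a ceiling so quantization can
  only exclude, never admit, sub-threshold pixels; with integer-exact
  calibrations (e.g. 1 PV per HU) selection matches the HU rule exactly.
- An empty selection yields `(area, PV_max, score) = (0, 0, 0)` and slices
  without a ROI contribute zeros rather than being skipped — identical
  sums, simpler bookkeeping.
- A zero-mass hole renders as pure agar and scores 0 in all modalities.
- `ct_calibration()` refuses `pv_water ≤ pv_air`; correlation on constant
  input and ROC with a single class are errors, not NaNs.
- Renderers restore the caller's RNG state; per-speck streams derive from
  the scene seed, so adding a speck does not shift its neighbours' noise.

## Problem sizes

The recovery and reproducibility analyses in the tests and examples use
the nine-speck scene at the geometry above: per speck, roughly 19
ultrasound slices of 90 × 70 px per axis and 19 CT slices of 108 × 84 px
— about 4 s for a full render-and-score pass of all nine specks, so the
whole validation suite completes in well under a minute.

## Known limitations

- DICOM and NPZ import are not provided; stacks travel as multi-page TIFF
  with a JSON sidecar (8-bit US, 16-bit CT) and IB readings as CSV.
- The phantom's two sweeps cover identical physical extents by
  construction; real probes see different windows per axis.
- Absolute score magnitudes depend on the simulator's contrast model and
  are not comparable to scanner-specific values; only relationships
  (monotonicity, linearity, discrimination, reproducibility) transfer.
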