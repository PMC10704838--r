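---
title: "Methods: stereology, capillary ultrastructure and group statistics in capimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereology, capillary ultrastructure and group statistics in capimorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capimorph)
```

`capimorph` implements the quantitative morphometry used to characterise
skeletal-muscle microangiopathy — capillary rarefaction on light micrographs
and capillary basement-membrane (CBM) thickening on electron micrographs —
together with the semiquantitative histopathology rubrics and the group
statistics that accompany such studies. Because raw micrographs from
clinical studies are rarely shareable, the package ships a synthetic
tissue/profile generator with known ground truth; every estimator can be
validated against the truth it was generated from.

## 1. Stereology on light-micrograph fields of view

A field of view is treated as an unbiased counting frame: the top and right
edges accept, the left and bottom edges — together with the upward extension
of the left edge and the downward extension of the right frame line below
the bottom-right corner — form the *forbidden line*. A profile is counted
iff it intersects the frame (interior or acceptance edges) and does not
touch the forbidden line. This convention makes counts additive under frame
tiling: every profile is counted exactly once, which the test suite asserts
by tiling whole scenes with contiguous frames. Capillaries are counted as
points (their profiles are two orders of magnitude smaller than fibers at
this magnification); fibers as polygons. Tangencies are resolved with a
1e-9 µm tolerance: touching an acceptance edge counts, touching a
forbidden edge does not.

Test points form a 10 × 10 grid whose 100 points each represent one
`spacing²` tile; the grid's counting area spans the field. From the counted
quantities:

* **C/F ratio** = capillary profiles / fiber profiles,
* **total fiber area** = (test points on fibers / total points) × grid area,
* **MCSFA** (mean cross-sectional fiber area) = total fiber area / fiber
  profiles,
* **capillary density** = capillary profiles / total fiber area, reported
  per mm².

Per-sample aggregation pools raw counts across fields before forming
ratios (*ratio of sums*). Mean-of-ratios is biased for ratio estimators and
fails on fields without fibers; the pooled form also makes the identity
`capillary density × MCSFA = C/F` hold exactly (asserted to 1e-9).

The physical grid geometry is a required configuration parameter: the
defaults are 450 µm square fields, ten per sample. This size was chosen so
that the per-sample sampling coefficient of error of the C/F estimate
(≈0.08 on simulated mosaics) is small against the between-subject spread;
with small fields the estimator is unbiased but too noisy for the group
comparisons the package is designed to reproduce.

## 2. The synthetic tissue generator

Fiber mosaics are jittered hexagonal tilings: vertices shared by
neighbouring cells are perturbed consistently (truncated Gaussian, SD 10% of
the hexagon side), each fiber is shrunk about its centroid by a uniform
factor in [0.85, 1] (leaving interstitial endomysium and mild area
variability), and atrophic type-2b fibers are shrunk further by the
configured atrophy factor. A Voronoi tessellation with Lloyd relaxation
would serve equally; the jittered tiling was chosen because it needs no
spatial dependencies, has exactly controllable mean area, and guarantees
simple, interior-disjoint polygons. Hexagon area is set to
`mcsfa / E[u²]` so the realized mean fiber area matches the target.

Capillaries are placed at randomly chosen fiber-junction points and snapped
exactly onto the nearest fiber boundary, reflecting the anatomical position
of capillaries in the endomysium at fiber borders; the count is
`round(C/F × fibers)`, so the scene-level ratio is exact to within half a
fiber. The scene extent includes an empty rim one field wide. This makes
random field placement translation-invariant over the mosaic: without the
rim, objects near the scene border are counted with reduced probability
relative to interior ones (their admissible frame positions are truncated
asymmetrically for points and polygons), which biased the C/F estimate
downward by about 5% in early simulations. With the rim the estimator is
unbiased, as the placement-averaged test asserts.

What the generator does **not** emulate: fiber-type-specific size
differences, spatial clustering of fiber types, capillary tortuosity
(profiles are points), staining artefacts, or section folds. Passing tests
therefore demonstrate correctness of the estimators on idealized geometry,
not robustness to real-world image segmentation errors — contours and
annotations are assumed given.

## 3. TEM capillary profiles and CBM measurement

Synthetic capillary cross-sections consist of three nested closed contours
in nm — lumen (blood:endothelium), abluminal endothelial surface
(endothelium:BM) and outer basement membrane (BM:endomysium) — plus
pericyte arcs on the abluminal surface. The CBM thickness field varies
smoothly around the profile as a sum of order-2..4 harmonics with random
phases, scaled so its angular SD equals `cbm_sd`. Oblique sectioning is an
area-preserving affine stretch by `obliqueness`; thickness measured on a
stretched profile is geometrically distorted, which is precisely why
profiles with caliper aspect ratio above 1.2 are excluded before
measurement. (The field's customary phrasing, "ratio of the smallest to
largest diameter of more than 1.2", inverts the fraction; the implemented
criterion is largest/smallest > 1.2, strict.)

All CBM quantities are in nanometres. Published figures sometimes label the
same quantities "µm"; a 350 µm basement membrane is not physiological and a
7000× electron micrograph cannot contain one, so the package treats such
values as nm throughout, including the 350 nm display-outlier threshold.

**Six-site protocol.** Sites are six evenly spaced angles with a uniform
random rotation; any site within a 5° margin of a pericyte arc is re-drawn
uniformly from the pericyte-free angular domain, because the membrane is
irregular and thicker where pericyte processes intervene. Thickness at a
site is the length of the segment from the abluminal contour to the outer
BM contour along the local outward normal. Even spacing with random
rotation (rather than six independent uniform angles) guarantees distinct,
well-spread sites and makes the capillary mean nearly invariant under the
rotation offset. If the pericyte-free domain is smaller than one margin
width per site the profile errors out — such profiles should already have
been excluded by the coverage cutoff (default 80%).

**Contour morphometry.** Areas come from the shoelace formula,
circumferences from polyline length. Lumen radius is the equivalent-circle
radius `C/2π`; endothelial and BM thicknesses use the annulus mean-thickness
estimator `t = 2ΔA / (C_inner + C_outer)`, the standard unbiased form for a
thin annulus (area difference divided by mean circumference). The estimator
is validated against dense radial ray-casting: agreement is within 5% for
aspect ratios in the inclusion regime (≤1.2), and within 0.1% on concentric
circles. Pericyte coverage is the percentage of abluminal circumference
under pericyte arcs. Subjective exclusion criteria from practice ("blurry",
"abnormally large", "very high pericyte coverage") are operationalized as
configurable thresholds: lumen radius > 5000 nm, coverage > 80%.

Sample-level CBM is the mean of capillary means; group level reports both
the mean over all single measurements and the mean over sample means, since
published work rarely states which convention was used. Measurements above
the display-outlier threshold are flagged but retained in statistics (the
flag exists for plotting); dropping them is a configuration choice, not the
default, because the outliers are real measurements.

## 4. Histopathology rubrics

* **Type-2b atrophy (0–3):** fraction *f* of type-2b fibers that are
  atrophic; 0 if *f* = 0, 1 if *f* < 15%, 2 if 15% ≤ *f* ≤ 60% (both
  boundaries belong to grade 2, matching the rubric's closed "15–60%"
  band), 3 if *f* > 60% *and* "many" 2b fibers are under 20 µm minimal
  Feret diameter. "Many" is operationalized as a configurable fraction,
  default 0.30, since the rubric gives no number. Fiber diameter is the
  minimal Feret diameter — robust to oblique sectioning, standard in
  myopathology. In re-analysis mode "atrophic" is an input flag; for tables
  lacking it, `derive_atrophic()` applies an area < 0.5 × same-type-median
  rule (configurable).
* **MHC class I (0/1/2):** single positive fibers (< 20%) are within normal
  range (score 1, not significant); sarcolemmal upregulation in ≥ 20% of
  fibers scores 2 and is flagged significant.
* **Capillary pathology (0–4):** deterministic rubric in priority order
  4 → 0; endothelial necrosis/debris always scores 4; grade 3 is the
  grade-2 feature set plus an explicit `pronounced` severity flag, because
  the verbal rubric defines grade 3 only as "same as 2 but more
  pronounced".
* **Immune cells:** counted per 10 high-power fields; the generator draws
  per-sample expected totals from a gamma-mixed Poisson (negative binomial
  marginally) so that the per-group total SDs match the configured values,
  with CD68/CD169 means and SDs taken from the published group summaries.

## 5. Group statistics

`tukey_from_summary()` reconstructs the one-way ANOVA error term from
per-group means, SDs and sizes (`MSE = Σ(nᵢ−1)sᵢ²/Σ(nᵢ−1)`), uses the
Tukey–Kramer standard error `sqrt(MSE/2 (1/nᵢ + 1/nⱼ))` for unequal group
sizes, and evaluates `q = |Δ|/SE` against the studentized-range
distribution (R's `ptukey`, the standard double-integral quadrature; a
Monte-Carlo oracle in the tests checks its tail at k = 3, df = 24).
`anova_tukey()` is the raw-data path and is asserted to agree with the
summary path to 1e-12 and with base `aov`/`TukeyHSD` to 1e-6. Re-testing
*printed* summaries can only agree with the original raw-data analysis to
about one significant figure, because printed means and SDs are rounded;
for p-values below 0.001 it is additionally unknown whether the original
report rounded or truncated, so comparisons accept either.

Pearson correlations use the exact product-moment form with the t
transform (n − 2 df). ΔΔCt fold changes average triplicate Ct values after
dropping cycles above 40 (the "not expressed" cutoff), form
ΔCt = Ct_target − Ct_reference per sample, and report `2^−ΔΔCt` of the
case-minus-control ΔCt difference; a reference gene with no expressed
replicate is an error, a target with none is flagged not-expressed.

## 6. Default study conditions and power

The default cohort mirrors a three-group case-control design: HDC (n = 8),
2BA (n = 8), PCS (n = 11); 20–30 TEM capillaries per sample; C/F
1.82/1.80/1.50; MCSFA 4400/5000/3500 µm²; CBM 300/301.5/340 nm. Dispersion
defaults are a design choice. The package's validation operating point asks
that a configured C/F difference of 0.30 and CBM difference of 40 nm be
detected (Tukey p < 0.05, PCS vs HDC) in at least 90% of repeated
simulations, so dispersions were set by a normal-model power analysis to
give ~98% design power at n = 8/8/11: between-sample SDs of 0.12 (C/F) and
15 nm (CBM), between-capillary SD 40 nm, within-capillary site SD 30 nm.
These are tighter than the dispersions implied by the significance levels
typically printed for effects of this size (p in the 0.007–0.016 range at
n = 8/8/11 implies total sample SDs near 0.20 and 29 nm, i.e. only
~75–78% power); a generator reproducing such dispersions would detect its
own effects in barely three of four runs — a statement about clinical
study precision at these sample sizes, not about the estimators validated
here.

Problem sizes used by the test suite and acceptance script — 780-fiber
scenes, ten 450 µm fields, 24 capillaries of 96-vertex contours per sample,
50 (tests) or 10 (script) replicate cohorts — were chosen so the grand-mean
recoveries have Monte-Carlo error well inside the asserted bands.

## 7. Numerical choices and degenerate inputs

* Geometry tolerance 1e-9 (µm or nm) for tangency and intersection tests.
* Zero-area polygons are counted as points at their vertex mean; empty
  profile lists count 0.
* The minimal Feret diameter is computed over convex-hull edge normals
  (rotating-calipers equivalent); contours need ≥ 8 vertices for an aspect
  ratio.
* The CBM harmonic field is clamped below at 10% of its mean, so extreme
  `cbm_sd` cannot produce non-nested contours; contour nesting is verified
  and violations name the offending pair.
* Sample-level C/F draws are truncated at ±3 SD and at the hexagonal
  mosaic's junction capacity (~2.15 capillaries per fiber); an infeasible
  target raises an error naming the limiting parameter.
* All randomness flows from one seed through stable string-hash substreams
  (`substream_seed`), so any sample or stage can be regenerated in
  isolation and whole runs are byte-reproducible (checksummed manifests).

## 8. Known limitations

* Geometry in, geometry out: no raster image processing, no contour
  tracing, no blur/artefact modelling.
* Single 2-D sections only; no disector or other 3-D stereology.
* The synthetic mosaic has lower fiber-area variance than real muscle and
  no fiber-type size structure; composition estimates are correspondingly
  optimistic.
* Scoring rubrics are deterministic mappings of feature flags; inter-rater
  variability of the underlying subjective judgements is out of scope.
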