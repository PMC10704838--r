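# capimorph

Quantitative capillary morphometry for skeletal muscle biopsies.

Studies of muscle microangiopathy — for example in post-infectious fatigue
syndromes, diabetes or mitochondrial disease — rest on a small set of
quantitative readouts: the **capillary-to-fiber ratio (C/F)** and
**capillary density** estimated by point-counting stereology on semithin
sections, the **capillary basement-membrane (CBM) thickness** measured at
six sites per capillary on transmission-electron-microscopy profiles, and
semiquantitative rubrics for type-2b fiber atrophy, MHC class I
upregulation and capillary pathology, compared across groups with one-way
ANOVA and Tukey's test. `capimorph` implements this entire pipeline as
tested, reusable R functions, together with a synthetic tissue and
TEM-profile generator with known ground truth so that every estimator can
be validated without access to clinical images.

## The quantities

With an unbiased counting frame (acceptance edges top/right, forbidden
line left/bottom with its infinite extensions) and a 10 × 10 test-point
grid of total area *A*:

- C/F = N_cap / N_fib (both counted under the forbidden-line rule)
- total fiber area Â = (P_fiber / P_total) · A
- MCSFA = Â / N_fib  (mean cross-sectional fiber area, µm²)
- capillary density = N_cap / Â  (per mm²)

so that density × MCSFA = C/F exactly when counts are pooled per sample
(ratio of sums across ≥10 fields of view).

On TEM contours (lumen, abluminal endothelium, outer basement membrane;
areas *A* by shoelace, circumferences *C* by polyline length):

- lumen radius = C_lumen / 2π
- endothelial thickness = 2(A_ec − A_lumen)/(C_lumen + C_ec)
- BM thickness = 2(A_bm − A_ec)/(C_ec + C_bm)
- pericyte coverage = arc length under pericyte processes / C_ec

Profiles with caliper aspect ratio > 1.2 are excluded as obliquely
sectioned; CBM thickness is additionally measured at six evenly spaced
sites (random rotation, pericyte arcs avoided by a 5° margin) along the
local outward normal. All CBM values are in nanometres.

Group comparisons use the Tukey–Kramer studentized-range test, available
both from raw per-sample values (`anova_tukey()`) and directly from
printed group summaries (`tukey_from_summary()`), plus Pearson
correlation and ΔΔCt fold changes (`ddct_fold_change()`, 40-cycle
expression cutoff).

## Worked example

Re-test published macrophage counts (cells per 10 high-power fields,
mean [SD], n = 8/8/11) straight from the printed summaries:

```r
library(capimorph)
cd68 <- data.frame(group = c("HDC", "2BA", "PCS"),
                   mean = c(32, 34, 58), sd = c(12, 15, 16), n = c(8, 8, 11))
tukey_from_summary(cd68)
#> Tukey-Kramer comparisons (k = 3, MSE = 214.3, df = 24)
#>  group_i group_j mean_difference standard_error q_statistic p_adjusted
#>      HDC     2BA              -2       5.175564   0.3864313      0.960
#>      HDC     PCS             -26       4.809757   5.4056788      0.002
#>      2BA     PCS             -24       4.809757   4.9898574      0.005
```

The PCS group has ~26 more CD68⁺ cells per 10 HPF than healthy disease
controls (adjusted p ≈ 0.002); the two control groups do not differ.

Simulate a small three-group cohort and run the whole pipeline
(stereology → TEM morphometry → histology scores → statistics):

```r
spec <- cohort_spec(group_sizes = c(3L, 3L, 3L), scene_fibers = 260L,
                    capillaries_per_sample_range = c(10L, 12L), seed = 42L)
res <- run_pipeline(run_config(seed = 42L, cohort = spec))
res$per_sample[, c("sample_id", "group", "cf_ratio", "mcsfa_um2", "cbm_mean_nm")]
#>   sample_id group cf_ratio mcsfa_um2 cbm_mean_nm
#> 1     HDC-1   HDC    1.899      4541       348.1
#> 2     HDC-2   HDC    1.956      4677       309.9
#> 3     HDC-3   HDC    1.850      4353       272.9
#> 4     2BA-1   2BA    1.841      4802       288.3
#> 5     2BA-2   2BA    1.771      4339       293.3
#> 6     2BA-3   2BA    1.581      4176       316.9
#> 7     PCS-1   PCS    1.611      3078       370.5
#> 8     PCS-2   PCS    1.429      3258       354.7
#> 9     PCS-3   PCS    1.587      3330       333.7
```

Each row is one simulated biopsy: the PCS samples show the configured
capillary rarefaction (C/F ≈ 1.5 vs ≈ 1.8), smaller fibers, and thicker
basement membranes. At n = 3 per group the CBM Tukey comparison is not yet
significant (`res$stats$cbm_mean_nm$tukey` gives HDC-vs-PCS p ≈ 0.19) —
the study-sized design (8/8/11, 24 capillaries per sample) detects the
same 40 nm difference in >90% of runs, which is what the acceptance
script measures.

With `run_pipeline(config, out_dir = ...)` the per-sample table, all 6 ×
N single CBM measurements, the exclusion log, ground truth and a JSON
report are written as TSV/JSON with an md5 manifest; identical
config + seed reproduces identical checksums.

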