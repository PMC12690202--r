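# qsmgrad

Principal-axis iron gradient mapping for quantitative susceptibility MRI of
subcortical nuclei.

## The problem

Quantitative susceptibility mapping (QSM) measures tissue magnetic
susceptibility, which in deep gray matter is dominated by iron. Classical
ROI analyses average susceptibility over a whole nucleus and therefore miss
where inside the nucleus iron accumulates. In Parkinson's disease this
matters: degeneration in the substantia nigra (SN) and striatum is spatially
graded (e.g. the posterior putamen and the ventrolateral nigra are hit
first), and the two motor phenotypes — tremor-dominant (TD) and postural
instability/gait difficulty (PIGD) — are thought to involve different
circuits and different temporal patterns of iron accumulation.

`qsmgrad` implements a within-nucleus gradient analysis for this setting,
plus the clinical classification and statistical layers around it, and a
synthetic cohort generator so that every stage of the pipeline can be
exercised and validated end to end without patient data.

## The method

For a nucleus mask with voxel centres `x_1 … x_m` (in scanner mm via the
NIfTI affine, so anisotropic voxels do not bias the result):

1. **Principal axes.** Centre the coordinates and take the right singular
   vectors of the centred coordinate matrix `X − x̄`: the three orthonormal
   principal axes of the structure, ordered by singular value. Axes are
   matched to the anatomical directions medial–lateral (M-L),
   anterior–posterior (A-P) and ventral–dorsal (V-D) by maximum absolute
   cosine (globally, over all six assignments), and oriented so each axis
   points M→L, A→P, V→D.
2. **Equidistant segmentation.** For each axis, two bounding hyperplanes
   orthogonal to the axis pass through the outermost projections, and
   `n − 1` equally spaced parallel hyperplanes split the interval into
   `n = 7` equidistant segments; voxel with projection `p` falls in segment
   `⌊n (p − p_min)/(p_max − p_min)⌋ + 1` (the maximum closed into segment
   `n`). Segment 1 is always the medial / anterior / ventral end.
3. **Spatial functions.** Per subject, ROI and axis, the median
   susceptibility within each segment — a length-7 "spatial function" —
   plus the ROI mean. Functions are averaged across subjects per group and
   the segment of the maximum ("peak") is tracked across disease stages,
   with shifts reported anatomically (e.g. a peak moving from segment 4 to
   7 on M-L is a *lateral shift*).
4. **Clinical layer.** Motor subtype from the UPDRS tremor/PIGD item-mean
   ratio (TD ≥ 1.15, PIGD ≤ 0.9, otherwise intermediate); disease stage
   from duration (early < 2 y, middle 2–6 y, late > 6 y); hemispheres
   lateralized into more-/less-affected sides (MAS/LAS) contralateral to
   symptom onset (dominant/non-dominant for controls).
5. **Statistics.** Covariate-adjusted general linear models (age, sex,
   LEDD) with nested-model F tests and Bonferroni-corrected pairwise
   contrasts for group and stage comparisons (per mean ROI and per
   segment); normality-routed two-group tests (Kolmogorov–Smirnov →
   t-test or Mann–Whitney U); uncorrected Pearson chi-square for
   categorical tables; partial correlations (age-adjusted, residual
   method) between regional iron and clinical scores with
   Benjamini–Hochberg correction across each subtype's ROI × score grid.

The synthetic generator draws cohorts with the full design (47 HC, 55 PIGD,
53 TD; stages 11/28/16 and 12/26/15), rasterised bilateral SN / putamen /
caudate masks as rotated ellipsoids on a 0.9 × 0.9 × 2 mm grid,
within-nucleus Gaussian-bump gradients along configurable axes (optionally
moving with stage), additive stage offsets implementing the inverted-U
(PIGD) and S-shaped (TD) temporal presets, and clinical scores with
calibrated correlations to regional iron.

## Worked example

```r
library(qsmgrad)

cohort <- generate_cohort(cohort_config(), seed = 42)
cohort
#> Synthetic QSM cohort: 155 subjects (seed 42)
#>     HC  PD PIGD   PD TD
#>     47      55      53
#> grid 64 x 64 x 24, voxel 0.9 x 0.9 x 2 mm, 6 ROI masks

cohort$geometry$frames$SN_R
#> Principal axis frame (253 points)
#>   centroid (mm): 9.97, -6.01, -11.97
#>   singular values: 57.87, 27.85, 22.11
#>   M-L axis: [ 0.905,  0.320, -0.280]
#>   A-P axis: [ 0.272, -0.942, -0.197]
#>   V-D axis: [ 0.327, -0.102,  0.940]

sf <- compute_spatial_function(cohort$volumes[[1]],
                               cohort$geometry$masks$SN_R,
                               cohort$geometry$frames$SN_R)
sf
#> Spatial function: SN (R), n = 7, ROI mean = 51.611
#>       [,1]   [,2]   [,3]   [,4]   [,5]   [,6]   [,7]
#> M-L 41.366 47.760 44.733 45.577 53.932 61.888 71.853
#> A-P 53.308 50.997 51.509 50.294 47.292 50.764 45.516
#> V-D 52.953 50.764 49.668 48.983 52.108 49.051 50.565

peak_segment(sf, "M-L")
#> [1] 7
```

The frame prints the SN's three labeled axes (the leading one is M-L here);
the spatial function is the 3 × 7 matrix of per-segment median
susceptibilities (arbitrary ppb-like units). For this subject the M-L
function rises toward segment 7 — iron concentrated laterally, which is
exactly the gradient the default generator imposes (peak segment 7,
amplitude 30). This subject's ROI mean (51.6) sits about 1.3 between-subject
SDs (33) below the healthy-control SN baseline of 95.63.

The whole pipeline (simulate → axes → gradients → compare → correlate)
runs off one directory:

```r
run_pipeline(cohort_config(), seed = 42, out_dir = "out/")
read.delim("out/compare_mean.tsv")   # adjusted GLM comparisons
read.delim("out/correlations.tsv")   # age-adjusted partial correlations, BH
```

or from the shell via `inst/cli/qsmgrad.R` (`simulate`, `axes`,
`gradients`, `compare`, `correlate`, `report` subcommands).

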