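---
title: "Mapping iron gradients along the principal axes of subcortical nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping iron gradients along the principal axes of subcortical nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmgrad)
```

## The measurement model

A quantitative susceptibility map (QSM) assigns each voxel a magnetic
susceptibility value; in deep gray nuclei this is dominated by
non-heme iron. `qsmgrad` takes reconstructed QSM volumes and integer ROI
label masks on a shared grid as its starting point — everything upstream
(phase processing, dipole inversion, registration, atlas definition) is out
of scope and assumed done. Susceptibility values are treated as abstract,
ppb-like units throughout: the analysis is invariant to a global affine
rescaling of the map, and no claim depends on the absolute scale.

The core object is the **spatial function**: for one subject, nucleus and
hemisphere, the vector of per-segment median susceptibilities along each of
the nucleus's three principal axes.

### Principal axes

Voxel indices are mapped to scanner millimetres through the NIfTI affine
before any geometry is computed. This matters because acquisition voxels
are anisotropic (0.9 × 0.9 × 2 mm by default here): a singular value
decomposition in index space would stretch the slice direction by 2/0.9 and
bias the axes toward the in-plane directions. Users comparing with an
index-space implementation can pass index coordinates explicitly.

Given the centred coordinate matrix, the right singular vectors form the
axis frame, ordered by singular value. Two conventions make frames
comparable across subjects:

* **Anatomical labeling.** Axes are matched to the cardinal directions
  lateral, posterior, dorsal by *global* maximum-cosine assignment — the
  best of the six permutations of axes onto labels — rather than by
  assuming the singular-value order maps onto a fixed label order. Nuclei
  differ in which anatomical direction is longest (the SN is longest
  medial-laterally, the striatal nuclei anterior-posteriorly), so a fixed
  mapping would silently mislabel one or the other. An exact tie between
  permutations is broken toward singular-value order and flagged.
* **Orientation.** Each labeled axis is sign-flipped to point
  medial→lateral, anterior→posterior, ventral→dorsal. "Lateral" depends on
  the hemisphere (+x for right, −x for left in RAS), so labeling takes the
  hemisphere as input. The payoff is that segment 1 is always the
  medial/anterior/ventral end, which makes statements like "the peak
  shifted laterally from segment 4 to segment 7" well defined and
  comparable across subjects and hemispheres.

Degenerate inputs are rejected, not guessed at: fewer than 4 voxels, or a
coordinate cloud of rank < 3 after centring (tolerance: singular value
below `1e-8` times the largest), raises an error naming the deficient
directions.

### Equidistant hyperplane segmentation

For the chosen axis, the two bounding hyperplanes pass through the extreme
projections and `n − 1` equally spaced parallel hyperplanes partition the
interval into `n` equidistant segments. A voxel with projection `p` falls
into segment `floor(n (p − pmin)/(pmax − pmin)) + 1`; the half-open
convention with the maximum closed into segment `n` guarantees an exact
partition (every voxel in exactly one segment). The default `n = 7`
balances spatial resolution against per-segment voxel counts for nuclei of
this size at this voxel size.

Masks smaller than `3 n` voxels are rejected at the spatial-function stage:
below roughly three voxels per segment a median is not a meaningful summary.
Interior segments can still be empty for sparse or slice-aligned masks; they
are permitted, carried as missing, and excluded segment-wise downstream
(available-case group averaging) rather than imputed.

### Medians, group averages, peaks

The per-segment summary is the median (even counts: midpoint of the central
pair — the conventional definition), chosen over the mean for robustness to
the heavy-tailed voxel noise of QSM reconstructions near vessels and
nucleus borders. Group-averaged functions are plain segment-wise means and
SDs of the per-subject functions; the covariate-adjusted comparison lives
in the statistics layer, not in the descriptive curves. Peaks are the
argmax per function; exact ties break toward the lower (more
medial/anterior/ventral) index and are flagged. Peak trajectories across
stages are reported with anatomical shift labels derived from the axis
(toward segment 1 on M-L = "medial shift", etc.).

## The clinical layer

* **Motor subtype**: ratio of the mean of the 11 UPDRS tremor items to the
  mean of the 5 PIGD items; TD when ≥ 1.15, PIGD when ≤ 0.9, intermediate
  in between (both thresholds inclusive on their own side). A zero PIGD
  mean with positive tremor yields ratio +∞, hence TD (limit-consistent);
  both means zero is unclassifiable and errors.
* **Stage**: early < 2 years, late > 6 years, middle otherwise — both
  boundary durations (exactly 2 or 6 years) fall in the middle stage, since
  the early and late definitions are strict inequalities.
* **Lateralization**: the more-affected side (MAS) is the hemisphere
  *contralateral* to the body side of first motor symptoms, because basal
  ganglia pathology is predominantly contralateral to the symptomatic side;
  for controls the dominant side (DS) is the hemisphere contralateral to
  the dominant hand. This hemisphere mapping is a convention of this
  package (the contralateral choice is the physiologically standard one)
  and is recorded in every output.

## The statistics layer

Group comparisons adjust for age, sex (coded 0/1) and levodopa-equivalent
daily dose, with the group factor treatment-coded against HC (or the
earliest stage). The omnibus group effect is the nested-model F (full vs
covariate-only); pairwise contrasts are t-tests on coefficient differences.
Bonferroni families are declared and written into the output: for mean-ROI
models, the 3 pairwise contrasts within an ROI × side; for segment-level
models, the `n = 7` segments within an ROI × side × axis. Users who prefer
a different family definition can re-correct from the raw p-values, which
are always reported alongside.

Descriptive two-group comparisons are routed by a per-group
Kolmogorov–Smirnov test against a normal with estimated moments (the
`lilliefors` option switches to the small-sample-corrected variant via
`nortest`); the route taken is recorded in the result, never silent.
Categorical tables use the uncorrected Pearson chi-square — validated
against both demographic-table p-values it must reproduce (0.083 and
0.858), which the Yates-corrected statistic does not.

Partial correlations use the residual method (Pearson correlation of the
residuals of each variable regressed on the covariates), with
`t = r sqrt((n − 2 − k)/(1 − r²))` on `n − 2 − k` degrees of freedom, and
Benjamini–Hochberg correction across each subtype's ROI × score grid.
Missing data are handled by listwise deletion with a logged count.

## What the synthetic generator emulates — and what it does not

The generator exists so that every downstream stage is testable without
patient data. Its defaults *are* the study conditions the package targets:

| parameter | default | rationale |
|---|---|---|
| group sizes | 47 HC / 55 PIGD / 53 TD | the cohort design |
| stage sizes | 11/28/16 (PIGD), 12/26/15 (TD) | the stage stratification |
| grid / voxel | 64 × 64 × 24 at 0.9 × 0.9 × 2 mm | acquisition voxel size |
| baselines (MAS, LAS) | SN 95.63/87.81, putamen 39.17/34.88, caudate 28.06/27.09 | healthy-control regional means |
| between-subject SD | SN 33, putamen 20, caudate 14 | healthy-control regional SDs |
| voxel noise SD | 10 | sub-subject-level measurement noise |
| gradient amplitude | SN 30 (M-L, peak 7), putamen 20 (A-P, peak 6), caudate 15 (A-P, peak 2) | lateral nigral / posterior putaminal / anterior caudate iron concentration |
| stage offsets | PIGD +25/+25/−25, TD +25/−25/+25 | inverted-U and S-shaped temporal presets, ~0.75 SN subject SD |
| ages | Normal(65, 7²) | cohort demographics |

Design notes:

* **Nucleus geometry is idealised**: rotated ellipsoids, mirrored across
  the mid-sagittal plane, placed with mild obliquity so that no principal
  axis is locked to the slice direction (a thin axis exactly aligned with
  2 mm slices would sample only 3–4 discrete planes and leave interior
  segments empty). The pipeline's mathematics depends only on distinct
  principal axes, not on anatomical shape.
* **The gradient profile** is a Gaussian bump along the designated axis,
  centred at the configured peak segment (width: 1.2 segment widths). The
  published quantity is the segment-wise median profile, which constrains
  only peak position and unimodality; a Gaussian is the smoothest profile
  with a directly testable peak. The bump is **centred to zero mean over
  the ROI**, so the configured baseline remains the exact ROI mean — level
  and shape are decoupled, and with zero noise and zero amplitude every
  ROI mean equals its configured baseline exactly.
* **Temporal patterns** are additive stage offsets per subtype (the
  magnitudes are configurable; the published shapes are qualitative). The
  stage-varying gradient-peak presets (`preset_sn_ml_trajectory`) move the
  nigral M-L peak 4→7→4 (PIGD) or 7→4→7 (TD) across stages.
* **Clinical couplings** draw a score as `r·z + sqrt(1 − r²)·ε` against the
  within-group z-scored lateralized regional iron level, so the population
  correlation equals the configured `r` before rounding/clipping to the
  score's ordinal range. Tremor/PIGD items are drawn so the ratio rule
  reproduces the configured subtype *exactly* (a cap-aware integer fix-up
  loop guarantees it, item scores bounded at 4). LEDD is log-normal with a
  point mass at zero for untreated TD patients; ordinal scores are rounded
  and clipped.

What it does **not** emulate: MRI physics (phase, dipole fields,
streaking), reconstruction artefacts, registration error, anatomical shape
variation, partial-volume effects at nucleus borders, or the
cerebellar-thalamo-cortical tremor circuit. Passing tests therefore show
that the pipeline recovers structure *of the kind the generator produces* —
peak positions, temporal sign patterns, calibrated correlations — at
realistic noise levels and sample sizes; they do not validate QSM
reconstruction or segmentation quality on real data.

## Numerical choices

* Axis signs before labeling are fixed deterministically
  (largest-magnitude component positive), so frames are bitwise
  reproducible; SVD itself is deterministic.
* The segment formula never compares against accumulated boundary
  positions, avoiding cumulative floating-point drift; the maximum
  projection is closed into segment `n` explicitly.
* A response that the covariate-only model already fits exactly yields
  F = 0, p = 1 (rather than 0/0), and degenerate zero-signal contrasts
  report t = 0.
* Configuration provenance is YAML with 17-digit precision; regeneration
  from a provenance file is bit-identical, and every output table carries
  an MD5 hash of the canonical-JSON config.

## Validation problem sizes

The test suite validates against independent oracles (eigen-decomposition
of the coordinate covariance; `cut()`-based equal-width binning; sort-based
medians; normal-equation GLM and explicit-F formulas; textbook
Benjamini–Hochberg step-up) on: 500 random masks for segment assignment,
100 random rotated ellipsoids (semi-axis ratio ≥ 2, 1 mm grid) for axis
recovery within 3°, 200 simulated volumes for gradient-peak recovery under
the default noise regime, 200 Monte-Carlo replicates for the null
calibration of the adjusted stage comparison, 100 cohort replicates per
temporal preset for sign-pattern recovery, and 100 replicates for
partial-correlation recovery at the PIGD group size (n = 55). These sizes
were chosen to give binomial confidence intervals tight enough to be
informative while keeping the default test run fast.

## Limitations

* The ellipsoid phantom cannot probe labeling robustness for nuclei whose
  principal axes are genuinely ambiguous (near-spherical shapes); the tie
  flag exists for that case but real-data behaviour is untested here.
* Group-averaged spatial functions are unadjusted means; covariate
  adjustment happens only in the GLM layer, so descriptive curves and
  adjusted inferences can disagree when covariates are imbalanced.
* The generator's voxel noise is i.i.d. Gaussian; real QSM noise is
  spatially correlated, which would widen the effective confidence
  intervals of per-segment medians relative to what the recovery rates
  here suggest.
* With 2 mm slices the SN spans few planes; per-segment counts on its
  shorter axes are small (~15–20 voxels), and results for the thinnest
  axis of small nuclei should be read with that in mind.
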