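---
title: "The B-score shape-space method and the synthetic paired-knee trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The B-score shape-space method and the synthetic paired-knee trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bshape)
```

## The model

Osteoarthritic (OA) femoral bone shape change is gradual, directional and
continuous: condyles broaden and flatten, and osteophytes grow along the rim
of the cartilage plate. The B-score summarizes a whole femoral surface as a
single number measuring how far along that pathological direction the bone
sits.

The construction has four stages, each a function in this package:

1. **Correspondence and alignment.** Every bone surface is a
   `corresponded_shape`: an ordered vertex list (mm) sharing one
   triangulation (`tri_topology`) with every other shape, so that vertex
   *i* is the same anatomical location on every bone.
   `generalized_procrustes()` rigidly aligns the training set to an evolving
   consensus (rotation + translation only, convergence when the consensus
   moves less than 1e-7 mm RMS, at most 100 iterations).
2. **Shape space.** `fit_shape_model()` performs PCA on the aligned,
   flattened vertex coordinates, retaining the smallest number of leading
   modes reaching `variance_retained` (default 0.98) of total variance.
3. **OA vector.** `fit_oa_vector()` draws the line through the mean
   shape-space coordinates of a non-OA and an OA population:
   `direction = (mean_OA - mean_nonOA) / ||.||`, pooled across sex.
4. **Standardized projection.** `bscore_of()` projects a shape's
   coordinates orthogonally onto that line and standardizes per sex:
   B = (proj − origin_sex) / scale_sex, with origin_sex the mean and
   scale_sex the (n−1) SD of the non-OA projections of that sex. By
   construction the non-OA training group has per-sex B-score mean 0 and
   SD 1, and B is invariant both to rigid motion of the input and to any
   shape component orthogonal to the OA vector.

`local_area_change()` renders the geometry of progression: it reconstructs
the model shape at two B-scores along the vector and reports each
corresponded triangle's percent area change (cross-product areas), the
per-triangle heat map familiar from OA shape-change figures.

### Design choices that were genuinely open

* **Rigid, not similarity, alignment.** OA progression includes genuine
  size increase (osteophyte growth enlarges rim triangles), so scale is
  signal, not nuisance. Similarity alignment remains available
  (`procrustes_align(..., scale = TRUE)`, `alignment_scaling` in the run
  config) for sensitivity analyses.
* **One pooled OA-vector direction, per-sex origin and unit.** The origin
  and unit are explicitly per-sex (sex shifts femur size); the direction is
  fitted on both sexes pooled so there is a single line through the two
  population means. Fitting fully per-sex vectors is possible by calling
  `fit_oa_vector()` on each sex's rows.
* **Truncated shape space.** B-scores are computed in the retained-mode
  space so that training and application use one representation;
  `variance_retained = 1` recovers the full-rank computation.
* **Mode sign convention.** Eigenvector signs are fixed by making the first
  component of each mode larger than 1e-9 in magnitude positive, so
  repeated fits are bit-reproducible.
* **Degenerate inputs.** Coincident-vertex shapes cannot be aligned
  (error); identical training shapes yield a zero-mode model; a zero-spread
  non-OA group is a degenerate-scale error rather than an infinite B-score;
  a zero-area triangle at the reference end of an area-change map is an
  error naming the triangle.

## Longitudinal metrics

`sdd()` implements the Bland-Altman smallest detectable difference: 1.96
times the SD of test-retest differences (the 95% limit of agreement).
`knee_slope()` is the per-annum OLS slope of a knee's B-score series.
`classify_progressor()` labels a knee a progressor when its projected
change over a 4-year horizon strictly exceeds 95% of the SDD
(`slope * 4 > 0.95 * sdd`). The 0.95 factor reads "95% of the SDD"
literally; setting `threshold_factor = 1` gives the alternative reading in
which the SDD, already a 95% limit, is itself the threshold. Only positive
(worsening) change classifies as progression by default; `direction =
"absolute"` classifies on magnitude.

## Trial statistics

The paired design treats one knee per subject (index) and uses the
contralateral placebo knee as its internal control. `paired_t()` compares
the two arms' changes from baseline within subject (difference reported as
control − index, positive favouring treatment); ICRS-grade subgroups, whose
index and control knees need not come from the same subjects, use Welch's
unpaired test (`welch_t()`; pooled-variance optional). `pearson_ci()`
reports product-moment correlations with t-based two-sided p-values and
Fisher-z 95% CIs. `quartile_stratify()` ranks index knees by B-score change
(ties broken by subject id; quartile sizes differ by at most one; Q1 = most
negative, i.e. most improved, with each quartile's change range printed in
the output so the ordering is explicit) and summarizes regional cartilage
thickness change per quartile as mean ± SEM. Missing values are handled by
pairwise deletion per analysis, so each table reports its own n. No
multiple-testing correction is applied; raw two-sided p-values are reported
at α = 0.05.

All-zero paired differences are reported as t = 0, p = 1 (no detectable
difference); zero difference variance with a nonzero mean is an error,
since the t statistic is undefined.

## What the synthetic generator emulates

No subject-level data accompany the published analysis, so
`generator_config()` fixes a synthetic study with the published summary
statistics as its truth:

| quantity | default | source of the value |
|---|---|---|
| subjects (bilateral pairs) | 78 | analyzed cohort size |
| QC counts | 93 → 78 | screening/analysis counts (84% retention) |
| baseline B-score mean | 1.48 | printed baseline mean, both arms |
| baseline B-score SD | 2.0 | matched to the printed baseline histogram spread |
| within-subject baseline correlation | 0.85 | bilateral knees of one person are highly similar |
| index mean change 6/12 m | 0.0298 / 0.0856 | printed per-arm means |
| control mean change 6/12 m | 0.1246 / 0.1969 | printed per-arm means |
| change SD | 0.30 | back-derived: printed 95% CI half-widths ≈ 0.06–0.07 at n = 78 |
| change correlation across knees | 0.3 | back-derived from the printed paired p-values (0.02/0.01) |
| temporal correlation 6 m → 12 m | 0.7 | within-knee consistency; 12 m change = 6 m change + increment |
| thickness–B-score change correlation (index, 12 m) | −0.303/−0.329/−0.296/−0.320 (entire/medial FC, entire/medial TF), 0 lateral | printed index-knee correlation table |
| control-knee thickness correlations | 0 | printed control-knee table is null throughout |
| reference slopes | 0.04 / 0.24 per annum | historical non-progressor/progressor slopes |
| retest noise SD | 0.26 | sets SDD ≈ 0.51 so a 0.24/yr knee crosses 95% of the SDD over 4 years and a 0.04/yr knee does not |

The publication reports confidence intervals and p-values, not SDs or
correlations, so every SD/correlation above is a back-derived assumption,
not a published fact; they are config fields precisely so that sensitivity
to them can be explored. The 6-month thickness correlations are the
12-month ones scaled by 0.65, the approximate printed 6 m/12 m ratio.

ICRS grades are assigned by thresholding baseline latent B-score plus
Normal(0, 0.5) grading noise at cut points (−0.08, 1.09, 2.30) chosen to
reproduce the published grade proportions (roughly 22/20/23/35% for grades
0/2/3/4; grade 1 does not occur in the trial's grading of these knees).
This is a generative convenience: the publication documents only the
observed gradient of baseline B-score across grades, which the thresholds
reproduce qualitatively.

At the shape level, `make_template()` builds a closed bilobed ellipsoid
(semi-axes 32/26/22 mm) standing in for the femoral condyle surface, with
rim weights peaking along an equatorial band that plays the cartilage-plate
edge. `deform_to_bscore()` displaces vertices outward along normals by
`latent_b × 0.4 mm × profile`, where the profile is the squared rim weight
(osteophyte-like rim concentration) plus a 0.2 uniform term (central
flattening/broadening), plus i.i.d. Gaussian vertex noise (0.1 mm). Male
templates are 6% larger, making sex a real confounder that the per-sex
origin/unit must absorb. Non-OA training shapes sit at latent B ~ N(0, 1),
OA shapes at N(3, 1) truncated below 1.5.

**What passing tests do and do not show.** The generator produces exactly
the correlation and mean structure the analysis assumes: a linear
deformation family, Gaussian noise, no segmentation failures, no scanner
drift, no real anatomy. Tests therefore demonstrate that the pipeline
measures faithfully *when its model assumptions hold* — parameter recovery,
invariances, calibration — not that it would segment or score clinical MRI
correctly. Score-level cohort B-scores equal the latent values: the
`change_sd` calibration came from printed CIs that already include
measurement noise, so adding noise again would double-count it.

## Problem sizes and numerics

Default study sizes are the published ones (78 subjects, 2 knees, 3
timepoints). Shape-level runs default to a 500-vertex template and a
60-shape training set, which keeps a full simulate → align → PCA → OA
vector → score → analyze cycle around a second on one CPU while leaving
measured-vs-latent calibration at R² > 0.9; these sizes are config fields.
Monte-Carlo checks use 200 replicate cohorts (recovery of the calibrated
means), 500 knees (slope recovery), 2,000 null datasets (correlation
p-value calibration). GPA converges at 1e-7 mm RMS; orthonormality and
standardization invariants hold to 1e-8; rigid-motion invariance of
B-scores to 1e-6.

## Known limitations

* The condyle template is a schematic surface; no claim of anatomical
  realism is made, and mesh-level results (e.g. area-change maps) are
  qualitative illustrations of the method.
* The OA deformation family is exactly one-dimensional plus noise, so the
  shape space recovers it easily; real training sets mix many directions
  of variation.
* Appearance (image texture) modelling, image search/segmentation, and
  cartilage thickness measurement from images are entirely out of scope;
  thickness enters only as simulated scalars.
* The generator draws missing-data-free cohorts by default; the analysis
  functions tolerate missingness (pairwise deletion, per-table n) and are
  tested with it, but missingness rates are not part of the calibration.
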