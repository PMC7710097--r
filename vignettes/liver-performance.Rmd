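---
title: "Pre-operative liver performance analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-operative liver performance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverplanr)
```

## The problem

When liver resection is planned for primary or metastatic cancer, the care
team must judge whether the liver that remains — the future liver remnant
(FLR) — will be large enough and healthy enough to carry the patient
through recovery. FLR volume alone ignores parenchymal quality:
fibroinflammation, measurable non-invasively as an elevated iron-corrected
T1 relaxation time (cT1, ms), and steatosis, measurable as proton density
fat fraction (PDFF, %), both degrade the functional reserve per
millilitre. `liverplanr` implements the full quantitative chain from a
delineated liver mask to a composite pre-operative risk score and its
statistical evaluation, and ships analytic phantoms plus a synthetic
cohort generator so every stage is testable without clinical data.

## Geometry: Couinaud segmentation and virtual hepatectomy

The liver is divided into eight functionally independent Couinaud segments
by planes derived from nine anatomical landmarks (`build_planes()`):

* the IVC axis is the unit vector from the inferior to the superior vena
  cava landmark;
* each hepatic-vein plane contains the IVC axis and its vein landmark;
* the portal plane passes through the midpoint of the left/right portal
  branches with the IVC axis as its normal;
* the umbilical plane passes through the umbilical fissure, spanned by the
  IVC axis and the direction to the gallbladder fossa.

`label_segments()` classifies every foreground voxel (at its centre, in
scanner mm) by signed half-space tests: right of the right-hepatic-vein
plane gives segments 7/6 (superior/inferior of the portal plane), between
the right and middle vein planes 8/5, between the middle vein and
umbilical planes 4 (4a/4b merged — nothing downstream distinguishes
them), left of the umbilical plane 2/3. Sidedness is anchored to
landmarks (the right portal branch for the right-sided planes, the left
hepatic vein for the umbilical plane), which makes the rule
patient-independent; a voxel exactly on a plane goes to the anchor side,
which makes it deterministic. The caudate lobe (segment 1) has no
plane-based definition from these landmarks, so it is modelled as a
configurable cylinder (default radius 15 mm) around the IVC axis on the
posterior side of the middle-vein plane; it can be disabled and the FLR
arithmetic still partitions. Published segmentation guidelines admit
curved, vein-tracking inter-segmental surfaces; planes are a deliberate
simplification and the phantom oracles quantify exactly what it costs.

A resection plan (`resection_plan()`) removes whole segments and/or
atypical wedges. A wedge (`wedge_mask()`) is a conical frustrum along the
access axis from a surface entry point to the tumour: the deep face is
the tumour's bounding disc dilated by the resection margin (default
10 mm), the frustrum widens toward the surface with a fixed half-angle
(default 15°, configurable — the source material fixes the shape but not
the angle), and the result is unioned with the margin-dilated tumour and
clipped to the liver. When no entry point is given the closest surface
point to the tumour centroid is used (direct-access convention).

`apply_plan()` reports `FLR% = 100 × remnant parenchyma / total
parenchyma`, with tumour voxels excluded from numerator and denominator:
tumour tissue contributes no function, so the FLR is a parenchymal
fraction. This denominator convention is a design choice (the source does
not state one); it only matters when lesions are large. The "at least 10%
of the liver removed" eligibility filter used by the statistics is
inclusive at the boundary (an FLR of exactly 90% qualifies), implemented
with a small numeric tolerance so the boundary case is not lost to
floating point.

## Field-of-view rule

Cases in which more than 5% of the liver lies outside the imaging field
of view are excluded (strictly "more than": an estimated fraction of
exactly 0.05 is kept). How that fraction was measured is not specified in
the source, so an estimator had to be chosen. A convex-hull closure was
considered and rejected: for a convex organ clipped by a grid face, the
hull of the observed voxels *is* the observed region, so the estimate
would be identically zero. Instead `check_fov_coverage()` fits a
least-squares quadric (ellipsoid) to the interior boundary surface of the
mask (voxels on clipped faces excluded), inflates the fitted semi-axes by
half a voxel (boundary voxel centres sit on average half a voxel inside
the true surface), and reports `1 − observed/fitted` volume. On clipped
ellipsoid phantoms the estimate is accurate to well under one percentage
point; for strongly non-ellipsoidal organs it degrades gracefully to a
surface-share fallback.

## Quantitative map summaries

`region_summary()` reports median, IQR and mean of a cT1/PDFF/T2* map
over a region after excluding lesion masks. Multi-slice maps on a
different grid are matched by nearest-neighbour lookup in scanner mm (the
source overlays maps on 3D volumes without stating the method; nearest
neighbour is the choice that never invents values). The patient-level
liver cT1 is the median over whole-liver parenchyma excluding lesions;
whether the original analysis used whole-liver or FLR-restricted
summaries is unstated, so the region is an argument, not a constant. The
upper limit of normal for cT1 is 795 ms, strict (`classify_ct1()`).

## Scores

Daily post-operative liver dysfunction is scored as
`2.5·INR + 17.1·bilirubin(mg/dL) + 88.4·creatinine(mg/dL)`
(`modified_hp_daily()`), summed over post-operative days 1–5
(`modified_hp_sum()`). Bloods reported in SI units are converted with the
standard factors 17.1 (bilirubin) and 88.4 (creatinine) — numerically the
same constants as the weights, so in SI units the daily score is
`2.5·INR + bilirubin(µmol/L) + creatinine(µmol/L)`; this coincidence is
documented, not exploited. Missing late days (early discharge) are
imputed by carrying the previous day forward (`impute_carry_forward()`);
a missing day 1 is an error unless a pre-operative fallback is explicitly
enabled, because the imputation rule is defined for post-operative gaps
only. The day-3 score (`hp_day3()`) additionally weights the maximum
Clavien-Dindo grade; that weight is published elsewhere and is not
restated here, so it is a required configuration value with no default,
and scores above 9 (strict) are flagged.

The composite pre-operative risk score is

  score = exp(−(1.24 + ln(FLR%)·(−2.26) + cT1·0.013))

(`hepatica_score()`), increasing in FLR and decreasing in cT1, with lower
values indicating higher risk. The log is natural and FLR enters in
percent; the printed formula states neither, and this reading is the one
under which the published coefficient signs reproduce the published risk
direction. The coefficients are overridable for refitting.

Outcome labelling (`outcome_label()`) supports the two published rules: a
strict threshold (sum > 22) and the strict upper quartile
(linear-interpolation 75th percentile). Note an incongruity carried over
from the source: on physiological bloods the 5-day sum of the printed
daily formula is in the hundreds, so the ">22" rule flags every patient;
both rules are implemented exactly as printed, and the pipeline defaults
to the upper-quartile rule, the one against which the composite score's
ROC is defined.

Achieved regeneration (`regeneration_score()`) is reported under two
published definitions that are not equivalent: pre-operative volume
divided by follow-up volume (default), and the fraction of the resected
volume regained, `(followup − (preop − resected))/resected`. Neither is
asserted to be the source's sole intent; both are first-class.

## Statistics

`stepwise_logistic_aic()` performs bidirectional stepwise selection by
AIC from the intercept-only logistic model over nine pre-operative
candidates (age, BMI, creatinine, bilirubin, liver volume, lesion volume,
ln FLR%, PDFF, cT1); "stepwise" direction was not specified in the
source, and bidirectional-from-null is the common, deterministic choice.
FLR enters on the natural-log scale, matching the composite score's term.
Perfect separation is flagged, not fatal. `auroc()` computes the
Mann-Whitney area (ties counting 1/2) with DeLong variance and a
logit-scale Wald CI; `delong_test()` compares two correlated ROC curves
and returns z = 0, p = 1 exactly for rank-equivalent scores;
`youden_threshold()` maximises sensitivity + specificity − 1 with ties
broken toward higher specificity. `collinearity_check()` reports
variance-inflation factors (flag at 10). `rank_sum_test()` enumerates the
exact null distribution for small samples and otherwise uses a
tie-corrected normal approximation with continuity correction;
`spearman_cor()` uses the t approximation.

## The synthetic world

`synthetic_cohort()` draws FLR from a logit-normal and cT1/PDFF/bilirubin
from log-normals, each matched to the reported cohort median and IQR
(FLR 82.8% [61.0–94.6], cT1 722.5 ms [689.2–772.5], PDFF 3.9% [2.5–8.0],
bilirubin 10 µmol/L [8–19], age 64 [56–72], 97:46 male:female). These
families are chosen to respect the supports (FLR bounded by 100%, cT1
positive); only medians and IQRs were reported, so the σ is set from the
quartile spread. The poor-outcome flag is Bernoulli with
`logit p = 1.24 − 2.26·ln(FLR%) + 0.013·cT1` — the published composite's
coefficients taken at face value (which implies a high marginal event
rate at the cohort medians; that is what the printed formula says).
Five-day blood trajectories rise multiplicatively over the pre-operative
baseline with an amplitude increasing in the outcome risk and a
log-normal noise term (default σ 0.15), so the 5-day score sum's upper
quartile aligns with the high-risk tail; early discharge truncates the
series from a random day in 3–5 with probability `missing_day_prob`
(default 0.2). Follow-up volumes regain a logistic-in-composite-score
fraction of the resected volume; length of stay is log-normal around 5
days with a ×1.3 multiplier for cT1 > 795 ms (reported medians 5 vs 6.5);
histology grades are thresholded latents tied to cT1 (ballooning,
inflammation, fibrosis stage) and PDFF (steatosis). Everything is
reproducible bit-for-bit from one seed.

What the generator does **not** emulate: real MRI texture and
segmentation error, correlated comorbidity structure, chemotherapy
injury, or any site effect. A green test therefore establishes that the
implementation computes the stated quantities correctly and that the
statistical machinery recovers known structure — not that the clinical
effect sizes are externally valid.

The analytic phantom (`make_phantom()`) voxelises a sphere or spheroid
and places the landmarks so the cutting planes form a fixed fan through
the vena-cava axis (right-vein plane at azimuth 90°, middle-vein 120°,
umbilical 60°, portal plane at a chosen height). These angles are chosen
so every segment is non-empty and — deliberately — so no plane contains a
whole lattice sheet of voxel centres (a 45° plane on an isotropic grid
does, which makes voxel-centre counting degenerate at the boundary). The
per-segment volumes have closed forms (azimuthal sectors of spherical
caps, minus the caudate cylinder-sphere intersection), which is the
independent oracle the geometry tests and acceptance criteria use; at
1 mm voxels the voxelised volumes agree with the closed forms to within
2%, the caudate cylinder being the worst case (~1.3%).

## Numerical choices

* Half-space tests use a −1e−9 mm tolerance so that "exactly on the
  plane" is assigned to the anchor side under floating point.
* Eligibility boundaries (≥10% resected) use a 1e−12 tolerance so the
  exactly-90% FLR case is included.
* Quantiles are type-7 (linear interpolation) everywhere.
* The NIfTI writer stores masks/label maps as integers and quantitative
  maps as float64; the affine goes to the sform. The reader accepts
  uint8/int16/int32/float32/float64, either endianness, `.nii` or
  `.nii.gz`, and applies `scl_slope`/`scl_inter`.
* DeLong comparisons with zero variance error out, except the exact
  equal-AUC case, which is reported as z = 0, p = 1.

## A worked example

```{r example}
ph <- make_phantom(radii_mm = 50, spacing_mm = 2)
labels <- label_segments(ph$liver, build_planes(ph$landmarks))
res <- apply_plan(ph$liver, labels,
                  plan = resection_plan(c(5, 6, 7, 8)))
round(res$flr_percent, 1)

co <- synthetic_cohort(200, seed = 1)
panel <- score_panel(co$cohort)
summary(panel$mhp_sum)
round(hepatica_score(82.8, 722.5), 3)
```

## Known limitations

Plane-based inter-segmental boundaries (no vein tracking); a cylindrical
caudate; no image registration between pre- and post-operative scans; no
DICOM ingestion; the composite's coefficients are consumed as published,
not externally validated; and the ">22" outcome rule is kept verbatim
despite the unit incongruity described above.
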