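---
title: "Methods: phenotype analysis and mosaicism estimation in CdLS cohorts"
author: "cdlsmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype analysis and mosaicism estimation in CdLS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdlsmosaic)
```

## The problem

Cornelia de Lange syndrome (CdLS) is a cohesin-pathway disorder diagnosed
largely on facial gestalt, growth failure and intellectual disability.
Causative mutations — chiefly in *NIPBL*, with smaller contributions from
*SMC1A*, *SMC3*, *HDAC8* and *RAD21* — are found in only a fraction of
referred cases, and an important reason is somatic mosaicism: a mutation
present in too small a fraction of blood-derived cells to be detected by
standard sequencing. This package implements the computational side of a
cohort analysis aimed at that problem:

1. **Gestalt scores** — aggregate per-rater facial typicality ratings and
   check that raters agree before the scores are used.
2. **Yield summaries** — per-gene mutation counts as percentages of the
   screened cohort.
3. **Classification trees** — recursive partitioning of growth, severity
   and gestalt features over the mutation-positive cases, yielding a
   two-threshold growth rule ("NIPBL-like" filter) that is then applied to
   the mutation-negative group to estimate how many probable undetected
   (mosaic) *NIPBL* cases it contains.
4. **Average faces** — landmark-based composite photographs per genetic
   subgroup, the visual counterpart of the same argument.
5. **Mosaic quantification** — variant-allele-fraction (VAF) estimates with
   confidence intervals from read counts, and comparisons across tissues
   and timepoints.

Patient-level data are not distributable, so the package ships a synthetic
cohort and face generator with the statistical structure the analysis
assumes; every stage is exercised end-to-end on synthetic data.

## Reporting conventions

Cohort percentages are reported **truncated toward zero** at the stated
precision (`percent_truncated()`): 44/56 prints as 78%, 6/163 as 3.6%.
Truncation, not rounding, is the single convention consistent with every
percentage this analysis is expected to print, and it is computed in exact
integer arithmetic so floating-point rounding can never move a value across
a truncation boundary.

Severity scores categorise as mild below 15, moderate from 15 to 22
inclusive, and severe above 22 (`categorize_severity()`). Both boundary
values are moderate.

## Gestalt aggregation and concordance

Raters score a frontal photograph from 1 (highly atypical) to 10 (highly
typical). The per-patient score used downstream is the arithmetic mean of
available ratings; missing ratings are simply dropped (no imputation).
Inter-rater agreement is summarised by pairwise Pearson correlation on
pairwise-complete observations, gated at r >= 0.60. The correlation test's
p-value is reported for reference but does not enter the gate: it depends
on the number of shared photographs, which varies between runs and between
cohorts, whereas the correlation itself is the quantity of interest.

## Classification trees

`fit_tree()` is a from-scratch CART-style learner: greedy binary splits
maximising Gini impurity decrease, with the defaults `minsplit = 3` and
`maxdepth = 3` that suit a small, strongly structured clinical cohort.
Specific, deliberately pinned-down semantics:

* Candidate thresholds are midpoints between consecutive distinct observed
  feature values.
* A record goes left when strictly below the threshold, right otherwise —
  ties at the threshold go right, matching the ">= -4.4 SD" phrasing of the
  growth filter the tree analysis produces.
* Equal-gain ties resolve to the lowest feature index, then the smallest
  threshold, so fitting is deterministic.
* Missing split-feature values are excluded from the subtree by default
  (mirroring complete-case reporting); a majority-branch policy is
  available. No surrogate splits and no pruning: the target is a single
  shallow, interpretable tree, not a tuned classifier.
* The impurity gain of a candidate split is computed on the records with an
  observed feature value and scaled by the observed fraction at the node,
  so features with heavy missingness are penalised.

The depth-1 fit is verified against an exhaustive search over every
(feature, midpoint) pair on 100 random small datasets, and the depth-2 fit
against planted two-feature AND-structure whose thresholds are known by
construction.

The published NIPBL-like rule itself — weight below -2.4 SD **and** birth
weight at or above -4.4 SD — is kept as explicit defaults in
`nipbl_like_filter()` rather than re-fitted, because the tree it came from
cannot be reproduced without the patient-level data. Records missing either
growth value are never flagged but stay in the denominator, so the reported
fraction is a lower bound.

## Average faces

`build_average_face()` composes four stages, each exposed on its own:

1. **Generalized Procrustes analysis** (`generalized_procrustes()`):
   iterative similarity alignment (translation, isotropic scale, rotation —
   reflections disallowed, since a reflection would mirror a face) to a
   common mean, initialised from the first constellation, iterated until
   the mean moves less than 1e-7 RMS or 100 iterations. Scaling is fitted
   because photographs differ in magnification.
2. **Reference frame**: the unit-size mean shape is rotated onto the
   package's canonical upright 36-point template and placed so its bounding
   box fills 80% of the raster. Orientation canonicalisation makes the
   whole pipeline invariant to a tilt, scale or shift shared by every input
   photograph; without it the average would inherit any systematic camera
   tilt.
3. **Delaunay mesh** (`delaunay_mesh()`): Bowyer–Watson triangulation of
   the mean constellation, validated against a brute-force
   empty-circumcircle check. Co-circular quadruples (where the diagonal is
   not unique) resolve deterministically by insertion order.
4. **Piecewise affine warping and averaging**
   (`piecewise_affine_warp()`, `average_appearance()`): each target pixel
   centre inside the mesh hull is mapped through its triangle's affine map
   (barycentric transfer) and sampled bilinearly from the source
   photograph; pixels on shared edges go to the first containing triangle
   in mesh order. Warped appearances are averaged pixel-wise with a
   per-pixel coverage count. Pixels outside the landmark hull (hair,
   background) are excluded from averaging — hull-exterior appearance is
   not landmark-controlled, so averaging it would be meaningless; the
   coverage map records exactly what was averaged.

Bilinear sampling clamps out-of-bounds source locations to the nearest
edge pixel. Colour images are averaged per channel after identical
geometric treatment.

## Mosaic quantification

`quantify_vaf()` reports VAF = alt/total with a **Wilson score interval**
(95% by default). The Wilson interval is used instead of the Wald interval
because mosaic variants live at small alternate-read counts, where the Wald
interval degenerates; its empirical coverage is checked by simulation at
true fractions 0.05, 0.15 and 0.5 with n of 50 and 200. `flag_mosaic()`
formalises the qualitative judgement "15% of reads implies mosaicism": a
sample is consistent-with-mosaic when its whole interval lies below
0.5 - margin, consistent-with-heterozygous when the interval covers the
band [0.5 - margin, 0.5 + margin], and indeterminate otherwise, with a
default margin of 0.05. Pyrosequencing allele-quantification output, which
arrives as a percentage rather than counts, enters through
`quantify_from_percent()` with a stated effective n.

## The synthetic generators

**Cohort** (`generate_cohort()`): group sizes default to the screened-cohort
composition (46 *NIPBL*, 5 *SMC1A*, 5 *SMC3*, 6 *HDAC8*, 1 *RAD21*,
3 *ANKRD11*, 2 CNV, 95 negative; 163 in all). Group means encode the
qualitative genotype–phenotype structure: *NIPBL* shows progressive growth
failure (birth weight mean -2.3 SD, postnatal weight -3.4 SD), high
severity (mean 24) and the most typical gestalt (latent mean 8); *SMC1A*
shows postnatal weight normalisation; *ANKRD11* a normal head
circumference; the mutation-negative group is intermediate and
heterogeneous (SD 1.5 against ~1.0 elsewhere). SDs near one z-unit are
realistic for clinical growth data. Rater scores are the latent gestalt
value plus independent Gaussian noise (SD 1), rounded to the integer 1–10
scale and clipped; with latent SD ~1.2–1.8 this puts expected inter-rater
correlations near the 0.6–0.8 range the concordance gate anticipates.
Missingness is independent per field (20% birth weight, 5% weight, 10%
height/OFC/severity, 15% per rating — birth measurements are the most
often unavailable in referral cohorts). Values are rounded to one decimal,
the precision of clinical records.

**Faces** (`generate_faces()`): each face is the canonical 36-point
template plus a per-group mean offset plus per-individual landmark noise
(default SD 2 px at 128 px), then a random similarity transform (rotation
±0.1 rad, scale ±8%, translation ±4% of the frame) applied to the
landmarks, with the face rendered directly at the transformed landmarks so
image and constellation are exactly consistent. Rendering draws smooth
shaded regions (skin polygon, brow/nose strokes, eye and mouth polygons,
philtrum ridges) softened by a Gaussian blur of ~1% of the image width,
with a global illumination jitter of ±5%. The default "NIPBL" offset
lengthens the philtrum and thins the upper lip — the gestalt features the
composite-face comparison turns on.

The annotation scheme (which of the 36 indexes is which facial feature) is
fixed and documented in `face_template()`; it is an explicit stand-in, not
a reconstruction of any published scheme.

What the generators do **not** emulate: photographic texture (skin, hair,
lighting geometry), perspective and out-of-plane pose, landmark annotation
error correlated with image quality, rater bias and drift, and any
correlation between facial shape and the growth variables. Passing tests
therefore demonstrate the correctness of the machinery under the stated
statistical model, not clinical performance on photographs.

## Numerical choices

* Truncated percentages use integer floor-division; counts are far below
  2^53, so the arithmetic is exact.
* Procrustes alignment is the closed-form SVD solution with the smaller
  singular direction sign-constrained (determinant +1, no reflections);
  constellations whose points are collinear to within 1e-10 relative
  tolerance are rejected.
* The Bowyer–Watson incircle test uses a relative tolerance of 1e-10 on
  the squared-radius scale; degenerate slivers (area below 1e-12 of the
  squared span) are dropped.
* Triangle membership at pixel centres accepts barycentric coordinates
  down to -1e-9, so pixels on shared edges are claimed exactly once by the
  first triangle in mesh order.
* The pipeline derives fixed per-stage seeds from the single global seed,
  so disabling one stage leaves every other stage's draws unchanged, and
  two runs with the same config and seed are byte-identical.

## Problem sizes in the shipped tests

The test-suite simulations use the sizes at which the checked properties
are already sharp: 50 constellations for mean-shape recovery (noise SD
2 px gives a predicted mean-shape error near 0.4 px against the 0.5 px
bound), 100 random datasets for the exhaustive-split comparison, 60 records
per arm for planted-threshold recovery, 10,000 binomial replicates per
condition for Wilson coverage, and 256×256 rasters with four faces for the
full-resolution warp checks (96×96 and smaller elsewhere). The interpolation
tolerance for comparisons that involve one extra bilinear resampling of a
blurred rendering is 0.05 in intensity units (images in [0, 1]); the second
derivative of a Gaussian-blurred edge bounds the per-resampling bilinear
error an order of magnitude below that.

## Known limitations

* The published classification tree cannot be re-fitted without
  patient-level data; only its printed two-threshold rule is reproduced,
  and tree induction is validated on synthetic planted structure instead.
* The NIPBL-like fraction is a lower bound under missingness by
  construction, but no attempt is made to model informative missingness.
* Average-face construction assumes landmark correspondence is correct and
  photographs are comparable in resolution and colour balance; only
  geometric normalisation is performed.
* `flag_mosaic()` is a deliberate formalisation of a qualitative argument;
  its margin is a policy choice, not an estimated quantity.
* Statistical comparison of averaged faces (beyond shape distances) is out
  of scope; assessing composite faces remains a human-gestalt judgement.
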