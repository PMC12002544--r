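---
title: "Multi-parametric lesion and perilesional shell analysis: methods"
author: "LesionShells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parametric lesion and perilesional shell analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LesionShells)
```

## The problem

Quantitative MRI promises objective, scanner-independent tissue parameters
for multiple sclerosis (MS): myelin water fraction (MWF), magnetization
transfer saturation (MTsat), inhomogeneous MT ratio (ihMTR), relaxation
times qT1/qT2/qT2\*, proton density (PD), magnetic susceptibility (QSM)
and the T1w/T2w ratio. The analytical question this package addresses is
how to compare such a panel *within the same subjects* across the tissue
compartments that matter in MS — focal lesions, the perilesional rim,
and normal-appearing white and grey matter (NAWM/NAGM) — and against
healthy-control tissue (HCWM/HCGM), at three levels:

* **subject level** — one mean per subject per compartment
  (`avgLesion`, `avgPL`, WM, GM);
* **group level** — cohort medians (and ranges) of those subject means;
* **lesion level** — each lesion analysed individually together with its
  own surround, to expose between-lesion heterogeneity.

Because clinical cohorts of this kind cannot be shared, the package pairs
the analysis pipeline with a fully synthetic phantom generator whose
defaults encode the reference cohort's printed summary statistics, so
that every stage can be validated against known ground truth.

## Volumes and geometry

All volumes are 3D scalar fields (`MRVolume`) with a 4×4 voxel-to-world
affine; missing data is `NaN` and is excluded from every mean. Maps are
brought onto the subject's reference grid (1×1×1 mm, the grid of the
anatomical scan on which lesions are drawn) by trilinear interpolation;
binary masks and probability maps use nearest-neighbour resampling,
since interpolated fractional labels are meaningless. Two deliberate
numerical choices:

* **No extrapolation.** Resampling positions outside the source extent
  become missing, never zero: zero-filled voxels would silently bias VOI
  means. The *common imaging volume* — the intersection of the coverage
  of every available map — is recomputed per subject, and all VOIs are
  restricted to it. An absent modality (e.g. a susceptibility scan that
  could not be acquired) is simply omitted from the intersection and
  handled downstream by pairwise exclusion.
* **Zero-weight corners do not propagate missingness.** A trilinear
  sample whose interpolation weight on a missing voxel is exactly zero
  is unaffected by it, so resampling onto the identical grid is the
  identity even next to missing voxels.

## VOI construction

For each subject the builder produces lesion, perilesion (PL), shells
1–3, WM and GM masks, plus the same five masks per individual lesion:

1. **Connected components.** Lesions are labelled as maximal connected
   components (26-connectivity by default, the standard for lesion
   labelling; 6-connectivity via `voiParams()`), in deterministic
   first-voxel order.
2. **One-voxel erosion** with the radius-1 spherical element (the
   6-cross) suppresses partial-volume rim voxels. Lesions emptied by
   erosion are dropped and logged.
3. **Perilesion**: the eroded lesion dilated by the radius-2 discrete
   Euclidean ball (33 offsets), minus every lesion voxel of the subject,
   intersected with the WM mask — a two-voxel-wide NAWM shell.
4. **Shells 1–3**: the PL dilated by the radius-*n* ball (*n* = 1, 2, 3),
   minus *all* inner structure (lesions, PL, and shells 1..*n*−1),
   intersected with the WM mask. Removing all inner masks — not only
   shell *n*−1 — is required for the shells to be pairwise disjoint;
   with ball-*n* dilation of the PL, excluding only the previous shell
   would let earlier shells re-enter.
5. **Tissue masks**: GM/WM probability maps thresholded strictly at
   0.9 (a voxel at exactly the threshold is excluded), minus lesion
   voxels.
6. **Common-volume restriction**: a lesion whose footprint (lesion +
   PL + shells) is not fully covered is dropped (partial coverage would
   bias its means); `dropPartial = FALSE` trims instead.

Two genuinely open design points are resolved as follows, with switches
for the alternative reading:

* **Eroded vs original masks.** The erosion step precedes everything
  else, and the eroded masks are thereafter treated as *the* lesion
  segmentations: shell geometry and the lesion-exclusion rule both use
  the eroded masks by default (`useErodedMasks = FALSE` switches to the
  pre-erosion masks).
* **NAWM content.** Only lesion voxels are excluded from the WM/GM
  VOIs; PL and shell voxels remain part of NAWM by default
  (`excludePerilesionFromWM = TRUE` removes them).

Per-lesion VOIs are independent, so the surrounds of two nearby lesions
may share voxels; in the subject-level union masks each voxel is counted
once, attributed to its innermost class (PL before shell 1 before shell
2 before shell 3). Structuring-element radii are in voxel units; on an
anisotropic grid the builder warns.

The shell construction is validated voxel-for-voxel against an
independent brute-force classifier that assigns classes by explicit
Euclidean distance, with no code shared with the shift-accumulate
morphology used by the implementation.

## Extraction and aggregation

`voiMean()` averages valid voxels only and reports the contributing
count; an empty effective VOI is *undefined* (`NA`, never zero).
Subject-level `avgLesion`/`avgPL` are **voxel-pooled** means over the
union masks: patients contribute through voxels, not lesion counts, so a
patient with many lesions is treated like a patient with few. The
alternative (unweighted mean of per-lesion means) is available via
`avgMode = "perLesionMean"`. Group cells are medians with (min, max)
ranges; the median of an even-sized sample is the midpoint of the two
central order statistics.

## Statistics

The battery mirrors the reference layout: per biomarker, Mann-Whitney U
for the two independent group contrasts (HCWM vs NAWM, HCGM vs NAGM)
and Wilcoxon signed-rank for the five within-patient contrasts (lesion
vs PL / NAWM / NAGM, PL vs NAWM / NAGM) — 63 tests.

* **Exactness.** Exact null distributions are used whenever the
  relevant sample size is ≤ 25 and there are no ties (no tied absolute
  differences for the signed-rank test); the study's group sizes (13,
  14) are comfortably exact. Beyond that, the midrank tie-corrected
  normal approximation with continuity correction applies. Exact
  two-sided p-values are twice the smaller tail, capped at 1. Zero
  differences are dropped (classical convention; if all differences are
  zero the test is undecidable and reports p = 1 with the zero count).
  The underlying distributions come from base R; the package's tests
  verify the exact p-values against full enumeration of rank
  assignments and sign patterns.
* **FDR control.** Benjamini-Hochberg step-up at α = 0.05, applied
  within each contrast family of nine biomarker tests. The nine-test
  family is the structure consistent with a rank-1 critical value of
  0.05/9 ≈ 0.006; `familyMode = "global"` widens the family to all 63
  tests. Outputs carry both the BH-adjusted p-value and the per-rank
  critical values i/m·α, because results in this field are often quoted
  against the critical value (as a "q-value") rather than the adjusted
  p — with m = 9 an adjusted-p reading of such a quote would be
  inconsistent (9 × 0.048 ≫ 0.006), so the critical-value reading is
  used and documented.
* **Missing cells** (absent modality, emptied VOI) exclude the subject
  pairwise for the affected tests.

## The synthetic phantom

The generator emulates the statistical structure the analysis assumes,
not anatomy or MR physics. Geometry is an idealized nested-ellipsoid
head: background (missing), a GM ribbon, and a WM core in a 64³ grid at
1 mm (defaults). Spherical lesions (2–4 per patient, radius 2–3.5
voxels by default; radii ≥ 2 so erosion cannot empty them) are placed
by rejection sampling inside the WM core with a separation that keeps
the full shell structures of different lesions disjoint — so per-lesion
ground truth stays clean; placement restarts from scratch up to 60
times before declaring the configuration infeasible.

Voxel values are assigned through the *same* VOI-geometry code path the
analysis uses: each voxel gets its class value (GM, WM, or the
lesion/PL/shell-1–3 radial profile), plus three noise layers:

* **Between-subject effects**, one per biomarker and tissue, with SD a
  quarter of the printed range of the reference subject means (a range
  over ~14 subjects spans roughly ±2 SD under normality — a documented
  heuristic, tunable via `sigmaSubjectScale`). Group differences enter
  through the different GM/WM means of the two groups' value tables.
* **Per-lesion heterogeneity**: one shared factor per (lesion,
  biomarker), multiplied by the class-specific reference SDs, which are
  markedly larger in the lesion class than in shell 3 for qT1, qT2,
  qT2\*, PD and QSM — reproducing elevated between-lesion heterogeneity
  for exactly those markers. The factor is drawn from a standard normal
  truncated at ±1.5: the smallest ratio of class gap to SD difference
  across the nine biomarkers is ≈ 1.6 (qT2), so the truncation
  guarantees that every lesion, and hence every simulated patient,
  preserves the lesion-vs-PL ordering — the strict per-patient ordering
  the reference cohort exhibits — while the across-lesion spread stays
  proportional to the reference SDs.
* **Voxel noise**, i.i.d. Gaussian per biomarker at typical map-noise
  magnitudes (e.g. 1.5 % for MWF, 50 ms for qT1, 6 ppb for QSM);
  negligible after VOI averaging but realistic at voxel scale.

Determinism: a subject's stream is seeded by a fixed affine function of
the master seed and the subject index, so identical `(spec, seed)`
yield bit-identical volumes and adding a subject never perturbs
existing ones. One control subject loses its QSM map when
`missingModality` is on, emulating the reference cohort's dropout.

Each subject records a ground truth sufficient to predict every
noise-free VOI mean *exactly*. Note that the NAWM prediction is a
composition-weighted mixture, not the bare WM table value: NAWM
legitimately retains perilesional voxels (see VOI construction), and
the ground truth accounts for that. Lesion-level VOI means equal the
configured radial-profile values exactly in the noise-free setting.

`simulateSubjectMeans()` exposes the generator's subject-level
distributional model directly — the same tissue means, between-subject
SDs and truncated lesion factors, without rendering volumes. This is
the intended fast path for calibration studies needing hundreds or
thousands of cohort replicates (type-I error under the global null,
sign-structure rates); the rendered phantom and the model agree by
construction up to voxel-noise terms that vanish after VOI averaging.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: anatomical shape and spatial correlation of
noise, lesion-type physiology (rims, remyelination), registration
error (affines are taken as exact; only resampling is applied), field
inhomogeneities, and the upstream map-fitting toolchains. Conclusions
about the pipeline's correctness transfer; conclusions about biological
effect sizes do not.

## Validation problem sizes

The shipped validation suite uses: ~100 random mask configurations at
14–18³ against the brute-force distance oracle; a full noise-free
default cohort (13 + 14 subjects, 64³) for ground-truth recovery at
1e-10 relative tolerance; 2000 model-level null cohorts for the type-I
error of the exact Mann-Whitney test at n = 13/14 (analytically
0.0482 at α = 0.05, inside the 0.03–0.06 band the discrete exact test
permits); 100 model-level replicates plus one rendered cohort for the
per-patient sign structure; and a duplicated 3 + 3 subject end-to-end
run for byte-level determinism. These sizes are the package's own
choices for a thorough-but-routine check; all of them scale up via the
corresponding function arguments.

## Known limitations

* GM/WM are treated as single compartments (no cortical/deep-GM or
  tract parcellation), matching the reference analysis.
* Biomarkers are analysed separately; no multivariate combination.
* The T1w/T2w map is a plain ratio, with no intensity calibration.
* Lesion segmentation quality is out of scope: masks are inputs.
* On anisotropic grids structuring elements remain voxel-based
  (warned), so shells are geometrically anisotropic there.
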