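#' @import methods
NULL

#' MRVolume: a 3D scalar field with voxel-to-world geometry
#'
#' The basic carrier for quantitative parameter maps and binary masks.
#' Voxel values live in a 3D numeric array; missing data (voxels with no
#' valid measurement, e.g. outside the coverage of an acquisition) are
#' encoded as `NaN` and are excluded from every mean computed downstream.
#' The affine maps 0-based voxel indices `(i, j, k, 1)` to world
#' coordinates in millimetres (NIfTI convention).
#'
#' @slot data 3D numeric array; `NaN` marks missing voxels.
#' @slot affine 4x4 voxel-to-world transform (mm).
#' @slot units unit label, e.g. `"%"`, `"ms"`, `"ppb"`, `""`.
#' @export
setClass("MRVolume",
  representation(data = "array", affine = "matrix", units = "character"),
  prototype(units = "")
)

setValidity("MRVolume", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "data must be a 3D array with all dimensions >= 1")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (length(object@units) != 1L)
    msg <- c(msg, "units must be a single string")
  if (length(msg)) msg else TRUE
})

#' ReferenceGrid: the target sampling grid for a subject
#'
#' All maps of a subject are resampled onto one reference grid (in the
#' study this is the 1x1x1 mm T1-weighted anatomical grid on which the
#' lesion masks are drawn).
#'
#' @slot dim integer(3) grid extent in voxels.
#' @slot affine 4x4 voxel-to-world transform (mm).
#' @export
setClass("ReferenceGrid",
  representation(dim = "integer", affine = "matrix")
)

setValidity("ReferenceGrid", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be 3 positive integers")
  if (!all(dim(object@affine) == c(4L, 4L)) ||
      abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  if (any(sp <= 0)) msg <- c(msg, "voxel spacing must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' LesionComponents: connected-component labelling of a lesion mask
#'
#' @slot labels 3D integer array, 0 = background, k = lesion k.
#' @slot count number of labelled lesions.
#' @slot perLesion data.frame with one row per component: `label`,
#'   `n_voxels`, bounding box columns, `dropped`, `reason`.
#' @export
setClass("LesionComponents",
  representation(labels = "array", count = "integer", perLesion = "data.frame")
)

setValidity("LesionComponents", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  lab <- sort(unique(as.integer(object@labels[object@labels > 0])))
  if (object@count > 0L && !identical(lab, seq_len(object@count)))
    msg <- c(msg, "labels must be consecutive integers 1..count")
  if (length(msg)) msg else TRUE
})

#' VOISet: all volumes of interest of one subject
#'
#' Holds the union masks (lesion, perilesion, shells 1-3, white and grey
#' matter), per-lesion masks stored as linear voxel indices, and full
#' provenance of the parameters used to build them. All masks live on the
#' subject's reference grid and are pairwise consistent: lesion, PL and
#' shells are mutually disjoint, no lesion voxel enters a non-lesion VOI,
#' and every VOI is restricted to the common imaging volume.
#'
#' @slot dim integer(3) grid extent.
#' @slot masks named list of logical arrays: `lesion`, `pl`, `shell1`,
#'   `shell2`, `shell3`, `wm`, `gm`.
#' @slot perLesion named list (one element per retained lesion) of lists of
#'   integer voxel indices: `lesion`, `pl`, `shell1`, `shell2`, `shell3`.
#' @slot dropped data.frame of dropped lesions: `label`, `n_voxels`, `reason`.
#' @slot provenance named list of the parameters used.
#' @export
setClass("VOISet",
  representation(dim = "integer", masks = "list", perLesion = "list",
                 dropped = "data.frame", provenance = "list")
)

setValidity("VOISet", function(object) {
  msg <- character()
  need <- c("lesion", "pl", "shell1", "shell2", "shell3", "wm", "gm")
  if (!all(need %in% names(object@masks)))
    msg <- c(msg, paste("masks must contain:", paste(need, collapse = ", ")))
  else {
    excl <- c("lesion", "pl", "shell1", "shell2", "shell3")
    for (i in seq_along(excl)) for (j in seq_along(excl)) {
      if (i < j && any(object@masks[[excl[i]]] & object@masks[[excl[j]]])) {
        msg <- c(msg, sprintf("%s and %s overlap", excl[i], excl[j]))
      }
    }
    les <- object@masks$lesion
    for (nm in setdiff(need, "lesion"))
      if (any(les & object@masks[[nm]]))
        msg <- c(msg, sprintf("lesion voxels present in %s", nm))
  }
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameterization of the synthetic cohort generator
#'
#' @slot dim integer(3) grid extent (default 64^3 at 1 mm).
#' @slot spacing numeric(3) voxel edge length in mm.
#' @slot geometry named list of ellipsoid semi-axis fractions
#'   (`brain`, `wm`) relative to the half-extent of the grid.
#' @slot lesionCountRange integer(2), lesions per MS subject.
#' @slot lesionRadiusRange numeric(2), lesion radius range in voxels.
#' @slot valueTable data.frame: biomarker x tissue-class means (HC/NA GM
#'   and WM, per group).
#' @slot radialProfile data.frame: biomarker x {lesion, pl, shell1..3} means.
#' @slot radialSD data.frame, same shape, across-lesion SDs.
#' @slot sigmaVoxel named numeric, per-biomarker voxel noise SD.
#' @slot sigmaSubject data.frame: biomarker x tissue between-subject SDs.
#' @slot sigmaLesionScale numeric scalar multiplying `radialSD` for the
#'   per-lesion heterogeneity effect.
#' @slot missingModality logical; drop the susceptibility map (QSM) for
#'   exactly one control subject, emulating a study dropout.
#' @export
setClass("PhantomSpec",
  representation(
    dim = "integer", spacing = "numeric", geometry = "list",
    lesionCountRange = "integer", lesionRadiusRange = "numeric",
    valueTable = "data.frame", radialProfile = "data.frame",
    radialSD = "data.frame", sigmaVoxel = "numeric",
    sigmaSubject = "data.frame", sigmaLesionScale = "numeric",
    missingModality = "logical"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 16L))
    msg <- c(msg, "dim must be 3 integers >= 16")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (any(object@lesionRadiusRange < 2))
    msg <- c(msg, "lesion radii must be >= 2 voxels (erosion must not empty them)")
  if (object@sigmaLesionScale < 0 || any(object@sigmaVoxel < 0))
    msg <- c(msg, "all SDs must be >= 0")
  bm <- biomarkerNames()
  if (!all(bm %in% rownames(object@valueTable)))
    msg <- c(msg, "valueTable must cover all nine biomarkers")
  if (!all(bm %in% rownames(object@radialProfile)) ||
      !all(c("lesion", "pl", "shell1", "shell2", "shell3") %in%
           colnames(object@radialProfile)))
    msg <- c(msg, "radialProfile must cover all nine biomarkers x five classes")
  if (length(msg)) msg else TRUE
})

#' TestResult: one nonparametric two-sample or paired test
#'
#' @slot method test name.
#' @slot statistic test statistic (U for Mann-Whitney, V for Wilcoxon).
#' @slot n sample sizes (n1, n2 for independent; effective n for paired).
#' @slot p two-sided p-value.
#' @slot exact TRUE when the exact null distribution was used.
#' @slot ties number of tied values (or tied absolute differences).
#' @slot zeros number of zero differences dropped (paired test only).
#' @export
setClass("TestResult",
  representation(method = "character", statistic = "numeric", n = "integer",
                 p = "numeric", exact = "logical", ties = "integer",
                 zeros = "integer")
)

setValidity("TestResult", function(object) {
  if (object@p < 0 || object@p > 1) "p must be in [0, 1]" else TRUE
})

#' FDRResult: Benjamini-Hochberg step-up correction over one test family
#'
#' @slot p raw p-values (input order).
#' @slot critical per-rank BH critical values i/m * alpha (sorted order).
#' @slot adjusted BH-adjusted p-values (input order).
#' @slot rejected rejection flags (input order).
#' @slot alpha FDR level.
#' @slot family family label.
#' @export
setClass("FDRResult",
  representation(p = "numeric", critical = "numeric", adjusted = "numeric",
                 rejected = "logical", alpha = "numeric", family = "character")
)

setValidity("FDRResult", function(object) {
  msg <- character()
  if (any(object@p < 0 | object@p > 1)) msg <- c(msg, "p-values outside [0,1]")
  if (any(object@adjusted > 1 + 1e-12)) msg <- c(msg, "adjusted p > 1")
  if (is.unsorted(object@adjusted[order(object@p)]))
    msg <- c(msg, "adjusted p must be monotone in raw-p order")
  if (length(msg)) msg else TRUE
})
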