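#' @include AllClasses.R
NULL

#' Accessors for MRVolume and ReferenceGrid
#'
#' `volData` returns the raw 3D array (NaN = missing), `volAffine` the 4x4
#' voxel-to-world transform, `volUnits` the unit label, `missingMask` a
#' logical array of missing voxels, and `gridSpacing` the voxel edge
#' lengths in mm.
#'
#' @param x an `MRVolume` or `ReferenceGrid`.
#' @return See description.
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname volume-accessors
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))
#' @rdname volume-accessors
#' @export
setGeneric("volUnits", function(x) standardGeneric("volUnits"))
#' @rdname volume-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname volume-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname volume-accessors
setMethod("volData", "MRVolume", function(x) x@data)
#' @rdname volume-accessors
setMethod("volAffine", "MRVolume", function(x) x@affine)
#' @rdname volume-accessors
setMethod("volUnits", "MRVolume", function(x) x@units)
#' @rdname volume-accessors
setMethod("missingMask", "MRVolume", function(x) is.nan(x@data))
#' @rdname volume-accessors
setMethod("gridSpacing", "ReferenceGrid",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))
#' @rdname volume-accessors
setMethod("gridSpacing", "MRVolume",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' VOISet and LesionComponents accessors
#'
#' `voiMask` extracts one union mask as a logical array; `voiNames` lists
#' the available masks; `retainedLesions` returns per-lesion VOI voxel
#' indices; `droppedLesions` the bookkeeping of excluded lesions;
#' `lesionCount` the number of components.
#'
#' @param x a `VOISet` or `LesionComponents`.
#' @param name mask name, one of `voiNames(x)`.
#' @name voiset-accessors
NULL

#' @rdname voiset-accessors
#' @export
setGeneric("voiMask", function(x, name) standardGeneric("voiMask"))
#' @rdname voiset-accessors
#' @export
setGeneric("voiNames", function(x) standardGeneric("voiNames"))
#' @rdname voiset-accessors
#' @export
setGeneric("retainedLesions", function(x) standardGeneric("retainedLesions"))
#' @rdname voiset-accessors
#' @export
setGeneric("droppedLesions", function(x) standardGeneric("droppedLesions"))
#' @rdname voiset-accessors
#' @export
setGeneric("lesionCount", function(x) standardGeneric("lesionCount"))

#' @rdname voiset-accessors
setMethod("voiMask", "VOISet", function(x, name) {
  if (!name %in% names(x@masks)) stop("unknown VOI: ", name)
  x@masks[[name]]
})
#' @rdname voiset-accessors
setMethod("voiNames", "VOISet", function(x) names(x@masks))
#' @rdname voiset-accessors
setMethod("retainedLesions", "VOISet", function(x) x@perLesion)
#' @rdname voiset-accessors
setMethod("droppedLesions", "VOISet", function(x) x@dropped)
#' @rdname voiset-accessors
setMethod("lesionCount", "LesionComponents", function(x) x@count)
#' @rdname voiset-accessors
setMethod("lesionCount", "VOISet", function(x) length(x@perLesion))

#' @rdname voiset-accessors
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))
#' @rdname voiset-accessors
setMethod("componentLabels", "LesionComponents", function(x) x@labels)

#' Test-result accessors
#'
#' @param x a `TestResult` or `FDRResult`.
#' @name stats-accessors
NULL

#' @rdname stats-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname stats-accessors
setMethod("pValue", "TestResult", function(x) x@p)
#' @rdname stats-accessors
#' @export
setGeneric("adjustedP", function(x) standardGeneric("adjustedP"))
#' @rdname stats-accessors
setMethod("adjustedP", "FDRResult", function(x) x@adjusted)
#' @rdname stats-accessors
#' @export
setGeneric("rejected", function(x) standardGeneric("rejected"))
#' @rdname stats-accessors
setMethod("rejected", "FDRResult", function(x) x@rejected)
#' @rdname stats-accessors
#' @export
setGeneric("criticalValues", function(x) standardGeneric("criticalValues"))
#' @rdname stats-accessors
setMethod("criticalValues", "FDRResult", function(x) x@critical)

setMethod("show", "MRVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MRVolume %dx%dx%d [%s], %d missing voxel(s)\n",
              d[1], d[2], d[3],
              if (nzchar(object@units)) object@units else "dimensionless",
              sum(is.nan(object@data))))
})

setMethod("show", "ReferenceGrid", function(object) {
  sp <- gridSpacing(object)
  cat(sprintf("ReferenceGrid %dx%dx%d, spacing %.3g x %.3g x %.3g mm\n",
              object@dim[1], object@dim[2], object@dim[3],
              sp[1], sp[2], sp[3]))
})

setMethod("show", "LesionComponents", function(object) {
  cat(sprintf("LesionComponents: %d component(s), %d labelled voxel(s)\n",
              object@count, sum(object@labels > 0)))
})

setMethod("show", "VOISet", function(object) {
  cat(sprintf("VOISet on %dx%dx%d grid\n", object@dim[1], object@dim[2],
              object@dim[3]))
  for (nm in names(object@masks))
    cat(sprintf("  %-7s %d voxel(s)\n", nm, sum(object@masks[[nm]])))
  cat(sprintf("  retained lesions: %d; dropped: %d\n",
              length(object@perLesion), nrow(object@dropped)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %dx%dx%d grid, %d biomarkers, %d-%d lesions/subject\n",
              object@dim[1], object@dim[2], object@dim[3],
              nrow(object@valueTable), object@lesionCountRange[1],
              object@lesionCountRange[2]))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %g, n = (%s), p = %.4g (%s)\n",
              object@method, object@statistic,
              paste(object@n, collapse = ", "), object@p,
              if (object@exact) "exact" else "asymptotic"))
})

setMethod("show", "FDRResult", function(object) {
  cat(sprintf("BH-FDR family '%s': m = %d, alpha = %g, %d rejection(s)\n",
              object@family, length(object@p), object@alpha,
              sum(object@rejected)))
})
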