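#' @include AllClasses.R
NULL

#' The nine-biomarker panel
#'
#' Names and units of the multi-parametric panel handled by the package:
#' myelin water fraction (MWF, %), magnetization transfer saturation
#' (MTsat, %), inhomogeneous magnetization transfer ratio (ihMTR, %),
#' quantitative relaxation times qT1/qT2/qT2* (ms), proton density (PD, %),
#' quantitative susceptibility (QSM, ppb) and the T1w/T2w ratio
#' (dimensionless).
#'
#' @return `biomarkerNames()`: character vector of the nine biomarker
#'   names; `biomarkerUnits()`: named character vector of unit labels.
#' @export
biomarkerNames <- function() {
  c("MWF", "MTsat", "ihMTR", "qT1", "qT2", "qT2star", "PD", "QSM", "T1wT2w")
}

#' @rdname biomarkerNames
#' @export
biomarkerUnits <- function() {
  c(MWF = "%", MTsat = "%", ihMTR = "%", qT1 = "ms", qT2 = "ms",
    qT2star = "ms", PD = "%", QSM = "ppb", T1wT2w = "")
}

#' Construct an MRVolume
#'
#' @param data 3D numeric or logical array; `NaN` marks missing voxels.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices, mm).
#' @param units unit label.
#' @return An [MRVolume-class] object.
#' @export
mrVolume <- function(data, affine = diag(4), units = "") {
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  storage.mode(data) <- "double"
  new("MRVolume", data = data, affine = affine, units = units)
}

#' Construct a ReferenceGrid
#'
#' The default is an isotropic 1 mm grid with the world origin at the
#' first voxel centre, matching the anatomical reference grid on which
#' lesion masks are defined.
#'
#' @param dim integer(3) grid extent.
#' @param spacing numeric(3) voxel edge lengths in mm (default 1,1,1).
#' @param origin world position (mm) of voxel (0,0,0).
#' @return A [ReferenceGrid-class] object.
#' @export
referenceGrid <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  affine <- diag(c(spacing, 1))
  affine[1:3, 4] <- origin
  new("ReferenceGrid", dim = as.integer(dim), affine = affine)
}

#' @rdname referenceGrid
#' @param vol an `MRVolume` whose sampling grid is wanted.
#' @export
gridOf <- function(vol) {
  new("ReferenceGrid", dim = dim(vol@data), affine = vol@affine)
}

.sameGeometry <- function(a, b, tol = 1e-6) {
  da <- if (is(a, "MRVolume")) dim(a@data) else a@dim
  db <- if (is(b, "MRVolume")) dim(b@data) else b@dim
  identical(as.integer(da), as.integer(db)) &&
    max(abs(a@affine - b@affine)) < tol
}

#' Read a volume from a NIfTI-1 file
#'
#' Missing voxels are encoded as `NaN` in floating-point images. The unit
#' label is taken from `units` when given, otherwise from a JSON sidecar
#' `<path>.json` written by [writeVolume()], otherwise left empty.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param units optional unit label override.
#' @return An [MRVolume-class].
#' @export
readVolume <- function(path, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  if (abs(det(affine)) < 1e-12) stop("non-invertible affine in ", path)
  if (is.null(units)) {
    sidecar <- paste0(path, ".json")
    units <- if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (!is.null(meta$units)) as.character(meta$units) else ""
    } else ""
  }
  data <- array(as.numeric(img), dim = d)
  # NIfTI files may encode missing data as NA; normalise to NaN
  data[is.na(data)] <- NaN
  mrVolume(data, affine, units)
}

#' Write a volume to a NIfTI-1 file
#'
#' Binary masks (values in {0, 1}) are stored as unsigned 8-bit; all other
#' volumes as 64-bit float so that a write-read round trip is bit-exact.
#' A JSON sidecar carrying the unit label is written next to the image
#' when the volume has one.
#'
#' @param vol an [MRVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype `"auto"` (default), `"double"`, `"float"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, datatype = "auto") {
  stopifnot(is(vol, "MRVolume"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  if (datatype == "auto") {
    v <- vol@data[!is.nan(vol@data)]
    datatype <- if (length(v) == length(vol@data) && all(v %in% c(0, 1)))
      "uint8" else "double"
  }
  img <- RNifti::asNifti(vol@data)
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  if (nzchar(vol@units))
    jsonlite::write_json(list(units = vol@units), paste0(path, ".json"),
                         auto_unbox = TRUE)
  invisible(path)
}

.targetVoxelWorldCoords <- function(grid) {
  d <- grid@dim
  i <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  cbind(i, j, k, 1)
}

#' Resample a volume onto a reference grid by trilinear interpolation
#'
#' Each output voxel takes the trilinear interpolation of the source
#' volume at the world position of the output voxel centre. Positions
#' outside the source extent are marked missing (`NaN`), never
#' zero-filled: uncovered voxels must drop out of the common imaging
#' volume rather than corrupt VOI means. Missing source voxels propagate
#' to every output voxel whose interpolation weight on them is non-zero.
#'
#' @param vol source [MRVolume-class].
#' @param grid target [ReferenceGrid-class].
#' @return An [MRVolume-class] on `grid`.
#' @export
resampleTrilinear <- function(vol, grid) {
  stopifnot(is(vol, "MRVolume"), is(grid, "ReferenceGrid"))
  if (.sameGeometry(vol, grid)) {
    return(mrVolume(vol@data, grid@affine, vol@units))
  }
  M <- solve(vol@affine) %*% grid@affine  # target voxel -> source voxel
  src <- .targetVoxelWorldCoords(grid) %*% t(M)
  sd <- dim(vol@data)
  x <- src[, 1]; y <- src[, 2]; z <- src[, 3]
  eps <- 1e-9
  inside <- x >= -eps & x <= sd[1] - 1 + eps &
            y >= -eps & y <= sd[2] - 1 + eps &
            z >= -eps & z <= sd[3] - 1 + eps
  out <- rep(NaN, nrow(src))
  if (any(inside)) {
    x <- pmin(pmax(x[inside], 0), sd[1] - 1)
    y <- pmin(pmax(y[inside], 0), sd[2] - 1)
    z <- pmin(pmax(z[inside], 0), sd[3] - 1)
    x0 <- pmin(floor(x), max(sd[1] - 2, 0)); fx <- x - x0
    y0 <- pmin(floor(y), max(sd[2] - 2, 0)); fy <- y - y0
    z0 <- pmin(floor(z), max(sd[3] - 2, 0)); fz <- z - z0
    x1 <- pmin(x0 + 1, sd[1] - 1)
    y1 <- pmin(y0 + 1, sd[2] - 1)
    z1 <- pmin(z0 + 1, sd[3] - 1)
    dat <- vol@data
    corner <- function(cx, cy, cz) dat[1 + cx + sd[1] * (cy + sd[2] * cz)]
    # zero-weight corners contribute exactly 0 even when the corner value
    # is missing, so NaN does not bleed into voxels it cannot influence
    acc <- function(w, v) { r <- w * v; r[w == 0] <- 0; r }
    val <- acc((1 - fx) * (1 - fy) * (1 - fz), corner(x0, y0, z0)) +
           acc(fx * (1 - fy) * (1 - fz),       corner(x1, y0, z0)) +
           acc((1 - fx) * fy * (1 - fz),       corner(x0, y1, z0)) +
           acc(fx * fy * (1 - fz),             corner(x1, y1, z0)) +
           acc((1 - fx) * (1 - fy) * fz,       corner(x0, y0, z1)) +
           acc(fx * (1 - fy) * fz,             corner(x1, y0, z1)) +
           acc((1 - fx) * fy * fz,             corner(x0, y1, z1)) +
           acc(fx * fy * fz,                   corner(x1, y1, z1))
    out[inside] <- val
  }
  mrVolume(array(out, dim = grid@dim), grid@affine, vol@units)
}

#' Resample a binary mask by nearest neighbour
#'
#' Masks are never interpolated trilinearly (fractional labels are
#' meaningless); the nearest source voxel is taken instead, and positions
#' outside the source extent become 0.
#'
#' @inheritParams resampleTrilinear
#' @return A binary [MRVolume-class] on `grid`.
#' @export
resampleNearest <- function(vol, grid) {
  stopifnot(is(vol, "MRVolume"), is(grid, "ReferenceGrid"))
  if (.sameGeometry(vol, grid)) {
    return(mrVolume(vol@data, grid@affine, vol@units))
  }
  M <- solve(vol@affine) %*% grid@affine
  src <- .targetVoxelWorldCoords(grid) %*% t(M)
  sd <- dim(vol@data)
  x <- round(src[, 1]); y <- round(src[, 2]); z <- round(src[, 3])
  inside <- x >= 0 & x <= sd[1] - 1 & y >= 0 & y <= sd[2] - 1 &
            z >= 0 & z <= sd[3] - 1
  out <- numeric(nrow(src))
  out[inside] <- vol@data[1 + x[inside] + sd[1] * (y[inside] + sd[2] * z[inside])]
  mrVolume(array(out, dim = grid@dim), grid@affine, vol@units)
}

#' Subject-specific common imaging volume
#'
#' The voxel region covered by every supplied map: true exactly where all
#' inputs (already resampled to a shared grid) are non-missing. Biomarker
#' means are only ever taken inside this region, so a map with partial
#' coverage shrinks every VOI rather than biasing it. Maps that are absent
#' for a subject (a missing modality) are simply not passed in and do not
#' restrict the volume.
#'
#' @param vols non-empty list of [MRVolume-class] objects on one grid.
#' @return A binary [MRVolume-class] mask.
#' @export
commonImagingVolume <- function(vols) {
  if (length(vols) == 0L) stop("empty volume list")
  d <- dim(vols[[1]]@data)
  cov <- !is.nan(vols[[1]]@data)
  for (v in vols[-1]) {
    if (!identical(dim(v@data), d)) stop("volume shape mismatch")
    cov <- cov & !is.nan(v@data)
  }
  mrVolume(cov, vols[[1]]@affine, "")
}

#' Compute the T1w/T2w ratio map
#'
#' Voxelwise ratio of a T1-weighted to a T2-weighted image (both already
#' on the same reference grid), a semi-quantitative myelin-related
#' measure in white matter. No intensity calibration is applied: the map
#' is the plain ratio. Voxels where the T2w value is non-positive, or
#' where either input is missing, are marked missing.
#'
#' @param t1w,t2w [MRVolume-class] objects on the same grid.
#' @return A dimensionless [MRVolume-class].
#' @export
t1wT2wRatio <- function(t1w, t2w) {
  stopifnot(is(t1w, "MRVolume"), is(t2w, "MRVolume"))
  if (!.sameGeometry(t1w, t2w)) stop("t1w and t2w are not on the same grid")
  num <- t1w@data
  den <- t2w@data
  out <- num / den
  out[!is.nan(den) & den <= 0] <- NaN
  mrVolume(array(out, dim = dim(num)), t1w@affine, "")
}
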