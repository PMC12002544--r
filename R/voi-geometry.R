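#' @include morphology.R
NULL

#' One-voxel lesion erosion
#'
#' Every lesion mask is eroded by one voxel before analysis, using the
#' radius-1 spherical element (the 6-neighbourhood cross), to suppress
#' partial-volume voxels at the lesion rim. Lesions emptied by the
#' erosion are dropped by the VOI builder.
#'
#' @param mask binary [MRVolume-class] or logical/0-1 array.
#' @return Eroded mask of the same type; always a subset of the input.
#' @export
erodeOneVoxel <- function(mask) {
  erodeMask(mask, makeBall(1))
}

#' Two-voxel perilesional shell of one lesion
#'
#' The perilesion (PL) of a lesion is the two-voxel-wide shell of
#' normal-appearing white matter around it: the lesion dilated by the
#' radius-2 spherical element, minus every lesion voxel of the subject
#' (lesion voxels are excluded from all non-lesion VOIs), intersected
#' with the white-matter mask.
#'
#' @param lesionK binary mask of one lesion.
#' @param wmMask binary white-matter mask.
#' @param allLesions binary union of all lesion voxels of the subject.
#' @return Binary PL mask of the same type as `lesionK`.
#' @export
perilesionShell <- function(lesionK, wmMask, allLesions) {
  lk <- .asMaskArray(lesionK, "lesion")
  wm <- .asMaskArray(wmMask, "WM mask")
  al <- .asMaskArray(allLesions, "lesion union")
  if (!identical(dim(lk), dim(wm)) || !identical(dim(lk), dim(al)))
    stop("grid mismatch between lesion, WM and lesion-union masks")
  .wrapLike(lesionK, dilateMask(lk, makeBall(2)) & !al & wm)
}

#' Concentric outer shell n around a perilesional shell
#'
#' Shell n (n in 1..3) is the PL mask dilated by the radius-n spherical
#' element, with all inner structure removed and the result intersected
#' with the white-matter mask. `inner` must be the union of every lesion
#' voxel, the PL, and shells 1..n-1: removing all of it (not only shell
#' n-1) keeps the shells pairwise disjoint, which a literal
#' "exclude shell n-1 only" rule would violate for n >= 2.
#'
#' @param n shell index, 1, 2 or 3.
#' @param pl binary perilesion mask.
#' @param inner binary union of lesions, PL and shells 1..n-1.
#' @param wmMask binary white-matter mask.
#' @return Binary shell mask of the same type as `pl`.
#' @export
outerShell <- function(n, pl, inner, wmMask) {
  if (!n %in% 1:3) stop("shell index n must be 1, 2 or 3")
  p <- .asMaskArray(pl, "PL")
  inn <- .asMaskArray(inner, "inner")
  wm <- .asMaskArray(wmMask, "WM mask")
  if (!identical(dim(p), dim(inn)) || !identical(dim(p), dim(wm)))
    stop("grid mismatch")
  .wrapLike(pl, dilateMask(p, makeBall(n)) & !inn & wm)
}

#' Threshold tissue-probability maps into GM/WM masks
#'
#' Grey- and white-matter masks are obtained by strict thresholding of
#' tissue-probability maps (probability > threshold, default 0.9, so a
#' voxel at exactly the threshold is excluded), with every lesion voxel
#' removed from both.
#'
#' @param gmProb,wmProb tissue-probability [MRVolume-class] maps in [0,1].
#' @param allLesions binary union of lesion voxels.
#' @param threshold probability threshold (default 0.9, strict).
#' @return Named list with binary `gm` and `wm` masks.
#' @export
tissueMasks <- function(gmProb, wmProb, allLesions, threshold = 0.9) {
  gp <- if (is(gmProb, "MRVolume")) gmProb@data else gmProb
  wp <- if (is(wmProb, "MRVolume")) wmProb@data else wmProb
  for (p in list(gp, wp)) {
    v <- p[!is.nan(p)]
    if (any(v < 0 | v > 1)) stop("tissue probabilities must lie in [0, 1]")
  }
  al <- .asMaskArray(allLesions, "lesion union")
  gm <- !is.nan(gp) & gp > threshold & !al
  wm <- !is.nan(wp) & wp > threshold & !al
  list(gm = .wrapLike(gmProb, gm), wm = .wrapLike(wmProb, wm))
}

#' VOI-construction parameters
#'
#' @param connectivity component connectivity, 26 (default) or 6.
#' @param threshold tissue-probability threshold (default 0.9).
#' @param useErodedMasks build shell geometry (and the lesion-exclusion
#'   rule) from the eroded lesion masks (default) or from the original
#'   pre-erosion masks.
#' @param excludePerilesionFromWM when TRUE, remove PL and shell voxels
#'   from the white-matter VOI; by default only lesion voxels are removed.
#' @param dropPartial drop a lesion whose footprint (lesion + PL + shells)
#'   leaves the common imaging volume (default); when FALSE the masks are
#'   trimmed to the common volume instead.
#' @param keepErodedEmpty retain the original single-voxel mask for a
#'   lesion emptied by erosion instead of dropping it.
#' @return Named list of parameters for [buildVOISet()].
#' @export
voiParams <- function(connectivity = 26, threshold = 0.9,
                      useErodedMasks = TRUE,
                      excludePerilesionFromWM = FALSE,
                      dropPartial = TRUE, keepErodedEmpty = FALSE) {
  list(connectivity = as.integer(connectivity), threshold = threshold,
       useErodedMasks = useErodedMasks,
       excludePerilesionFromWM = excludePerilesionFromWM,
       dropPartial = dropPartial, keepErodedEmpty = keepErodedEmpty)
}

# Bounding box of a set of linear voxel indices, padded and clamped.
.paddedBox <- function(idx, d, margin) {
  co <- arrayInd(idx, d)
  lo <- pmax(apply(co, 2, min) - margin, 1L)
  hi <- pmin(apply(co, 2, max) + margin, d)
  list(lo = lo, hi = hi)
}

# Map linear indices of a cropped box back to the full array.
.uncropIndex <- function(cropIdx, box, d) {
  cd <- box$hi - box$lo + 1L
  co <- arrayInd(cropIdx, cd)
  co <- sweep(co, 2, box$lo - 1L, "+")
  co[, 1] + d[1] * (co[, 2] - 1L) + d[1] * d[2] * (co[, 3] - 1L)
}

#' Build the full VOI set of one subject
#'
#' Orchestrates the whole VOI geometry: connected-component lesion
#' labelling, one-voxel erosion per lesion (lesions emptied by erosion
#' are dropped and logged), the two-voxel perilesional shell and
#' concentric shells 1-3 per lesion, tissue masks from the probability
#' maps, and restriction of everything to the common imaging volume.
#' A lesion whose footprint is not fully covered by the common volume is
#' dropped (partial coverage would bias its means) unless
#' `params$dropPartial = FALSE`, in which case it is trimmed.
#'
#' Per-lesion VOIs are independent: the surround of two nearby lesions
#' may share voxels. In the subject-level union masks each voxel is
#' counted once, attributed to the innermost class it belongs to for any
#' lesion (PL before shell 1 before shell 2 before shell 3).
#'
#' @param lesionMask binary lesion mask on the reference grid.
#' @param gmProb,wmProb tissue-probability maps.
#' @param common binary common-imaging-volume mask, or NULL for full
#'   coverage.
#' @param params parameter list from [voiParams()].
#' @return A [VOISet-class] object (its validity — pairwise disjointness,
#'   lesion exclusion, common-volume containment — is asserted on
#'   construction).
#' @export
buildVOISet <- function(lesionMask, gmProb, wmProb, common = NULL,
                        params = voiParams()) {
  les0 <- .asMaskArray(lesionMask, "lesion mask")
  d <- dim(les0)
  if (is(lesionMask, "MRVolume")) {
    sp <- gridSpacing(lesionMask)
    if (max(abs(sp - sp[1])) > 1e-6)
      warning("anisotropic grid: structuring-element radii are in voxels")
  }
  commonA <- if (is.null(common)) array(TRUE, d) else
    .asMaskArray(common, "common volume")
  if (!identical(dim(commonA), d)) stop("common volume grid mismatch")

  comps <- labelLesions(les0, params$connectivity)
  info <- comps@perLesion

  # per-component erosion (cropped to the component's bounding box)
  erodedIdx <- vector("list", comps@count)
  droppedRows <- list()
  retained <- logical(comps@count)
  for (k in seq_len(comps@count)) {
    idx <- which(comps@labels == k)
    box <- .paddedBox(idx, d, 1L)
    sub <- (comps@labels[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
                         box$lo[3]:box$hi[3], drop = FALSE] == k)
    dim(sub) <- box$hi - box$lo + 1L
    er <- .asMaskArray(erodeOneVoxel(sub))
    ei <- which(er)
    if (length(ei) == 0L && !params$keepErodedEmpty) {
      droppedRows[[length(droppedRows) + 1L]] <-
        data.frame(label = k, n_voxels = length(idx),
                   reason = "emptied by erosion")
      next
    }
    erodedIdx[[k]] <- if (length(ei)) .uncropIndex(ei, box, d) else idx
    retained[k] <- TRUE
  }

  # exclusion mask: every lesion voxel (eroded or original reading)
  exclUnion <- array(FALSE, d)
  if (params$useErodedMasks) {
    for (k in which(retained)) exclUnion[erodedIdx[[k]]] <- TRUE
  } else {
    exclUnion <- les0
  }

  wmFull <- !is.nan(if (is(wmProb, "MRVolume")) wmProb@data else wmProb)
  tm <- tissueMasks(gmProb, wmProb, exclUnion, params$threshold)
  gmVOI <- .asMaskArray(tm$gm)
  wmVOI <- .asMaskArray(tm$wm)
  wmSupport <- wmVOI  # lesion-excluded WM support for PL/shells

  perLesion <- list()
  for (k in which(retained)) {
    base <- if (params$useErodedMasks) erodedIdx[[k]] else
      which(comps@labels == k)
    box <- .paddedBox(base, d, 7L)
    cd <- box$hi - box$lo + 1L
    sl <- function(a) {
      s <- a[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
             box$lo[3]:box$hi[3], drop = FALSE]
      dim(s) <- cd
      s
    }
    baseC <- array(FALSE, cd)
    co <- arrayInd(base, d)
    co <- sweep(co, 2, box$lo - 1L, "-")
    baseC[co[, 1] + cd[1] * (co[, 2] - 1L) + cd[1] * cd[2] * (co[, 3] - 1L)] <- TRUE
    exclC <- sl(exclUnion)
    wmC <- sl(wmSupport)
    plC <- dilateMask(baseC, makeBall(2)) & !exclC & wmC
    inner <- exclC | plC
    s1C <- dilateMask(plC, makeBall(1)) & !inner & wmC
    inner <- inner | s1C
    s2C <- dilateMask(plC, makeBall(2)) & !inner & wmC
    inner <- inner | s2C
    s3C <- dilateMask(plC, makeBall(3)) & !inner & wmC
    masksK <- list(lesion = erodedIdx[[k]],
                   pl = .uncropIndex(which(plC), box, d),
                   shell1 = .uncropIndex(which(s1C), box, d),
                   shell2 = .uncropIndex(which(s2C), box, d),
                   shell3 = .uncropIndex(which(s3C), box, d))
    foot <- unlist(masksK, use.names = FALSE)
    outside <- !commonA[foot]
    if (any(outside)) {
      if (params$dropPartial) {
        droppedRows[[length(droppedRows) + 1L]] <-
          data.frame(label = k, n_voxels = length(erodedIdx[[k]]),
                     reason = "outside common imaging volume")
        next
      }
      masksK <- lapply(masksK, function(i) i[commonA[i]])
      if (length(masksK$lesion) == 0L) {
        droppedRows[[length(droppedRows) + 1L]] <-
          data.frame(label = k, n_voxels = 0L,
                     reason = "emptied by common-volume trimming")
        next
      }
    }
    perLesion[[paste0("lesion", k)]] <- masksK
  }

  # union masks with innermost-class priority, each voxel counted once
  unionOf <- function(field) {
    m <- array(FALSE, d)
    for (pk in perLesion) m[pk[[field]]] <- TRUE
    m
  }
  lesionU <- unionOf("lesion") & commonA
  plU <- unionOf("pl") & commonA
  s1U <- unionOf("shell1") & commonA & !plU
  s2U <- unionOf("shell2") & commonA & !plU & !s1U
  s3U <- unionOf("shell3") & commonA & !plU & !s1U & !s2U
  # a voxel in one lesion's surround and another lesion's core is lesion
  plU <- plU & !lesionU & !exclUnion
  s1U <- s1U & !lesionU & !exclUnion
  s2U <- s2U & !lesionU & !exclUnion
  s3U <- s3U & !lesionU & !exclUnion
  wmOut <- wmVOI & commonA
  if (params$excludePerilesionFromWM)
    wmOut <- wmOut & !plU & !s1U & !s2U & !s3U
  gmOut <- gmVOI & commonA

  dropped <- if (length(droppedRows)) do.call(rbind, droppedRows) else
    data.frame(label = integer(0), n_voxels = integer(0),
               reason = character(0))
  new("VOISet", dim = d,
      masks = list(lesion = lesionU, pl = plU, shell1 = s1U, shell2 = s2U,
                   shell3 = s3U, wm = wmOut, gm = gmOut),
      perLesion = perLesion, dropped = dropped,
      provenance = c(params, list(n_components = comps@count,
                                  n_retained = length(perLesion))))
}
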