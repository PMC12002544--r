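#' @include voi-geometry.R extraction.R
NULL

.bm <- function() biomarkerNames()

#' Built-in reference value tables for the synthetic cohort
#'
#' Central tissue values of the nine-biomarker panel used as generator
#' defaults, taken from a published multi-parametric MS cohort (13
#' patients, 14 controls): cohort medians and ranges of the per-subject
#' means in healthy-control and normal-appearing GM and WM
#' (`tissue`), subject-level lesion and perilesion medians
#' (`subjectLesion`), lesion-level radial profiles — across-lesion means
#' and SDs in lesion, PL and shells 1-3 (`radialProfile`, `radialSD`) —
#' and the reference per-biomarker p-values of the WM and GM group
#' contrasts (`groupPValues`), whose WM family (minimum 0.048 over nine
#' tests) is the worked FDR example.
#'
#' @return Named list of data.frames keyed by biomarker.
#' @export
defaultValueTable <- function() {
  bm <- .bm()
  tissue <- data.frame(
    gm_HC  = c(3.89, 1.53, 3.49, 1461.40, 87.60, 61.43, 76.85, 0.00, 1.11),
    gm_HC_min = c(2.68, 1.44, 2.64, 1412.30, 84.81, 56.56, 75.43, -0.48, 1.09),
    gm_HC_max = c(5.51, 1.63, 4.59, 1607.20, 92.96, 75.27, 77.92, 3.40, 1.15),
    gm_MS  = c(3.72, 1.53, 3.38, 1450.80, 85.74, 62.38, 76.55, 0.98, 1.12),
    gm_MS_min = c(2.18, 1.45, 2.80, 1358.10, 82.63, 54.52, 74.33, -0.21, 1.10),
    gm_MS_max = c(5.23, 1.67, 4.42, 1645.50, 92.55, 67.13, 78.91, 3.00, 1.21),
    wm_HC  = c(11.50, 2.68, 7.05, 993.50, 72.51, 43.01, 68.84, -4.28, 1.84),
    wm_HC_min = c(8.87, 2.55, 6.40, 935.60, 69.17, 40.72, 68.47, -8.73, 1.65),
    wm_HC_max = c(13.91, 2.84, 8.26, 1047.00, 74.57, 46.12, 68.95, 0.72, 2.04),
    wm_MS  = c(10.97, 2.65, 6.60, 1018.30, 73.53, 44.34, 68.73, -4.33, 1.83),
    wm_MS_min = c(7.40, 2.36, 5.69, 915.30, 70.92, 40.94, 68.41, -7.28, 1.71),
    wm_MS_max = c(12.70, 2.88, 8.18, 1103.30, 75.45, 47.59, 69.02, -2.82, 2.02),
    row.names = bm)
  subjectLesion <- data.frame(
    lesion = c(3.79, 1.28, 5.35, 1403.50, 107.92, 70.51, 78.54, 6.51, 0.65),
    pl     = c(9.67, 2.39, 7.00, 1050.30, 83.24, 46.74, 69.61, -7.45, 1.48),
    row.names = bm)
  radialProfile <- data.frame(
    lesion = c(5.52, 1.49, 5.69, 1371.75, 99.05, 66.44, 77.84, 3.23, 0.80),
    pl     = c(9.03, 2.47, 6.69, 1027.18, 81.88, 46.65, 69.70, -7.70, 1.54),
    shell1 = c(9.87, 2.61, 6.87, 997.21, 77.52, 44.81, 68.75, -7.60, 1.68),
    shell2 = c(10.11, 2.65, 6.89, 990.54, 76.05, 44.49, 68.58, -6.96, 1.73),
    shell3 = c(10.23, 2.67, 6.85, 989.05, 75.09, 44.36, 68.50, -6.50, 1.77),
    row.names = bm)
  radialSD <- data.frame(
    lesion = c(3.17, 0.36, 1.72, 201.32, 16.66, 15.04, 2.95, 15.85, 0.21),
    pl     = c(3.28, 0.29, 1.40, 97.02, 6.14, 5.91, 1.37, 10.91, 0.22),
    shell1 = c(3.51, 0.29, 1.38, 100.07, 5.04, 4.65, 1.15, 9.99, 0.24),
    shell2 = c(3.53, 0.28, 1.35, 90.55, 4.65, 4.33, 0.99, 8.92, 0.24),
    shell3 = c(3.53, 0.26, 1.33, 88.54, 4.43, 4.08, 0.89, 8.18, 0.24),
    row.names = bm)
  groupPValues <- data.frame(
    gm = c(0.756, 0.943, 0.220, 0.867, 0.325, 0.650, 0.350, 0.479, 0.793),
    wm = c(0.325, 0.259, 0.048, 0.325, 0.068, 0.202, 0.402, 0.579, 0.519),
    row.names = bm)
  list(tissue = tissue, subjectLesion = subjectLesion,
       radialProfile = radialProfile, radialSD = radialSD,
       groupPValues = groupPValues, units = biomarkerUnits())
}

#' Construct a PhantomSpec
#'
#' Parameterization of the synthetic multi-subject phantom. Defaults
#' encode the reference study conditions: a 64^3 isotropic 1 mm grid,
#' idealized nested-ellipsoid geometry (background, GM ribbon, WM core),
#' 2-4 lesions per patient of radius 2-3.5 voxels placed inside the WM
#' core with enough separation that shell structures of different
#' lesions stay disjoint, tissue means from the reference tables,
#' lesion-to-shell radial profiles and across-lesion SDs from the
#' lesion-level reference table, between-subject SDs set to a quarter of
#' the printed subject-mean ranges, and per-biomarker voxel noise of
#' typical map-noise magnitude. The per-lesion heterogeneity effect uses
#' one shared factor per (lesion, biomarker), scaled by the
#' class-specific SD; the factor is drawn from a standard normal
#' truncated at +/-1.5, which preserves the radial ordering of every
#' lesion (and hence the strict per-patient lesion-vs-PL ordering the
#' reference cohort exhibits for all nine biomarkers) while keeping the
#' across-lesion spread proportional to the reference SDs.
#'
#' @param dim grid extent (integer, scalar or length 3).
#' @param spacing voxel size in mm.
#' @param lesionCountRange integer(2) lesions per MS subject.
#' @param lesionRadiusRange numeric(2) lesion radius range in voxels
#'   (must be >= 2 so that one-voxel erosion cannot empty a lesion).
#' @param sigmaVoxel named per-biomarker voxel noise SD; `NULL` for the
#'   defaults, or a single number to scale the defaults.
#' @param sigmaSubjectScale multiplier on the between-subject SDs.
#' @param sigmaLesionScale multiplier on the per-lesion heterogeneity SDs.
#' @param missingModality emulate the study dropout (QSM absent for
#'   exactly one control subject).
#' @param values value tables as returned by [defaultValueTable()].
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = 64, spacing = c(1, 1, 1),
                        lesionCountRange = c(2L, 4L),
                        lesionRadiusRange = c(2, 3.5),
                        sigmaVoxel = NULL, sigmaSubjectScale = 1,
                        sigmaLesionScale = 1, missingModality = TRUE,
                        values = defaultValueTable()) {
  bm <- .bm()
  if (length(dim) == 1L) dim <- rep(dim, 3L)
  sv <- c(MWF = 1.5, MTsat = 0.12, ihMTR = 0.8, qT1 = 50, qT2 = 5,
          qT2star = 5, PD = 1.5, QSM = 6, T1wT2w = 0.12)
  if (is.null(sigmaVoxel)) sigmaVoxel <- sv
  else if (length(sigmaVoxel) == 1L && is.null(names(sigmaVoxel)))
    sigmaVoxel <- sv * sigmaVoxel
  tis <- values$tissue
  sigmaSubject <- data.frame(
    gm_HC = (tis$gm_HC_max - tis$gm_HC_min) / 4,
    gm_MS = (tis$gm_MS_max - tis$gm_MS_min) / 4,
    wm_HC = (tis$wm_HC_max - tis$wm_HC_min) / 4,
    wm_MS = (tis$wm_MS_max - tis$wm_MS_min) / 4,
    row.names = bm) * sigmaSubjectScale
  new("PhantomSpec",
      dim = as.integer(dim), spacing = as.numeric(spacing),
      geometry = list(brain = c(0.88, 0.84, 0.80), wm = c(0.62, 0.58, 0.55)),
      lesionCountRange = as.integer(lesionCountRange),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      valueTable = tis, radialProfile = values$radialProfile,
      radialSD = values$radialSD, sigmaVoxel = sigmaVoxel[bm],
      sigmaSubject = sigmaSubject, sigmaLesionScale = sigmaLesionScale,
      missingModality = isTRUE(missingModality))
}

#' Remove all randomness-bearing noise from a PhantomSpec
#'
#' Returns a copy with voxel, subject and lesion variability set to
#' zero, so every voxel equals its configured class value exactly —
#' the setting used for ground-truth recovery checks.
#'
#' @param spec a [PhantomSpec-class].
#' @return The noise-free [PhantomSpec-class].
#' @export
noiseFree <- function(spec) {
  spec@sigmaVoxel[] <- 0
  spec@sigmaSubject[] <- 0
  spec@sigmaLesionScale <- 0
  spec
}

# Squared ellipsoid coordinate for every voxel; semi = semi-axes in voxels.
.ellipsoidField <- function(d, semi) {
  ctr <- (d + 1) / 2
  x2 <- ((seq_len(d[1]) - ctr[1]) / semi[1])^2
  y2 <- ((seq_len(d[2]) - ctr[2]) / semi[2])^2
  z2 <- ((seq_len(d[3]) - ctr[3]) / semi[3])^2
  outer(outer(x2, y2, "+"), z2, "+")
}

# Place lesions by sampling centres from the eligible voxel set. The
# centre separation (rA + rB + 10) keeps the full shell structures of
# different lesions disjoint (each surround reaches ~r + 4 voxels from
# the centre), so per-lesion VOI values never contaminate each other.
# Placement is restarted from scratch on failure; an error is raised
# only after the retry budget is exhausted.
.placeLesions <- function(spec, wmField, maxRestarts = 60L) {
  d <- spec@dim
  nLes <- if (spec@lesionCountRange[1] == spec@lesionCountRange[2])
    spec@lesionCountRange[1] else
    sample(spec@lesionCountRange[1]:spec@lesionCountRange[2], 1L)
  half <- min(d * spec@geometry$wm) / 2
  co <- arrayInd(seq_len(prod(d)), d)
  for (attempt in seq_len(maxRestarts)) {
    centres <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    ok <- TRUE
    for (k in seq_len(nLes)) {
      r <- stats::runif(1, spec@lesionRadiusRange[1],
                        spec@lesionRadiusRange[2])
      # shrink the WM ellipsoid so the whole lesion stays inside WM
      shrink <- (half - (r + 2)) / half
      if (shrink <= 0) stop("lesion radius too large for the WM core")
      elig <- wmField <= shrink^2
      for (j in seq_len(nrow(centres))) {
        gap <- r + radii[j] + 10
        dd <- sqrt(rowSums(sweep(co, 2, centres[j, ])^2))
        elig <- elig & array(dd > gap, d)
      }
      eligIdx <- which(elig)
      if (length(eligIdx) == 0L) { ok <- FALSE; break }
      ci <- eligIdx[sample.int(length(eligIdx), 1L)]
      centres <- rbind(centres, arrayInd(ci, d))
      radii <- c(radii, r)
    }
    if (ok) return(list(centres = centres, radii = radii))
  }
  stop("infeasible lesion placement after ", maxRestarts, " restarts")
}

# Shared per-(lesion, biomarker) heterogeneity factor: standard normal
# truncated at +/-1.5. The smallest gap-to-SD-difference ratio across the
# nine biomarkers is ~1.6 (qT2), so bounding the factor below that keeps
# the class ordering of every lesion intact, as observed per patient in
# the reference cohort; unbounded draws would flip it occasionally.
.lesionFactor <- function(n) {
  lo <- stats::pnorm(-1.5)
  stats::qnorm(stats::runif(n, lo, 1 - lo))
}

.sphereMask <- function(d, centre, radius) {
  x2 <- (seq_len(d[1]) - centre[1])^2
  y2 <- (seq_len(d[2]) - centre[2])^2
  z2 <- (seq_len(d[3]) - centre[3])^2
  outer(outer(x2, y2, "+"), z2, "+") <= radius^2
}

#' Generate one synthetic subject
#'
#' Deterministic given `(spec, seed)`: builds the nested-ellipsoid
#' geometry, places lesions (MS only), classifies each voxel through the
#' very same VOI-geometry code path used by the analysis
#' ([buildVOISet()]), assigns tissue / radial-profile values plus
#' subject, lesion and voxel noise, and records a ground truth
#' sufficient to predict every noise-free VOI mean exactly.
#'
#' @param spec a [PhantomSpec-class].
#' @param group `"MS"` or `"HC"`.
#' @param seed integer seed for this subject's substream.
#' @param id subject identifier.
#' @return Named list: `id`, `group`, `lesionMask`, `gmProb`, `wmProb`
#'   ([MRVolume-class]), `maps` (named list of the nine biomarker
#'   volumes), `missing` (character vector of absent modalities, filled
#'   by the cohort generator), and `groundTruth` (subject effects,
#'   lesion table, per-lesion effects, and `predicted`: a data.frame of
#'   exact noise-free means per biomarker and VOI).
#' @export
generateSubject <- function(spec, group = c("MS", "HC"), seed = 1L,
                            id = "s1") {
  group <- match.arg(group)
  set.seed(as.integer(seed))
  d <- spec@dim
  grid <- referenceGrid(d, spec@spacing)
  brainField <- .ellipsoidField(d, d * spec@geometry$brain / 2)
  wmField <- .ellipsoidField(d, d * spec@geometry$wm / 2)
  wmRegion <- wmField <= 1
  gmRegion <- brainField <= 1 & !wmRegion
  brain <- wmRegion | gmRegion
  gmProb <- mrVolume(array(as.numeric(gmRegion), d), grid@affine)
  wmProb <- mrVolume(array(as.numeric(wmRegion), d), grid@affine)
  bm <- .bm()
  grpSuffix <- if (group == "MS") "MS" else "HC"
  # 1) subject effects, 2) lesion placement, 3) lesion effects, 4) voxel
  # noise -- fixed draw order keeps subjects bit-reproducible
  subjEff <- matrix(stats::rnorm(length(bm) * 2), length(bm), 2,
                    dimnames = list(bm, c("gm", "wm")))
  subjEff[, "gm"] <- subjEff[, "gm"] *
    spec@sigmaSubject[bm, paste0("gm_", grpSuffix)]
  subjEff[, "wm"] <- subjEff[, "wm"] *
    spec@sigmaSubject[bm, paste0("wm_", grpSuffix)]

  lesionMaskA <- array(FALSE, d)
  lesions <- data.frame(lesion = integer(0), cx = numeric(0),
                        cy = numeric(0), cz = numeric(0), radius = numeric(0))
  lesEff <- matrix(numeric(0), 0, length(bm), dimnames = list(NULL, bm))
  vois <- NULL
  if (group == "MS") {
    pl <- .placeLesions(spec, wmField)
    for (k in seq_along(pl$radii))
      lesionMaskA <- lesionMaskA | .sphereMask(d, pl$centres[k, ], pl$radii[k])
    lesions <- data.frame(lesion = seq_along(pl$radii),
                          cx = pl$centres[, 1], cy = pl$centres[, 2],
                          cz = pl$centres[, 3], radius = pl$radii)
    u <- matrix(.lesionFactor(length(pl$radii) * length(bm)),
                length(pl$radii), length(bm), dimnames = list(NULL, bm))
    lesEff <- u * spec@sigmaLesionScale
    vois <- buildVOISet(lesionMaskA, gmProb, wmProb, common = NULL,
                        params = voiParams())
  }
  lesionMask <- mrVolume(array(as.numeric(lesionMaskA), d), grid@affine)

  classes <- c("lesion", "pl", "shell1", "shell2", "shell3")
  maps <- list()
  predicted <- list()
  gmVal <- spec@valueTable[bm, paste0("gm_", grpSuffix)]
  wmVal <- spec@valueTable[bm, paste0("wm_", grpSuffix)]
  names(gmVal) <- names(wmVal) <- bm
  for (b in bm) {
    clean <- array(NaN, d)
    clean[gmRegion] <- gmVal[b] + subjEff[b, "gm"]
    clean[wmRegion] <- wmVal[b] + subjEff[b, "wm"]
    if (!is.null(vois)) {
      per <- retainedLesions(vois)
      for (k in seq_along(per)) {
        lid <- as.integer(sub("^lesion", "", names(per)[k]))
        for (cl in classes) {
          clean[per[[k]][[cl]]] <- spec@radialProfile[b, cl] +
            lesEff[lid, b] * spec@radialSD[b, cl]
        }
      }
      # pre-erosion rim voxels not claimed by any VOI class keep the PL
      # value of their lesion (they are excluded from analysis anyway
      # under the pre-erosion exclusion reading)
      rim <- lesionMaskA & !voiMask(vois, "lesion") & !voiMask(vois, "pl")
      if (any(rim)) {
        rimIdx <- which(rim)
        for (k in seq_along(per)) {
          lid <- as.integer(sub("^lesion", "", names(per)[k]))
          near <- .sphereMask(d, as.numeric(lesions[lid, c("cx", "cy", "cz")]),
                              lesions$radius[lid] + 0.5)
          hit <- rimIdx[near[rimIdx]]
          clean[hit] <- spec@radialProfile[b, "pl"] +
            lesEff[lid, b] * spec@radialSD[b, "pl"]
        }
      }
      for (k in seq_along(per)) {
        lid <- as.integer(sub("^lesion", "", names(per)[k]))
        for (cl in classes) {
          m <- voiMean(clean, per[[k]][[cl]])
          predicted[[length(predicted) + 1L]] <-
            data.frame(biomarker = b, voi = cl, level = "lesion",
                       lesion_id = lid, predicted = m$value,
                       stringsAsFactors = FALSE)
        }
      }
      for (vn in c("lesion", "pl", "wm", "gm")) {
        m <- voiMean(clean, voiMask(vois, vn))
        predicted[[length(predicted) + 1L]] <-
          data.frame(biomarker = b, voi = vn, level = "subject",
                     lesion_id = NA_integer_, predicted = m$value,
                     stringsAsFactors = FALSE)
      }
    } else {
      for (vn in c("wm", "gm")) {
        reg <- if (vn == "wm") wmRegion else gmRegion
        predicted[[length(predicted) + 1L]] <-
          data.frame(biomarker = b, voi = vn, level = "subject",
                     lesion_id = NA_integer_,
                     predicted = mean(clean[reg]), stringsAsFactors = FALSE)
      }
    }
    noisy <- clean
    if (spec@sigmaVoxel[b] > 0) {
      nb <- sum(brain)
      noisy[brain] <- noisy[brain] + stats::rnorm(nb, 0, spec@sigmaVoxel[b])
    }
    maps[[b]] <- mrVolume(noisy, grid@affine, biomarkerUnits()[b])
  }
  list(id = id, group = group, lesionMask = lesionMask, gmProb = gmProb,
       wmProb = wmProb, maps = maps, missing = character(0),
       groundTruth = list(subjectEffects = subjEff, lesions = lesions,
                          lesionEffects = lesEff,
                          predicted = do.call(rbind, predicted)))
}

# Substream rule: the seed of subject i is a fixed affine function of the
# master seed and the subject index, so adding subjects never perturbs
# the streams of existing ones.
.subjectSeed <- function(masterSeed, index) {
  (as.integer(masterSeed) %% 100003L) * 10007L + 131L * as.integer(index)
}

#' Generate a synthetic cohort
#'
#' Generates `nMs` patient and `nHc` control subjects with per-subject
#' seeds derived from the master seed by a fixed substream rule. When the
#' spec's `missingModality` flag is set and at least one control exists,
#' the first control lacks its QSM map (emulating a scan that could not
#' be performed). When `dir` is given the cohort is also written to disk
#' as per-subject NIfTI files plus a manifest CSV and ground-truth JSON.
#'
#' @param spec a [PhantomSpec-class].
#' @param nMs,nHc group sizes (defaults 13 and 14, the reference cohort).
#' @param seed master seed.
#' @param dir optional output directory.
#' @return Named list: `subjects` (list of [generateSubject()] results),
#'   `manifest` (data.frame subject/group/seed/missing), `spec`, `seed`.
#' @export
generateCohort <- function(spec, nMs = 13, nHc = 14, seed = 1L, dir = NULL) {
  stopifnot(nMs >= 0, nHc >= 0)
  subjects <- list()
  manifest <- list()
  idx <- 0L
  for (i in seq_len(nMs)) {
    idx <- idx + 1L
    id <- sprintf("MS%02d", i)
    subjects[[id]] <- generateSubject(spec, "MS", .subjectSeed(seed, idx), id)
    manifest[[idx]] <- data.frame(subject = id, group = "MS",
                                  seed = .subjectSeed(seed, idx),
                                  missing = "", stringsAsFactors = FALSE)
  }
  for (i in seq_len(nHc)) {
    idx <- idx + 1L
    id <- sprintf("HC%02d", i)
    sub <- generateSubject(spec, "HC", .subjectSeed(seed, idx), id)
    if (spec@missingModality && i == 1L) {
      sub$maps$QSM <- NULL
      sub$missing <- "QSM"
      sub$groundTruth$predicted <-
        sub$groundTruth$predicted[sub$groundTruth$predicted$biomarker != "QSM", ]
    }
    subjects[[id]] <- sub
    manifest[[idx]] <- data.frame(subject = id, group = "HC",
                                  seed = .subjectSeed(seed, idx),
                                  missing = paste(sub$missing, collapse = ";"),
                                  stringsAsFactors = FALSE)
  }
  cohort <- list(subjects = subjects,
                 manifest = if (idx) do.call(rbind, manifest) else
                   data.frame(subject = character(0), group = character(0),
                              seed = integer(0), missing = character(0)),
                 spec = spec, seed = as.integer(seed))
  if (!is.null(dir)) writeCohort(cohort, dir)
  cohort
}

#' Write / read a synthetic cohort on disk
#'
#' `writeCohort` stores one directory per subject (NIfTI biomarker maps,
#' lesion mask and tissue-probability maps), a cohort `manifest.csv`, a
#' per-subject map manifest `maps.csv` (map name, file, units) and the
#' ground truth as JSON. `readCohort` restores the same in-memory layout
#' from such a directory.
#'
#' @param cohort a cohort list from [generateCohort()].
#' @param dir directory path.
#' @return `writeCohort`: `dir`, invisibly; `readCohort`: a cohort list.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (sub in cohort$subjects) {
    sd <- file.path(dir, sub$id)
    dir.create(sd, showWarnings = FALSE)
    writeVolume(sub$lesionMask, file.path(sd, "lesion_mask.nii.gz"))
    writeVolume(sub$gmProb, file.path(sd, "gm_prob.nii.gz"),
                datatype = "double")
    writeVolume(sub$wmProb, file.path(sd, "wm_prob.nii.gz"),
                datatype = "double")
    for (b in names(sub$maps)) {
      f <- file.path(sd, paste0(b, ".nii.gz"))
      writeVolume(sub$maps[[b]], f, datatype = "double")
      rows[[length(rows) + 1L]] <-
        data.frame(subject = sub$id, group = sub$group, map = b,
                   file = file.path(sub$id, paste0(b, ".nii.gz")),
                   units = biomarkerUnits()[b], stringsAsFactors = FALSE)
    }
    gt <- sub$groundTruth
    jsonlite::write_json(
      list(subjectEffects = as.data.frame(gt$subjectEffects),
           lesions = gt$lesions, predicted = gt$predicted),
      file.path(sd, "ground_truth.json"), dataframe = "columns",
      digits = NA, na = "null")
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  maps <- do.call(rbind, rows)
  utils::write.csv(maps, file.path(dir, "maps.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(missing = "character"))
  maps <- utils::read.csv(file.path(dir, "maps.csv"),
                          stringsAsFactors = FALSE)
  subjects <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject[i]
    sd <- file.path(dir, id)
    panel <- list()
    for (j in which(maps$subject == id)) {
      panel[[maps$map[j]]] <- readVolume(file.path(dir, maps$file[j]),
                                         units = maps$units[j])
    }
    subjects[[id]] <- list(
      id = id, group = manifest$group[i],
      lesionMask = readVolume(file.path(sd, "lesion_mask.nii.gz")),
      gmProb = readVolume(file.path(sd, "gm_prob.nii.gz")),
      wmProb = readVolume(file.path(sd, "wm_prob.nii.gz")),
      maps = panel,
      missing = if (nzchar(manifest$missing[i]))
        strsplit(manifest$missing[i], ";")[[1]] else character(0),
      groundTruth = NULL)
  }
  list(subjects = subjects, manifest = manifest, spec = NULL, seed = NA)
}

#' Simulate subject-level biomarker means from the generator's model
#'
#' The distribution-level view of the phantom: instead of rendering 3D
#' volumes, draw the per-subject VOI means directly from the same
#' statistical model the voxel generator implements (tissue mean +
#' between-subject effect; per-lesion shared heterogeneity factor scaled
#' by class SD, averaged over the subject's lesions). This is the fast
#' path for calibration studies that need hundreds or thousands of
#' cohort replicates (type-I error, sign-structure rates); the rendered
#' phantom and this model agree by construction up to voxel-noise terms
#' that are negligible after VOI averaging.
#'
#' @param spec a [PhantomSpec-class].
#' @param nMs,nHc group sizes.
#' @param seed integer seed.
#' @param nullEffect when TRUE both groups are drawn from the control
#'   distribution (no group effect anywhere) — the global-null setting.
#' @return Subject-level cohort table (see [lesionLevelTable()] for the
#'   record layout).
#' @export
simulateSubjectMeans <- function(spec, nMs = 13, nHc = 14, seed = 1L,
                                 nullEffect = FALSE) {
  set.seed(as.integer(seed))
  bm <- .bm()
  nB <- length(bm)
  subj <- character(0); grp <- character(0); biom <- character(0)
  voi <- character(0); val <- numeric(0)
  for (i in seq_len(nMs + nHc)) {
    g <- if (i <= nMs) "MS" else "HC"
    id <- if (g == "MS") sprintf("MS%02d", i) else sprintf("HC%02d", i - nMs)
    eff <- if (nullEffect) "HC" else g
    gmv <- spec@valueTable[bm, paste0("gm_", eff)] +
      stats::rnorm(nB) * spec@sigmaSubject[bm, paste0("gm_", eff)]
    wmv <- spec@valueTable[bm, paste0("wm_", eff)] +
      stats::rnorm(nB) * spec@sigmaSubject[bm, paste0("wm_", eff)]
    subj <- c(subj, rep(id, 2L * nB)); grp <- c(grp, rep(g, 2L * nB))
    biom <- c(biom, bm, bm)
    voi <- c(voi, rep("gm", nB), rep("wm", nB))
    val <- c(val, gmv, wmv)
    if (g == "MS") {
      nLes <- if (spec@lesionCountRange[1] == spec@lesionCountRange[2])
        spec@lesionCountRange[1] else
        sample(spec@lesionCountRange[1]:spec@lesionCountRange[2], 1L)
      u <- matrix(.lesionFactor(nLes * nB), nLes, nB) * spec@sigmaLesionScale
      ubar <- colMeans(u)
      les <- spec@radialProfile[bm, "lesion"] + ubar * spec@radialSD[bm, "lesion"]
      plv <- spec@radialProfile[bm, "pl"] + ubar * spec@radialSD[bm, "pl"]
      subj <- c(subj, rep(id, 2L * nB)); grp <- c(grp, rep(g, 2L * nB))
      biom <- c(biom, bm, bm)
      voi <- c(voi, rep("lesion", nB), rep("pl", nB))
      val <- c(val, les, plv)
    }
  }
  data.frame(subject = subj, group = grp, biomarker = biom, voi = voi,
             level = "subject", lesion_id = NA_integer_, value = val,
             n_voxels = NA_integer_, stringsAsFactors = FALSE)
}
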