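#' @include voi-geometry.R
NULL

#' Mean biomarker value inside a VOI
#'
#' Arithmetic mean of the map over the mask voxels that carry a valid
#' (non-missing) value, together with the number of voxels that
#' contributed. An empty effective mask yields `value = NA, n = 0`
#' (undefined, never zero): callers decide whether to drop or propagate.
#'
#' @param map an [MRVolume-class] (or 3D array) parameter map.
#' @param mask binary mask (MRVolume, logical array) or integer vector of
#'   linear voxel indices.
#' @return List with `value` and `n` (contributing voxel count).
#' @export
voiMean <- function(map, mask) {
  a <- if (is(map, "MRVolume")) map@data else map
  idx <- if (is.numeric(mask) && is.null(dim(mask))) as.integer(mask)
         else which(.asMaskArray(mask))
  v <- a[idx]
  v <- v[!is.nan(v) & !is.na(v)]
  if (length(v) == 0L) list(value = NA_real_, n = 0L)
  else list(value = mean(v), n = length(v))
}

.emptyCohort <- function() {
  data.frame(subject = character(0), group = character(0),
             biomarker = character(0), voi = character(0),
             level = character(0), lesion_id = integer(0),
             value = numeric(0), n_voxels = integer(0),
             stringsAsFactors = FALSE)
}

#' Lesion-level biomarker table
#'
#' One mean per retained lesion, biomarker and VOI class (lesion, PL,
#' shells 1-3), each lesion's surround treated independently. VOI classes
#' emptied by the white-matter intersection yield an `NA` value with
#' `n_voxels = 0` (flagged undefined) so the table keeps its full
#' cardinality of lesions x biomarkers x 5.
#'
#' @param panel named list of [MRVolume-class] maps (subset of the
#'   nine-biomarker panel; absent modalities are simply not listed).
#' @param vois a [VOISet-class] with per-lesion VOIs.
#' @param subject subject identifier.
#' @param group group label (`"MS"` or `"HC"`).
#' @return Long-format data.frame of cohort-table records.
#' @export
lesionLevelTable <- function(panel, vois, subject = "s1", group = "MS") {
  stopifnot(is(vois, "VOISet"))
  classes <- c("lesion", "pl", "shell1", "shell2", "shell3")
  per <- retainedLesions(vois)
  rows <- vector("list", length(per) * length(panel) * length(classes))
  r <- 0L
  for (k in seq_along(per)) {
    lid <- as.integer(sub("^lesion", "", names(per)[k]))
    for (bm in names(panel)) {
      for (cl in classes) {
        m <- voiMean(panel[[bm]], per[[k]][[cl]])
        r <- r + 1L
        rows[[r]] <- data.frame(subject = subject, group = group,
                                biomarker = bm, voi = cl, level = "lesion",
                                lesion_id = lid, value = m$value,
                                n_voxels = m$n, stringsAsFactors = FALSE)
      }
    }
  }
  if (r == 0L) .emptyCohort() else do.call(rbind, rows[seq_len(r)])
}

#' Subject-level biomarker summary
#'
#' Per-subject means in the applicable VOIs. For an MS subject: the
#' average lesion and perilesion values (`lesion`, `pl` — voxel-pooled
#' means over the union masks, so subjects contribute through voxels,
#' not lesion counts), plus normal-appearing WM and GM. For a control:
#' WM and GM only. Undefined cells (empty VOI after restriction, or a
#' modality absent from `panel`) produce no record.
#'
#' @inheritParams lesionLevelTable
#' @param avgMode `"pooled"` (default): lesion/PL averages are
#'   voxel-pooled over union masks; `"perLesionMean"`: unweighted mean of
#'   per-lesion means.
#' @return Long-format data.frame of subject-level records.
#' @export
subjectLevelSummary <- function(panel, vois, subject = "s1", group = "HC",
                                avgMode = c("pooled", "perLesionMean")) {
  stopifnot(is(vois, "VOISet"))
  avgMode <- match.arg(avgMode)
  voisNeeded <- if (group == "MS") c("lesion", "pl", "wm", "gm")
                else c("wm", "gm")
  rows <- list()
  for (bm in names(panel)) {
    for (vn in voisNeeded) {
      if (vn %in% c("lesion", "pl") && avgMode == "perLesionMean") {
        per <- retainedLesions(vois)
        means <- vapply(per, function(pk) voiMean(panel[[bm]], pk[[vn]])$value,
                        numeric(1))
        ns <- vapply(per, function(pk) voiMean(panel[[bm]], pk[[vn]])$n,
                     integer(1))
        means <- means[!is.na(means)]
        m <- if (length(means)) list(value = mean(means), n = sum(ns))
             else list(value = NA_real_, n = 0L)
      } else {
        m <- voiMean(panel[[bm]], voiMask(vois, vn))
      }
      if (m$n == 0L) next
      rows[[length(rows) + 1L]] <-
        data.frame(subject = subject, group = group, biomarker = bm,
                   voi = vn, level = "subject", lesion_id = NA_integer_,
                   value = m$value, n_voxels = m$n, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else .emptyCohort()
}

#' Group-level medians and ranges
#'
#' Cohort medians (and min-max ranges) of the per-subject biomarker
#' means, one cell per (biomarker, VOI, group). Even-sized samples use
#' the midpoint-of-central-order-statistics median. Empty cells are
#' omitted.
#'
#' @param cohort a long-format cohort table (see [lesionLevelTable()]).
#' @return data.frame with `biomarker`, `voi`, `group`, `median`, `min`,
#'   `max`, `n`.
#' @export
groupLevelMedians <- function(cohort) {
  s <- cohort[cohort$level == "subject" & !is.na(cohort$value), , drop = FALSE]
  if (nrow(s) == 0L)
    return(data.frame(biomarker = character(0), voi = character(0),
                      group = character(0), median = numeric(0),
                      min = numeric(0), max = numeric(0), n = integer(0)))
  key <- interaction(s$biomarker, s$voi, s$group, drop = TRUE)
  out <- do.call(rbind, lapply(split(s, key), function(g) {
    data.frame(biomarker = g$biomarker[1], voi = g$voi[1], group = g$group[1],
               median = stats::median(g$value), min = min(g$value),
               max = max(g$value), n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$biomarker, out$voi, out$group), , drop = FALSE]
}

#' Extract the full cohort table for one subject
#'
#' Convenience wrapper combining [subjectLevelSummary()] and (for MS
#' subjects) [lesionLevelTable()].
#'
#' @inheritParams subjectLevelSummary
#' @return Long-format data.frame.
#' @export
extractSubject <- function(panel, vois, subject, group,
                           avgMode = "pooled") {
  out <- subjectLevelSummary(panel, vois, subject, group, avgMode)
  if (group == "MS")
    out <- rbind(out, lesionLevelTable(panel, vois, subject, group))
  out
}
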