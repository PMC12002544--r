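#' @include phantom.R stats.R
NULL

#' Analyze one subject: resampling, common volume, VOIs, extraction
#'
#' The per-subject pipeline: every biomarker map is brought onto the
#' subject's reference grid (the grid of the lesion mask) by trilinear
#' interpolation — masks and probability maps by nearest neighbour — the
#' subject-specific common imaging volume is computed as the
#' intersection of the coverage of all available maps, the full VOI set
#' is built restricted to that volume, and subject- plus lesion-level
#' records are extracted.
#'
#' @param sub subject list with `id`, `group`, `lesionMask`, `gmProb`,
#'   `wmProb`, `maps` (as produced by [generateSubject()] or
#'   [readCohort()]).
#' @param params VOI parameters from [voiParams()].
#' @param avgMode lesion averaging mode, see [subjectLevelSummary()].
#' @return List with `records` (long-format cohort rows), `vois`
#'   ([VOISet-class]) and `common` (binary [MRVolume-class]).
#' @export
analyzeSubject <- function(sub, params = voiParams(), avgMode = "pooled") {
  grid <- gridOf(sub$lesionMask)
  panel <- lapply(sub$maps, resampleTrilinear, grid = grid)
  gmProb <- resampleNearest(sub$gmProb, grid)
  wmProb <- resampleNearest(sub$wmProb, grid)
  common <- commonImagingVolume(panel)
  vois <- buildVOISet(sub$lesionMask, gmProb, wmProb, common, params)
  records <- extractSubject(panel, vois, sub$id, sub$group, avgMode)
  list(records = records, vois = vois, common = common)
}

#' Analyze a whole cohort
#'
#' Runs [analyzeSubject()] over every subject and assembles the
#' long-format cohort table driving all statistics and reports.
#'
#' @param cohort cohort list from [generateCohort()] or [readCohort()].
#' @inheritParams analyzeSubject
#' @return List with `table` (cohort table) and `dropped` (data.frame of
#'   dropped lesions per subject).
#' @export
analyzeCohort <- function(cohort, params = voiParams(), avgMode = "pooled") {
  tabs <- list()
  drops <- list()
  for (sub in cohort$subjects) {
    res <- analyzeSubject(sub, params, avgMode)
    tabs[[sub$id]] <- res$records
    dd <- droppedLesions(res$vois)
    if (nrow(dd)) {
      dd$subject <- sub$id
      drops[[sub$id]] <- dd
    }
  }
  list(table = do.call(rbind, c(tabs, list(make.row.names = FALSE))),
       dropped = if (length(drops)) do.call(rbind, drops) else
         data.frame(label = integer(0), n_voxels = integer(0),
                    reason = character(0), subject = character(0)))
}
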