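#' @include pipeline.R
NULL

.fmtNum <- function(x, digits = 2) {
  ifelse(is.na(x), "-", sprintf(paste0("%.", digits, "f"), x))
}

.fmtCell <- function(med, mn, mx, digits = 2) {
  ifelse(is.na(med), "-",
         sprintf("%s (%s; %s)", .fmtNum(med, digits), .fmtNum(mn, digits),
                 .fmtNum(mx, digits)))
}

.fmtP <- function(p, rejected) {
  ifelse(is.na(p), "-",
         paste0(sprintf("%.3f", p), ifelse(!is.na(rejected) & rejected,
                                           "*", "")))
}

.lookupMed <- function(gm, b, vn, grp) {
  r <- gm[gm$biomarker == b & gm$voi == vn & gm$group == grp, , drop = FALSE]
  if (nrow(r) == 0L) c(NA_real_, NA_real_, NA_real_)
  else c(r$median, r$min, r$max)
}

.lookupTest <- function(res, cn, b) {
  r <- res[res$contrast == cn & res$biomarker == b, , drop = FALSE]
  if (nrow(r) == 0L) list(p = NA_real_, rejected = NA)
  else list(p = r$p[1], rejected = r$rejected[1])
}

#' Group-level result tables
#'
#' Two formatted tables of cohort medians with "median (min; max)" cells
#' and p-value columns carrying an FDR significance marker (`*` iff the
#' BH procedure rejects). `groups`: per biomarker, GM and WM medians of
#' both groups with the two group-contrast p-values. `msTissues`: per
#' biomarker, the MS-patient medians in lesion, PL, NAWM and NAGM with
#' the five within-patient contrast p-values. Missing cells render
#' as `-`.
#'
#' @param cohort long-format cohort table.
#' @param battery result of [runTestBattery()].
#' @param digits formatting precision (default 2, matching the field's
#'   reporting conventions).
#' @return List of data.frames `groups`, `msTissues`, plus the numeric
#'   `medians` the cells were formatted from.
#' @export
makeGroupTables <- function(cohort, battery, digits = 2) {
  gm <- groupLevelMedians(cohort)
  res <- battery$results
  bms <- intersect(biomarkerNames(), unique(cohort$biomarker))
  un <- biomarkerUnits()
  rowLabel <- function(b) {
    if (nzchar(un[b])) sprintf("%s [%s]", b, un[b]) else b
  }
  groups <- do.call(rbind, lapply(bms, function(b) {
    gHC <- .lookupMed(gm, b, "gm", "HC"); gMS <- .lookupMed(gm, b, "gm", "MS")
    wHC <- .lookupMed(gm, b, "wm", "HC"); wMS <- .lookupMed(gm, b, "wm", "MS")
    tg <- .lookupTest(res, "HCGM-vs-NAGM", b)
    tw <- .lookupTest(res, "HCWM-vs-NAWM", b)
    data.frame(biomarker = rowLabel(b),
               gm_hc = .fmtCell(gHC[1], gHC[2], gHC[3], digits),
               gm_ms = .fmtCell(gMS[1], gMS[2], gMS[3], digits),
               p_gm = .fmtP(tg$p, tg$rejected),
               wm_hc = .fmtCell(wHC[1], wHC[2], wHC[3], digits),
               wm_ms = .fmtCell(wMS[1], wMS[2], wMS[3], digits),
               p_wm = .fmtP(tw$p, tw$rejected), stringsAsFactors = FALSE)
  }))
  msTissues <- do.call(rbind, lapply(bms, function(b) {
    les <- .lookupMed(gm, b, "lesion", "MS")
    pl <- .lookupMed(gm, b, "pl", "MS")
    wm <- .lookupMed(gm, b, "wm", "MS")
    g <- .lookupMed(gm, b, "gm", "MS")
    tt <- lapply(c("lesion-vs-PL", "lesion-vs-NAWM", "lesion-vs-NAGM",
                   "PL-vs-NAWM", "PL-vs-NAGM"), .lookupTest, res = res, b = b)
    data.frame(biomarker = rowLabel(b),
               lesion = .fmtCell(les[1], les[2], les[3], digits),
               pl = .fmtCell(pl[1], pl[2], pl[3], digits),
               nawm = .fmtCell(wm[1], wm[2], wm[3], digits),
               nagm = .fmtCell(g[1], g[2], g[3], digits),
               p_lesion_vs_pl = .fmtP(tt[[1]]$p, tt[[1]]$rejected),
               p_lesion_vs_nawm = .fmtP(tt[[2]]$p, tt[[2]]$rejected),
               p_lesion_vs_nagm = .fmtP(tt[[3]]$p, tt[[3]]$rejected),
               p_pl_vs_nawm = .fmtP(tt[[4]]$p, tt[[4]]$rejected),
               p_pl_vs_nagm = .fmtP(tt[[5]]$p, tt[[5]]$rejected),
               stringsAsFactors = FALSE)
  }))
  list(groups = groups, msTissues = msTissues, medians = gm)
}

#' Lesion-level shell table
#'
#' Across-lesion mean (SD) of the per-lesion biomarker means in lesion,
#' PL and shells 1-3. With a single lesion the SD is reported as 0 and
#' flagged (`sd_defined = FALSE`).
#'
#' @param cohort long-format cohort table containing lesion-level records.
#' @param digits formatting precision.
#' @return List with `stats` (numeric: biomarker, voi, mean, sd, n,
#'   sd_defined) and `formatted` (one "mean (SD)" cell per biomarker x
#'   class).
#' @export
makeShellTable <- function(cohort, digits = 2) {
  l <- cohort[cohort$level == "lesion" & !is.na(cohort$value), , drop = FALSE]
  classes <- c("lesion", "pl", "shell1", "shell2", "shell3")
  bms <- intersect(biomarkerNames(), unique(l$biomarker))
  rows <- list()
  for (b in bms) for (cl in classes) {
    v <- l$value[l$biomarker == b & l$voi == cl]
    if (length(v) == 0L) next
    rows[[length(rows) + 1L]] <-
      data.frame(biomarker = b, voi = cl, mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 n = length(v), sd_defined = length(v) > 1L,
                 stringsAsFactors = FALSE)
  }
  statsDf <- do.call(rbind, rows)
  formatted <- do.call(rbind, lapply(bms, function(b) {
    cells <- vapply(classes, function(cl) {
      r <- statsDf[statsDf$biomarker == b & statsDf$voi == cl, , drop = FALSE]
      if (nrow(r) == 0L) "-"
      else sprintf("%s (%s)", .fmtNum(r$mean, digits), .fmtNum(r$sd, digits))
    }, character(1))
    as.data.frame(as.list(c(biomarker = b, cells)), stringsAsFactors = FALSE)
  }))
  list(stats = statsDf, formatted = formatted)
}

#' Export tidy plot-data files
#'
#' Writes the data behind the standard figures as tidy CSV, separated
#' from any rendering so the testable surface is data, not pixels:
#' `boxplot.csv` (per-subject means per VOI and group), `lineplot.csv`
#' (per-patient trajectories over lesion, PL, NAWM, NAGM plus the cohort
#' mean trajectory), `violin.csv` (one record per lesion per VOI class)
#' and `spider.csv` (cohort medians per biomarker in HCWM, NAWM, avgPL,
#' avgLesion).
#'
#' @param cohort long-format cohort table.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
exportPlotData <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- cohort[cohort$level == "subject" & !is.na(cohort$value), , drop = FALSE]
  files <- c()
  box <- s[order(s$biomarker, s$voi, s$group, s$subject),
           c("subject", "group", "biomarker", "voi", "value")]
  f <- file.path(dir, "boxplot.csv")
  utils::write.csv(box, f, row.names = FALSE)
  files["boxplot"] <- f

  ms <- s[s$group == "MS" & s$voi %in% c("lesion", "pl", "wm", "gm"), ,
          drop = FALSE]
  traj <- ms[order(ms$biomarker, ms$subject,
                   match(ms$voi, c("lesion", "pl", "wm", "gm"))),
             c("subject", "biomarker", "voi", "value")]
  meanRows <- do.call(rbind, lapply(split(ms, list(ms$biomarker, ms$voi),
                                          drop = TRUE), function(g) {
    data.frame(subject = "cohort-mean", biomarker = g$biomarker[1],
               voi = g$voi[1], value = mean(g$value),
               stringsAsFactors = FALSE)
  }))
  meanRows <- meanRows[order(meanRows$biomarker,
                             match(meanRows$voi,
                                   c("lesion", "pl", "wm", "gm"))), ]
  f <- file.path(dir, "lineplot.csv")
  utils::write.csv(rbind(traj, meanRows), f, row.names = FALSE)
  files["lineplot"] <- f

  l <- cohort[cohort$level == "lesion" & !is.na(cohort$value), , drop = FALSE]
  f <- file.path(dir, "violin.csv")
  utils::write.csv(
    l[order(l$biomarker, l$voi, l$subject, l$lesion_id),
      c("subject", "lesion_id", "biomarker", "voi", "value", "n_voxels")],
    f, row.names = FALSE)
  files["violin"] <- f

  gm <- groupLevelMedians(cohort)
  spider <- do.call(rbind, lapply(intersect(biomarkerNames(),
                                            unique(s$biomarker)),
                                  function(b) {
    data.frame(biomarker = b,
               hcwm = .lookupMed(gm, b, "wm", "HC")[1],
               nawm = .lookupMed(gm, b, "wm", "MS")[1],
               avgPL = .lookupMed(gm, b, "pl", "MS")[1],
               avgLesion = .lookupMed(gm, b, "lesion", "MS")[1],
               stringsAsFactors = FALSE)
  }))
  f <- file.path(dir, "spider.csv")
  utils::write.csv(spider, f, row.names = FALSE)
  files["spider"] <- f
  files
}

#' Qualitative sensitivity summary per biomarker
#'
#' Condenses the battery and shell statistics into the per-biomarker
#' diagnostic overview: (a) whether the three focal contrasts (lesion vs
#' PL, lesion vs NAWM, PL vs NAWM) are all FDR-significant; (b) the
#' signed absolute and relative NAWM-vs-HCWM median difference and its
#' rank across biomarkers (largest |relative difference| first); (c) a
#' lesion-heterogeneity flag: across-lesion SD in the lesion class
#' exceeding the shell-3 SD by more than `sdRatioThreshold`. No single
#' hard criterion for "most promising" is imposed; ranks and thresholds
#' are exposed instead.
#'
#' @param battery result of [runTestBattery()].
#' @param shellStats the `stats` element of [makeShellTable()].
#' @param medians numeric medians from [makeGroupTables()] (or
#'   [groupLevelMedians()]).
#' @param sdRatioThreshold heterogeneity threshold on the lesion/shell-3
#'   SD ratio (default 1.5).
#' @return data.frame with one row per biomarker.
#' @export
sensitivitySummary <- function(battery, shellStats, medians,
                               sdRatioThreshold = 1.5) {
  res <- battery$results
  bms <- intersect(biomarkerNames(), unique(res$biomarker))
  rows <- do.call(rbind, lapply(bms, function(b) {
    focal <- vapply(c("lesion-vs-PL", "lesion-vs-NAWM", "PL-vs-NAWM"),
                    function(cn) {
                      t <- .lookupTest(res, cn, b)
                      isTRUE(t$rejected)
                    }, logical(1))
    hcwm <- .lookupMed(medians, b, "wm", "HC")[1]
    nawm <- .lookupMed(medians, b, "wm", "MS")[1]
    absDiff <- nawm - hcwm
    relDiff <- if (!is.na(hcwm) && abs(hcwm) > .Machine$double.eps)
      100 * absDiff / abs(hcwm) else NA_real_
    sdl <- shellStats$sd[shellStats$biomarker == b &
                         shellStats$voi == "lesion"]
    sd3 <- shellStats$sd[shellStats$biomarker == b &
                         shellStats$voi == "shell3"]
    ratio <- if (length(sdl) && length(sd3) && sd3 > 0) sdl / sd3 else
      NA_real_
    data.frame(biomarker = b, focal_contrasts_significant = all(focal),
               nawm_abs_diff = absDiff, nawm_rel_diff_pct = relDiff,
               lesion_sd_ratio = ratio,
               heterogeneous_lesions = !is.na(ratio) &
                 ratio > sdRatioThreshold,
               stringsAsFactors = FALSE)
  }))
  rows$nawm_rank <- rank(-abs(rows$nawm_rel_diff_pct), ties.method = "min",
                         na.last = "keep")
  rows
}
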