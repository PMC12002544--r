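#' @include AllClasses.R
NULL

.hasTies <- function(x) anyDuplicated(x) > 0L

#' Mann-Whitney U test (two-sided)
#'
#' Nonparametric test for a location difference between two independent
#' samples, used for the between-group contrasts (control vs
#' normal-appearing tissue). The exact null distribution of U is used
#' when the smaller sample is at most `exactThreshold` and there are no
#' ties across the pooled sample; otherwise the midrank, tie-corrected
#' normal approximation with continuity correction is used. The study's
#' group sizes (13 and 14) sit comfortably in the exact regime.
#'
#' @param x,y numeric samples (non-empty).
#' @param exactThreshold largest min(n1, n2) for exact enumeration.
#' @return A [TestResult-class]; the statistic is U for `x` relative to
#'   `y`. Swapping `x` and `y` leaves the two-sided p unchanged.
#' @export
mannWhitneyU <- function(x, y, exactThreshold = 25) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- sum(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= exactThreshold && ties == 0L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  new("TestResult", method = "Mann-Whitney U",
      statistic = unname(wt$statistic),
      n = c(length(x), length(y)), p = min(unname(wt$p.value), 1),
      exact = exact, ties = as.integer(ties), zeros = 0L)
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Nonparametric test for paired samples, used for the within-patient
#' tissue contrasts (lesion vs PL vs normal-appearing tissue). Zero
#' differences are dropped (classical convention). The exact null
#' distribution (all sign patterns) is used when the effective n is at
#' most `exactThreshold` and there are no tied absolute differences;
#' otherwise the normal approximation with continuity correction.
#' If every difference is zero the test is undecidable: p = 1 with the
#' zero count recorded.
#'
#' @param x,y paired numeric samples of equal length; pairs with a
#'   missing member are dropped.
#' @param exactThreshold largest effective n for exact enumeration.
#' @return A [TestResult-class]; the statistic is the signed-rank sum V.
#' @export
wilcoxonSignedRank <- function(x, y, exactThreshold = 25) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  if (length(d) == 0L) stop("no complete pairs")
  zeros <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(new("TestResult", method = "Wilcoxon signed-rank", statistic = 0,
               n = 0L, p = 1, exact = TRUE, ties = 0L,
               zeros = as.integer(zeros)))
  }
  ties <- sum(duplicated(abs(d)))
  exact <- length(d) <= exactThreshold && ties == 0L
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)
  )
  new("TestResult", method = "Wilcoxon signed-rank",
      statistic = unname(wt$statistic), n = length(d),
      p = min(unname(wt$p.value), 1), exact = exact,
      ties = as.integer(ties), zeros = as.integer(zeros))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Step-up procedure over one family of m tests: order the p-values
#' ascending, find the largest rank i with p_(i) <= i/m * alpha, and
#' reject hypotheses 1..i. Adjusted p-values are the standard BH
#' adjustment (computed via [stats::p.adjust()]); the per-rank critical
#' values i/m * alpha are reported alongside, since results in this
#' field are often quoted against the rank-1 critical value
#' ("q-value") rather than the adjusted p.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @param family family label for bookkeeping.
#' @return An [FDRResult-class]; `critical` is in sorted order, `adjusted`
#'   and `rejected` in input order.
#' @export
benjaminiHochberg <- function(p, alpha = 0.05, family = "") {
  if (length(p) == 0L) stop("empty p-value family")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  critical <- seq_len(m) / m * alpha
  adjusted <- stats::p.adjust(p, method = "BH")
  ps <- sort(p)
  ok <- which(ps <= critical)
  thresh <- if (length(ok)) ps[max(ok)] else -Inf
  new("FDRResult", p = p, critical = critical, adjusted = adjusted,
      rejected = p <= thresh, alpha = alpha, family = family)
}

#' Run the full statistical battery on a subject-level cohort table
#'
#' Reproduces the study's test layout: per biomarker, Mann-Whitney U for
#' the two independent group contrasts (control WM vs normal-appearing
#' WM; control GM vs normal-appearing GM) and Wilcoxon signed-rank for
#' the five within-patient contrasts (lesion vs PL, lesion vs WM, lesion
#' vs GM, PL vs WM, PL vs GM) — 63 tests in total. BH-FDR correction is
#' applied within each contrast family of nine biomarker tests (the
#' family structure implied by the reported rank-1 critical value
#' 0.05/9 ≈ 0.006); `familyMode` can widen the family to all 63 tests.
#' Subjects with a missing cell are excluded pairwise for that test.
#'
#' @param cohort long-format cohort table with subject-level records.
#' @param alpha significance / FDR level (default 0.05).
#' @param familyMode `"contrast"` (default): one BH family per contrast;
#'   `"global"`: a single family over all tests; `"none"`: no correction.
#' @param exactThreshold passed to the tests.
#' @return List with `results` (one row per test: contrast, biomarker,
#'   method, statistic, n1, n2, p, exact, adjusted p, rank-1 critical
#'   value of its family, rejected flag) and `fdr` (named list of
#'   [FDRResult-class], one per family).
#' @export
runTestBattery <- function(cohort, alpha = 0.05,
                           familyMode = c("contrast", "global", "none"),
                           exactThreshold = 25) {
  familyMode <- match.arg(familyMode)
  s <- cohort[cohort$level == "subject" & !is.na(cohort$value), , drop = FALSE]
  bms <- intersect(biomarkerNames(), unique(s$biomarker))
  cell <- function(bm, grp, vn) {
    r <- s[s$biomarker == bm & s$group == grp & s$voi == vn, , drop = FALSE]
    stats::setNames(r$value, r$subject)
  }
  groupContrasts <- list(
    "HCWM-vs-NAWM" = "wm",
    "HCGM-vs-NAGM" = "gm"
  )
  pairedContrasts <- list(
    "lesion-vs-PL"   = c("lesion", "pl"),
    "lesion-vs-NAWM" = c("lesion", "wm"),
    "lesion-vs-NAGM" = c("lesion", "gm"),
    "PL-vs-NAWM"     = c("pl", "wm"),
    "PL-vs-NAGM"     = c("pl", "gm")
  )
  rows <- list()
  for (cn in names(groupContrasts)) {
    vn <- groupContrasts[[cn]]
    for (bm in bms) {
      hc <- cell(bm, "HC", vn); ms <- cell(bm, "MS", vn)
      if (length(hc) == 0L || length(ms) == 0L) next
      tr <- mannWhitneyU(hc, ms, exactThreshold)
      rows[[length(rows) + 1L]] <-
        data.frame(contrast = cn, biomarker = bm, method = tr@method,
                   statistic = tr@statistic, n1 = tr@n[1], n2 = tr@n[2],
                   p = tr@p, exact = tr@exact, stringsAsFactors = FALSE)
    }
  }
  for (cn in names(pairedContrasts)) {
    vv <- pairedContrasts[[cn]]
    for (bm in bms) {
      a <- cell(bm, "MS", vv[1]); b <- cell(bm, "MS", vv[2])
      subj <- intersect(names(a), names(b))
      if (length(subj) == 0L) next
      tr <- wilcoxonSignedRank(a[subj], b[subj], exactThreshold)
      rows[[length(rows) + 1L]] <-
        data.frame(contrast = cn, biomarker = bm, method = tr@method,
                   statistic = tr@statistic, n1 = tr@n[1], n2 = tr@n[1],
                   p = tr@p, exact = tr@exact, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contrast = character(0), biomarker = character(0),
               method = character(0), statistic = numeric(0),
               n1 = integer(0), n2 = integer(0), p = numeric(0),
               exact = logical(0))
  res$p_adjusted <- NA_real_
  res$q_critical_rank1 <- NA_real_
  res$rejected <- NA
  fdr <- list()
  if (nrow(res)) {
    fams <- switch(familyMode,
      contrast = split(seq_len(nrow(res)), res$contrast),
      global = list(global = seq_len(nrow(res))),
      none = NULL)
    if (is.null(fams)) {
      res$p_adjusted <- res$p
      res$rejected <- res$p <= alpha
    } else {
      for (fn in names(fams)) {
        ii <- fams[[fn]]
        f <- benjaminiHochberg(res$p[ii], alpha, family = fn)
        fdr[[fn]] <- f
        res$p_adjusted[ii] <- f@adjusted
        res$q_critical_rank1[ii] <- f@critical[1]
        res$rejected[ii] <- f@rejected
      }
    }
  }
  list(results = res, fdr = fdr, alpha = alpha, familyMode = familyMode)
}
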