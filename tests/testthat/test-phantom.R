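test_that("default value tables carry the reference cohort structure", {
  vt <- defaultValueTable()
  expect_equal(vt$tissue["MWF", "wm_HC"], 11.50)
  expect_equal(vt$tissue["MWF", "wm_MS"], 10.97)
  expect_equal(vt$subjectLesion["qT1", "lesion"], 1403.50)
  expect_equal(vt$subjectLesion["qT1", "pl"], 1050.30)
  expect_equal(unlist(vt$radialProfile["T1wT2w", ], use.names = FALSE),
               c(0.80, 1.54, 1.68, 1.73, 1.77))
  # lesion-to-shell3 qT1 profile is monotone decreasing
  expect_true(all(diff(unlist(vt$radialProfile["qT1", ])) < 0))
  # across-lesion SDs are larger in the lesion than in shell 3 for the
  # relaxometry/susceptibility markers
  for (b in c("qT1", "qT2", "qT2star", "PD", "QSM"))
    expect_gt(vt$radialSD[b, "lesion"], vt$radialSD[b, "shell3"])
})

test_that("subject generation is deterministic and lesion counts are exact", {
  spec <- phantomSpec(dim = 48, lesionCountRange = c(2L, 2L))
  a <- generateSubject(spec, "MS", seed = 9, id = "x")
  b <- generateSubject(spec, "MS", seed = 9, id = "x")
  expect_identical(lapply(a$maps, volData), lapply(b$maps, volData))
  expect_identical(volData(a$lesionMask), volData(b$lesionMask))
  c2 <- generateSubject(spec, "MS", seed = 10, id = "x")
  expect_false(identical(volData(a$lesionMask), volData(c2$lesionMask)))
  expect_identical(names(a$maps), names(c2$maps))

  comps <- labelLesions(a$lesionMask)
  expect_equal(lesionCount(comps), 2L)
  # lesions lie inside the WM region
  expect_true(all(volData(a$wmProb)[volData(a$lesionMask) == 1] == 1))
})

test_that("noise-free subjects take exactly the configured class values", {
  spec <- noiseFree(phantomSpec(dim = 48, lesionCountRange = c(2L, 2L)))
  sub <- generateSubject(spec, "MS", seed = 12, id = "x")
  vt <- defaultValueTable()
  mwf <- volData(sub$maps$MWF)
  wmR <- volData(sub$wmProb) == 1
  gmR <- volData(sub$gmProb) == 1
  vois <- buildVOISet(sub$lesionMask, sub$gmProb, sub$wmProb)
  surround <- voiMask(vois, "lesion") | voiMask(vois, "pl") |
    voiMask(vois, "shell1") | voiMask(vois, "shell2") |
    voiMask(vois, "shell3") | (volData(sub$lesionMask) == 1)
  expect_true(all(mwf[wmR & !surround] == vt$tissue["MWF", "wm_MS"]))
  expect_true(all(mwf[gmR] == vt$tissue["MWF", "gm_MS"]))
  expect_true(all(is.nan(mwf[!wmR & !gmR])))
  # HC subjects have no lesions at all
  hc <- generateSubject(spec, "HC", seed = 12, id = "h")
  expect_equal(sum(volData(hc$lesionMask)), 0)
})

test_that("cohort generation handles sizes, substreams and the missing modality", {
  spec <- noiseFree(phantomSpec(dim = 48, lesionCountRange = c(2L, 2L)))
  coh <- generateCohort(spec, nMs = 2, nHc = 2, seed = 5)
  expect_equal(length(coh$subjects), 4L)
  expect_equal(coh$manifest$group, c("MS", "MS", "HC", "HC"))
  # the first control lacks QSM; everyone else has the full panel
  expect_false("QSM" %in% names(coh$subjects$HC01$maps))
  expect_equal(coh$subjects$HC01$missing, "QSM")
  expect_true("QSM" %in% names(coh$subjects$HC02$maps))
  expect_equal(length(coh$subjects$MS01$maps), 9L)
  # adding subjects never changes the streams of existing ones
  big <- generateCohort(spec, nMs = 3, nHc = 2, seed = 5)
  expect_identical(volData(big$subjects$MS01$lesionMask),
                   volData(coh$subjects$MS01$lesionMask))
  # HC-only cohorts are valid
  hcOnly <- generateCohort(spec, nMs = 0, nHc = 2, seed = 5)
  expect_equal(unique(hcOnly$manifest$group), "HC")
})

test_that("cohorts round-trip through disk", {
  spec <- noiseFree(phantomSpec(dim = 32, lesionCountRange = c(1L, 1L),
                                lesionRadiusRange = c(2, 2.5)))
  dir <- withr::local_tempdir()
  coh <- generateCohort(spec, nMs = 1, nHc = 1, seed = 2, dir = dir)
  back <- readCohort(dir)
  expect_setequal(names(back$subjects), names(coh$subjects))
  expect_equal(volData(back$subjects$MS01$maps$MWF),
               volData(coh$subjects$MS01$maps$MWF), tolerance = 1e-12)
  expect_identical(volData(back$subjects$MS01$lesionMask),
                   volData(coh$subjects$MS01$lesionMask))
  expect_equal(back$subjects$HC01$missing, "QSM")
})

test_that("simulated subject means show group overlap but no perfect separation", {
  spec <- phantomSpec()
  sep <- 0L
  for (s in 1:5) {
    tab <- simulateSubjectMeans(spec, 13, 14, seed = s)
    for (b in biomarkerNames()) {
      hc <- tab$value[tab$group == "HC" & tab$voi == "wm" &
                      tab$biomarker == b]
      ms <- tab$value[tab$group == "MS" & tab$voi == "wm" &
                      tab$biomarker == b]
      if (max(ms) < min(hc) || max(hc) < min(ms)) sep <- sep + 1L
    }
  }
  expect_equal(sep, 0L)  # distributions overlap for every biomarker
})

test_that("lesion heterogeneity: lesion-class SD exceeds shell-3 SD where configured", {
  spec <- phantomSpec(dim = 48, lesionCountRange = c(2L, 2L))
  tabs <- list()
  for (i in 1:10) {
    sub <- generateSubject(spec, "MS", seed = 100 + i, id = sprintf("m%d", i))
    res <- analyzeSubject(sub)
    tabs[[i]] <- res$records
  }
  shell <- makeShellTable(do.call(rbind, tabs))$stats
  for (b in c("qT1", "qT2", "qT2star", "PD")) {
    sdl <- shell$sd[shell$biomarker == b & shell$voi == "lesion"]
    sd3 <- shell$sd[shell$biomarker == b & shell$voi == "shell3"]
    expect_gt(sdl, sd3)
  }
})
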