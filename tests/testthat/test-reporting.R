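makeSmallRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantomSpec(dim = 48, lesionCountRange = c(1L, 2L))
      coh <- generateCohort(spec, nMs = 8, nHc = 4, seed = 11)
      ana <- analyzeCohort(coh)
      bat <- runTestBattery(ana$table)
      cache <<- list(cohort = coh, table = ana$table, battery = bat)
    }
    cache
  }
})

test_that("group tables follow the median (range) + p-value layout", {
  run <- makeSmallRun()
  tabs <- makeGroupTables(run$table, run$battery)
  expect_equal(nrow(tabs$groups), 9L)
  expect_named(tabs$groups, c("biomarker", "gm_hc", "gm_ms", "p_gm",
                              "wm_hc", "wm_ms", "p_wm"))
  expect_equal(nrow(tabs$msTissues), 9L)
  expect_equal(ncol(tabs$msTissues), 10L)  # 4 value + 5 p columns + label
  expect_true(all(grepl("^-?\\d+\\.\\d{2} \\(-?\\d+\\.\\d{2}; -?\\d+\\.\\d{2}\\)$",
                        tabs$msTissues$lesion)))
  # significance markers appear exactly where the FDR rejects
  res <- run$battery$results
  for (i in seq_len(nrow(tabs$msTissues))) {
    b <- sub(" \\[.*", "", tabs$msTissues$biomarker[i])
    r <- res[res$contrast == "lesion-vs-PL" & res$biomarker == b, ]
    expect_equal(grepl("\\*$", tabs$msTissues$p_lesion_vs_pl[i]),
                 r$rejected)
  }
})

test_that("table cells re-derive from the serialized cohort table", {
  run <- makeSmallRun()
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cohort_table.csv")
  write.csv(run$table, f, row.names = FALSE)
  tab2 <- read.csv(f, stringsAsFactors = FALSE)
  # independent recomputation of one printed cell
  v <- tab2$value[tab2$level == "subject" & tab2$group == "MS" &
                  tab2$biomarker == "qT1" & tab2$voi == "lesion"]
  cell <- sprintf("%.2f (%.2f; %.2f)", median(v), min(v), max(v))
  tabs <- makeGroupTables(run$table, run$battery)
  expect_equal(tabs$msTissues$lesion[tabs$msTissues$biomarker == "qT1 [ms]"],
               cell)
})

test_that("shell table reports mean (SD) and flags degenerate SDs", {
  run <- makeSmallRun()
  shell <- makeShellTable(run$table)
  expect_equal(nrow(shell$formatted), 9L)
  expect_named(shell$formatted, c("biomarker", "lesion", "pl", "shell1",
                                  "shell2", "shell3"))
  expect_true(all(shell$stats$n >= 2))
  l <- run$table[run$table$level == "lesion" & !is.na(run$table$lesion_id), ]
  single <- l[l$subject == l$subject[1] & l$lesion_id == l$lesion_id[1], ]
  s1 <- makeShellTable(single)
  expect_true(all(s1$stats$sd == 0))
  expect_false(any(s1$stats$sd_defined))
})

test_that("plot-data exports have the documented cardinalities", {
  run <- makeSmallRun()
  dir <- withr::local_tempdir()
  files <- exportPlotData(run$table, dir)
  expect_true(all(file.exists(files)))
  box <- read.csv(files["boxplot"])
  sdf <- run$table[run$table$level == "subject" & !is.na(run$table$value), ]
  expect_equal(nrow(box), nrow(sdf))
  line <- read.csv(files["lineplot"])
  nMS <- length(unique(sdf$subject[sdf$group == "MS"]))
  expect_equal(nrow(line), 9 * (nMS + 1) * 4)  # subjects + cohort mean
  violin <- read.csv(files["violin"])
  lesRows <- sum(run$table$level == "lesion" & !is.na(run$table$value))
  expect_equal(nrow(violin), lesRows)
  spider <- read.csv(files["spider"])
  expect_equal(nrow(spider), 9L)
  expect_named(spider, c("biomarker", "hcwm", "nawm", "avgPL", "avgLesion"))
})

test_that("sensitivity summary flags heterogeneous lesion biomarkers", {
  run <- makeSmallRun()
  tabs <- makeGroupTables(run$table, run$battery)
  shell <- makeShellTable(run$table)
  sens <- sensitivitySummary(run$battery, shell$stats, tabs$medians)
  expect_equal(nrow(sens), 9L)
  # the focal flag is the conjunction of the three focal FDR decisions
  res <- run$battery$results
  for (b in sens$biomarker) {
    expected <- all(vapply(c("lesion-vs-PL", "lesion-vs-NAWM", "PL-vs-NAWM"),
                           function(cn) res$rejected[res$contrast == cn &
                                                     res$biomarker == b],
                           logical(1)))
    expect_equal(sens$focal_contrasts_significant[sens$biomarker == b],
                 expected)
  }
  # lesion-vs-PL separates by construction for every biomarker
  expect_true(all(res$rejected[res$contrast == "lesion-vs-PL"]))
  for (b in c("qT1", "qT2", "qT2star", "PD"))
    expect_true(sens$heterogeneous_lesions[sens$biomarker == b])
  expect_false(sens$heterogeneous_lesions[sens$biomarker == "MWF"])
  expect_equal(sort(sens$nawm_rank), sort(rank(-abs(sens$nawm_rel_diff_pct),
                                               ties.method = "min")))
})

test_that("the CLI validates configuration before computing", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.yaml")
  writeLines("tissue_threshold: 1.5", bad)
  expect_equal(cliMain(c("simulate", "--out", file.path(dir, "o"),
                         "--config", bad)), 2L)
  expect_false(dir.exists(file.path(dir, "o")))
  expect_equal(cliMain(c("frobnicate", "--out", dir)), 2L)
  expect_equal(cliMain(character(0)), 0L)  # usage
})

test_that("HC-only simulation produces a control-only dataset", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "hconly")
  cfg <- file.path(dir, "cfg.yaml")
  writeLines(c("dim: 32", "n_hc: 2", "n_ms: 0", "noise: false",
               "lesion_radius: [2.0, 2.5]"), cfg)
  status <- cliMain(c("simulate", "--out", out, "--config", cfg,
                      "--seed", "3"))
  expect_equal(status, 0L)
  man <- read.csv(file.path(out, "manifest.csv"))
  expect_equal(unique(man$group), "HC")
  expect_equal(nrow(man), 2L)
})
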