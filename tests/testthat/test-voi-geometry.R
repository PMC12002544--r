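test_that("perilesional shell of a single-voxel lesion in uniform WM", {
  d <- c(13, 13, 13)
  w <- makeWorld(d, c(7, 7, 7))
  pl <- perilesionShell(w$lesion, w$wm, w$lesion)
  expect_equal(sum(pl), 32L)  # 33-offset ball minus the lesion voxel
  expect_identical(which(pl),
                   which(oracleDistanceLE(d, which(w$lesion), 2) & !w$lesion))

  # WM mask hole removes that voxel from PL
  holed <- w$wm
  holed[8, 7, 7] <- FALSE
  pl2 <- perilesionShell(w$lesion, holed, w$lesion)
  expect_equal(sum(pl2), 31L)
  expect_false(pl2[8, 7, 7])

  # a second lesion voxel inside the shell region is excluded from PL
  les2 <- w$lesion
  les2[9, 7, 7] <- TRUE
  pl3 <- perilesionShell(w$lesion, w$wm, les2)
  expect_false(pl3[9, 7, 7])
  expect_error(perilesionShell(w$lesion, array(TRUE, c(5, 5, 5)), w$lesion),
               "mismatch")
})

test_that("shells 1-3 are disjoint and match the distance-transform oracle", {
  d <- c(17, 17, 17)
  w <- makeWorld(d, c(9, 9, 9))
  pl <- perilesionShell(w$lesion, w$wm, w$lesion)
  inner <- w$lesion | pl
  s1 <- outerShell(1, pl, inner, w$wm); inner <- inner | s1
  s2 <- outerShell(2, pl, inner, w$wm); inner <- inner | s2
  s3 <- outerShell(3, pl, inner, w$wm)
  masks <- list(lesion = w$lesion, pl = pl, s1 = s1, s2 = s2, s3 = s3)
  for (i in seq_along(masks)) for (j in seq_along(masks)) {
    if (i < j) expect_false(any(masks[[i]] & masks[[j]]))
  }
  ref <- oraclePLShells(w$lesion, w$lesion, w$wm)
  expect_identical(which(s1), which(ref$shell1))
  expect_identical(which(s2), which(ref$shell2))
  expect_identical(which(s3), which(ref$shell3))

  # empty WM -> empty shells
  noWM <- array(FALSE, d)
  expect_false(any(outerShell(1, pl, inner, noWM)))
  expect_error(outerShell(4, pl, inner, w$wm), "1, 2 or 3")
})

test_that("PL and shells match the oracle on random lesion/WM configurations", {
  set.seed(20)
  for (i in 1:25) {
    d <- rep(sample(14:20, 1), 3)
    n <- sample(1:2, 1)
    w <- makeWorld(d)
    centres <- matrix(sample(5:(d[1] - 4), 3 * n, replace = TRUE), n, 3)
    for (k in seq_len(n)) {
      r <- runif(1, 1, 2.5)
      sph <- oracleDistanceLE(d, centres[k, 1] + d[1] * (centres[k, 2] - 1) +
                                 d[1] * d[2] * (centres[k, 3] - 1), r)
      w$lesion <- w$lesion | sph
    }
    wm <- array(runif(prod(d)) < 0.9, d)  # WM mask with random holes
    comps <- labelLesions(w$lesion)
    for (k in seq_len(lesionCount(comps))) {
      lk <- componentLabels(comps) == k
      pl <- perilesionShell(lk, wm, w$lesion)
      inner <- w$lesion | pl
      s1 <- outerShell(1, pl, inner, wm); inner <- inner | s1
      s2 <- outerShell(2, pl, inner, wm); inner <- inner | s2
      s3 <- outerShell(3, pl, inner, wm)
      ref <- oraclePLShells(lk, w$lesion, wm)
      expect_identical(which(pl), which(ref$pl))
      expect_identical(which(s1), which(ref$shell1))
      expect_identical(which(s2), which(ref$shell2))
      expect_identical(which(s3), which(ref$shell3))
    }
  }
})

test_that("shell dilations are nested", {
  set.seed(21)
  m <- array(runif(12^3) < 0.1, c(12, 12, 12))
  d1 <- dilateMask(m, makeBall(1))
  d2 <- dilateMask(m, makeBall(2))
  d3 <- dilateMask(m, makeBall(3))
  expect_true(all(d1[m])); expect_true(all(d2[d1])); expect_true(all(d3[d2]))
})

test_that("tissue thresholding is strict and excludes lesion voxels", {
  d <- c(5, 5, 5)
  gm <- array(0.95, d)
  wm <- array(0.2, d)
  wm[1, 1, 1] <- 0.9    # exactly at threshold: excluded
  wm[2, 2, 2] <- 0.99
  les <- array(FALSE, d)
  les[2, 2, 2] <- TRUE  # lesion voxel with high WM probability
  tm <- tissueMasks(mrVolume(gm), mrVolume(wm), les)
  expect_false(volData(tm$wm)[1, 1, 1] == 1)
  expect_false(volData(tm$wm)[2, 2, 2] == 1)
  expect_true(volData(tm$gm)[3, 3, 3] == 1)
  expect_false(volData(tm$gm)[2, 2, 2] == 1)
  expect_error(tissueMasks(mrVolume(array(1.2, d)), mrVolume(wm), les),
               "\\[0, 1\\]")
})

test_that("buildVOISet enforces its invariants and drop policies", {
  d <- c(20, 20, 20)
  les <- array(FALSE, d)
  les[5:7, 5:7, 5:7] <- TRUE           # survives erosion
  les[14, 14, 14] <- TRUE              # single voxel: emptied by erosion
  les[15, 14, 14] <- TRUE              # two-voxel lesion, also emptied
  gmP <- array(0, d)
  wmP <- array(1, d)
  vois <- buildVOISet(les, mrVolume(gmP), mrVolume(wmP))
  expect_s4_class(vois, "VOISet")
  expect_equal(lesionCount(vois), 1L)
  expect_equal(droppedLesions(vois)$reason, "emptied by erosion")
  expect_equal(sum(voiMask(vois, "lesion")), 1L)  # 3^3 cube erodes to centre

  # lesion footprint leaving the common volume is dropped with reason
  common <- array(TRUE, d)
  common[1:13, , ] <- FALSE
  les2 <- array(FALSE, d)
  les2[4:6, 10:12, 10:12] <- TRUE
  vois2 <- buildVOISet(les2, mrVolume(gmP), mrVolume(wmP),
                       mrVolume(common))
  expect_equal(lesionCount(vois2), 0L)
  expect_match(droppedLesions(vois2)$reason, "common")
  # trim-instead-of-drop keeps the covered part
  vois3 <- buildVOISet(les2, mrVolume(gmP), mrVolume(wmP), mrVolume(common),
                       voiParams(dropPartial = FALSE))
  for (nm in voiNames(vois3))
    expect_false(any(voiMask(vois3, nm) & !common))
})

test_that("union VOIs equal the union of per-lesion VOIs for separated lesions", {
  d <- c(26, 26, 26)
  les <- array(FALSE, d)
  les[4:6, 4:6, 4:6] <- TRUE
  les[18:20, 18:20, 18:20] <- TRUE
  vois <- buildVOISet(les, mrVolume(array(0, d)), mrVolume(array(1, d)))
  expect_equal(lesionCount(vois), 2L)
  per <- retainedLesions(vois)
  for (field in c("lesion", "pl", "shell1", "shell2", "shell3")) {
    u <- array(FALSE, d)
    for (pk in per) u[pk[[field]]] <- TRUE
    expect_identical(which(voiMask(vois, field)), which(u))
  }
  # NAWM keeps PL/shell voxels by default, excludes them on request
  expect_true(any(voiMask(vois, "wm") & voiMask(vois, "pl")))
  voisX <- buildVOISet(les, mrVolume(array(0, d)), mrVolume(array(1, d)),
                       params = voiParams(excludePerilesionFromWM = TRUE))
  expect_false(any(voiMask(voisX, "wm") & voiMask(voisX, "pl")))
})
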