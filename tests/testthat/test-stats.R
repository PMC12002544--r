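test_that("Mann-Whitney U: hand-enumerated cases", {
  t1 <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(t1@statistic, 0)
  expect_true(t1@exact)
  expect_equal(t1@p, 2 / 6)         # 2 of C(4,2)=6 assignments as extreme

  t2 <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t2@statistic, 0)
  expect_equal(t2@p, 2 / 20)        # 2 of C(6,3)=20 assignments

  t3 <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))  # identical multisets
  expect_equal(t3@p, 1)
  expect_false(t3@exact)            # ties force the approximation
  expect_error(mannWhitneyU(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney U matches full enumeration on random small samples", {
  set.seed(30)
  for (i in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1), 6); y <- round(rnorm(n2, 0.5), 6)
    got <- mannWhitneyU(x, y)
    expect_true(got@exact)
    expect_equal(got@p, oracleMWUp(x, y), tolerance = 1e-12)
    # two-sided p is symmetric in the sample order
    expect_equal(mannWhitneyU(y, x)@p, got@p, tolerance = 1e-12)
  }
})

test_that("Wilcoxon signed-rank: hand-enumerated and degenerate cases", {
  t1 <- wilcoxonSignedRank(c(1, 2, 3), c(2, 4, 6))
  expect_equal(t1@p, 2 / 8)         # all-negative signs, n = 3
  expect_true(t1@exact)

  t2 <- wilcoxonSignedRank(c(1, 5), c(1, 5))  # all zero differences
  expect_equal(t2@p, 1)
  expect_equal(t2@zeros, 2L)

  t3 <- wilcoxonSignedRank(1, 2)    # single pair
  expect_equal(t3@p, 1)

  # zero differences are dropped, not ranked
  t4 <- wilcoxonSignedRank(c(1, 2, 3, 9), c(1, 4, 6, 3))
  expect_equal(t4@zeros, 1L)
  expect_equal(t4@n, 3L)
  expect_error(wilcoxonSignedRank(1:3, 1:4), "equal length")
})

test_that("Wilcoxon signed-rank matches sign-pattern enumeration", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    x <- round(rnorm(n), 6); y <- round(rnorm(n, 0.3), 6)
    got <- wilcoxonSignedRank(x, y)
    expect_true(got@exact)
    expect_equal(got@p, oracleWSRp(x, y), tolerance = 1e-12)
  }
})

test_that("BH step-up: worked cases", {
  # nine-test family with minimum p = 0.048: the rank-1 critical value
  # 0.05/9 rounds to 0.006 and nothing survives
  p9 <- c(0.325, 0.259, 0.048, 0.325, 0.068, 0.202, 0.402, 0.579, 0.519)
  f <- benjaminiHochberg(p9, 0.05)
  expect_equal(round(criticalValues(f)[1], 3), 0.006)
  expect_equal(sum(rejected(f)), 0L)

  f1 <- benjaminiHochberg(0.03, 0.05)
  expect_equal(adjustedP(f1), 0.03)
  expect_true(rejected(f1))

  f3 <- benjaminiHochberg(c(0.01, 0.02, 0.04), 0.05)
  expect_equal(adjustedP(f3), c(0.03, 0.03, 0.04))
  expect_true(all(rejected(f3)))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH properties: order invariance, bracketing by Bonferroni and raw", {
  set.seed(32)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    f <- benjaminiHochberg(p, 0.05)
    perm <- sample(length(p))
    fp <- benjaminiHochberg(p[perm], 0.05)
    expect_equal(adjustedP(fp), adjustedP(f)[perm])
    expect_identical(rejected(fp), rejected(f)[perm])
    # BH rejects a subset of raw-alpha and a superset of Bonferroni
    expect_true(all(!rejected(f) | (p <= 0.05)))
    bonf <- p <= 0.05 / length(p)
    expect_true(all(!bonf | rejected(f)))
    # adjusted p monotone in raw-p order
    expect_false(is.unsorted(adjustedP(f)[order(p)]))
  }
})

test_that("the battery reproduces the 63-test layout with 7 families of 9", {
  spec <- phantomSpec()
  tab <- simulateSubjectMeans(spec, nMs = 13, nHc = 14, seed = 77)
  bat <- runTestBattery(tab)
  expect_equal(nrow(bat$results), 63L)
  expect_equal(length(bat$fdr), 7L)
  for (f in bat$fdr) expect_equal(length(f@p), 9L)
  expect_setequal(unique(bat$results$method[bat$results$contrast ==
                                            "HCWM-vs-NAWM"]),
                  "Mann-Whitney U")
  expect_setequal(unique(bat$results$method[bat$results$contrast ==
                                            "lesion-vs-PL"]),
                  "Wilcoxon signed-rank")
  expect_equal(unique(bat$results$n1[bat$results$contrast == "HCWM-vs-NAWM"]),
               14L)
  # strong focal contrasts should be detected with these group sizes
  focal <- bat$results[bat$results$contrast == "lesion-vs-PL", ]
  expect_true(all(focal$rejected))
})

test_that("a missing modality leads to pairwise subject exclusion", {
  spec <- phantomSpec()
  tab <- simulateSubjectMeans(spec, nMs = 13, nHc = 14, seed = 78)
  # drop the QSM records of one control, as when the scan was not acquired
  drop <- tab$subject == "HC01" & tab$biomarker == "QSM"
  bat <- runTestBattery(tab[!drop, ])
  res <- bat$results
  qsmN <- res$n1[res$contrast == "HCWM-vs-NAWM" & res$biomarker == "QSM"]
  expect_equal(qsmN, 13L)
  otherN <- res$n1[res$contrast == "HCWM-vs-NAWM" & res$biomarker == "MWF"]
  expect_equal(otherN, 14L)
})
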