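# Boundary semantics of the exclusion rules are pinned exactly:
# sample rule ">= 1%" inclusive, probe detection rule ">= 0.5%" inclusive,
# detection failure "p > 0.05" strict, beadcount "< 3" strict, "> 5 samples"
# strict.

test_that("sample detection rule: >= 1% failing is inclusive, > 0.05 strict", {
  m <- makeMset(1000, 4)
  dp <- detectionP(m)
  dp[1:10, 1] <- 0.06    # exactly 1.0% failing -> excluded
  dp[1:9, 2] <- 0.06     # 0.9% -> kept
  dp[1:50, 3] <- 0.05    # at the p threshold, not "in excess of" -> kept
  m <- MethylationSet(betas(m), dp, beadcounts(m))
  expect_equal(filterSamplesByDetection(m), "S001")
})

test_that("all-clean detection matrix excludes nothing", {
  m <- makeMset(100, 5, detp = 0)
  expect_length(filterSamplesByDetection(m), 0)
  expect_equal(nrow(filterProbes(m)), 0)
})

test_that("beadcount rule: < 3 strict, > 5 samples strict", {
  m <- makeMset(10, 20)
  bc <- beadcounts(m)
  bc[1, 1:5] <- 2L   # low in exactly 5 samples -> retained
  bc[2, 1:6] <- 2L   # low in 6 samples -> excluded
  bc[3, 1:7] <- 3L   # beadcount 3 is not "less than 3" -> retained
  m <- MethylationSet(betas(m), detectionP(m), bc)
  out <- filterProbes(m)
  expect_equal(out$probe, "cg0002")
  expect_equal(out$reason, "beadcount")
})

test_that("probe detection rule: >= 0.5% of samples is inclusive", {
  m <- makeMset(10, 200)
  dp <- detectionP(m)
  dp[1, 1] <- 0.06   # 1/200 = 0.5% -> excluded
  m <- MethylationSet(betas(m), dp, beadcounts(m))
  out <- filterProbes(m)
  expect_equal(out$probe, "cg0001")
  expect_equal(out$reason, "detection")
})

test_that("missing beadcount assay skips the rule with a warning", {
  m <- makeMset(10, 20)
  m2 <- MethylationSet(betas(m), detectionP(m))
  expect_warning(out <- filterProbes(m2), "beadcount")
  expect_equal(nrow(out), 0)
})

test_that("sex concordance flags exactly the swapped labels", {
  cc <- smallCohort(seed = 11, nFamilies = 30, generations = 1,
                    qcFail = list(samples = 0, detectionProbes = 0,
                                  beadcountProbes = 0, sexSwaps = 2))
  expect_equal(ncol(cc$sim$mset), 60)
  flagged <- checkSexConcordance(cc$sim$mset)
  expect_setequal(flagged, cc$sim$injected$sexSwaps)
  expect_length(flagged, 2)
  # concordant cohort: empty
  clean <- smallCohort(seed = 11, nFamilies = 30, generations = 1)
  expect_length(checkSexConcordance(clean$sim$mset), 0)
})

test_that("runQC applies rules in order and reconciles counts", {
  cc <- smallCohort(seed = 12, nFamilies = 20,
                    qcFail = list(samples = 3, detectionProbes = 2,
                                  beadcountProbes = 2, sexSwaps = 1))
  n <- ncol(cc$sim$mset); p <- nrow(cc$sim$mset)
  qc <- runQC(cc$sim$mset)
  expect_equal(unname(qcCounts(qc$report)$after),
               c(n - 4L, p - 4L))
  expect_setequal(excludedSamples(qc$report),
                  c(cc$sim$injected$failedSamples, cc$sim$injected$sexSwaps))
  expect_setequal(excludedProbes(qc$report),
                  c(cc$sim$injected$detectionProbes,
                    cc$sim$injected$beadcountProbes))
  # clean fixture passes through unchanged
  clean <- smallCohort(seed = 12, nFamilies = 20)
  qc0 <- runQC(clean$sim$mset)
  expect_identical(dim(qc0$mset), dim(clean$sim$mset))
  expect_length(excludedSamples(qc0$report), 0)
})

test_that("runQC is idempotent on its own output", {
  cc <- smallCohort(seed = 13, nFamilies = 20,
                    qcFail = list(samples = 2, detectionProbes = 2,
                                  beadcountProbes = 1, sexSwaps = 1))
  q1 <- runQC(cc$sim$mset)
  q2 <- runQC(q1$mset)
  expect_identical(dim(q2$mset), dim(q1$mset))
  expect_length(excludedSamples(q2$report), 0)
  expect_length(excludedProbes(q2$report), 0)
  expect_identical(betas(q2$mset), betas(q1$mset))
})

test_that("probe fractions are computed on samples surviving step 1", {
  # two-pass oracle: remove bad samples first, then evaluate probe rules on
  # the reduced matrices with plain arithmetic
  cc <- smallCohort(seed = 14, nFamilies = 25,
                    qcFail = list(samples = 3, detectionProbes = 3,
                                  beadcountProbes = 2, sexSwaps = 0))
  m <- cc$sim$mset
  qc <- runQC(m)
  keep <- setdiff(colnames(m), filterSamplesByDetection(m))
  dp <- detectionP(m)[, keep]
  bc <- beadcounts(m)[, keep]
  oracleBad <- rownames(m)[rowSums(bc < 3) > 5 |
                             rowMeans(dp > 0.05) >= 0.005]
  expect_setequal(excludedProbes(qc$report), oracleBad)
})

test_that("relaxing thresholds never excludes more items", {
  cc <- smallCohort(seed = 15, nFamilies = 20,
                    qcFail = list(samples = 3, detectionProbes = 3,
                                  beadcountProbes = 2, sexSwaps = 0))
  m <- cc$sim$mset
  strictS <- filterSamplesByDetection(m, 0.05, 0.01)
  relaxedS <- filterSamplesByDetection(m, 0.05, 0.05)
  expect_true(all(relaxedS %in% strictS))
  relaxedP <- filterSamplesByDetection(m, 0.2, 0.01)
  expect_true(all(relaxedP %in% strictS))
  strictPr <- filterProbes(m)$probe
  relaxedPr <- filterProbes(m, beadcountMaxSamples = 10,
                            failFraction = 0.05)$probe
  expect_true(all(relaxedPr %in% strictPr))
})

test_that("degenerate everything-excluded input raises a distinct error", {
  m <- makeMset(50, 4, detp = 0.9)
  expect_error(runQC(m), "every sample")
})
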