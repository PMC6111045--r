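test_that("bonferroni adjustment matches hand arithmetic and caps at 1", {
  out <- bonferroniAdjust(c(0.001, 0.5, 1), m = 12)
  expect_equal(out$p_adjusted, c(0.012, 1, 1))
  expect_equal(out$threshold, 0.0042)
  expect_equal(bonferroniAdjust(0.01, m = 3)$p_adjusted, 0.03)
  expect_error(bonferroniAdjust(c(0.1, 0.2), m = 1), "at least")
  expect_error(bonferroniAdjust(c(0, 0.1)), NULL)
})

test_that("the suite returns 24 rows, 12 per exposure, adjusted within exposure", {
  cc <- smallCohort(seed = 60, nFamilies = 40, generations = 3)
  qc <- runQC(cc$sim$mset)
  acc <- computeAcceleration(qc$mset, cc$sim$clocks$horvath,
                             cc$sim$clocks$hannum)
  A <- buildRelationshipMatrix(cc$ped)
  res <- runAssociationSuite(cc$phen$phenotypes, acc$accel, A,
                             chain = list(nIter = 600, burnin = 150,
                                          seed = 1))
  expect_equal(nrow(res), 24)
  expect_equal(as.vector(table(res$exposure)), c(12L, 12L))
  expect_setequal(res$risk_factor, riskFactorRoster())
  ok <- !is.na(res$p)
  expect_equal(res$p_adjusted[ok], pmin(1, 12 * res$p[ok]))
  expect_true(all(res$ci_low[ok] <= res$beta[ok] &
                    res$beta[ok] <= res$ci_high[ok]))
  expect_equal(attr(res, "threshold"), 0.0042)
})

test_that("missing phenotype columns are reported by name", {
  cc <- smallCohort(seed = 61, nFamilies = 10)
  ph <- cc$phen$phenotypes
  ph$bmi <- NULL
  ph$hdl <- NULL
  expect_error(
    runAssociationSuite(ph, data.frame(sample_id = ph$id, ieaa = 0, eeaa = 0),
                        buildRelationshipMatrix(cc$ped)),
    "bmi, hdl")
})

test_that("a strongly injected BMI effect is detected; null traits are not", {
  et <- nullEffectTable()
  et$ieaa[et$factor == "bmi"] <- 0.3
  et$eeaa[et$factor == "bmi"] <- 0.3
  cc <- smallCohort(seed = 62, nFamilies = 75, generations = 3,
                    effectTable = et)
  qc <- runQC(cc$sim$mset)
  acc <- computeAcceleration(qc$mset, cc$sim$clocks$horvath,
                             cc$sim$clocks$hannum)
  A <- buildRelationshipMatrix(cc$ped)
  res <- runAssociationSuite(cc$phen$phenotypes, acc$accel, A,
                             chain = list(nIter = 800, burnin = 200,
                                          seed = 2))
  bmi <- res[res$risk_factor == "bmi", ]
  expect_true(all(bmi$p_adjusted < 0.05))
  expect_true(all(bmi$beta > 0))
  nullG <- res[res$family == "gaussian" & res$risk_factor != "bmi", ]
  expect_lt(mean(nullG$p_adjusted < 0.05), 0.2)
})

test_that("permuted exposures produce no adjusted rejections (gaussian roster)", {
  gaussians <- defaultEffectTable()
  gaussians <- gaussians$factor[gaussians$family == "gaussian"]
  clear <- logical(4)
  for (r in 1:4) {
    cc <- smallCohort(seed = 70 + r, nFamilies = 40, generations = 3,
                      effectTable = nullEffectTable())
    qc <- runQC(cc$sim$mset)
    acc <- computeAcceleration(qc$mset, cc$sim$clocks$horvath,
                               cc$sim$clocks$hannum)
    perm <- withr::with_seed(80 + r, sample.int(nrow(acc$accel)))
    acc$accel$ieaa <- acc$accel$ieaa[perm]
    acc$accel$eeaa <- acc$accel$eeaa[perm]
    res <- runAssociationSuite(cc$phen$phenotypes, acc$accel,
                               buildRelationshipMatrix(cc$ped),
                               roster = gaussians)
    clear[r] <- all(res$p_adjusted > 0.05, na.rm = TRUE)
  }
  expect_gte(sum(clear), 3)
})

test_that("education can be analysed per unit instead of in SD units", {
  cc <- smallCohort(seed = 63, nFamilies = 40)
  qc <- runQC(cc$sim$mset)
  acc <- computeAcceleration(qc$mset, cc$sim$clocks$horvath,
                             cc$sim$clocks$hannum)
  A <- buildRelationshipMatrix(cc$ped)
  rSd <- runAssociationSuite(cc$phen$phenotypes, acc$accel, A,
                             roster = "education")
  rUnit <- runAssociationSuite(cc$phen$phenotypes, acc$accel, A,
                               roster = "education", educationPerUnit = TRUE)
  ids <- intersect(cc$phen$phenotypes$id, acc$accel$sample_id)
  sdEdu <- sd(cc$phen$phenotypes$education[match(ids, cc$phen$phenotypes$id)])
  expect_equal(rUnit$beta, rSd$beta * sdEdu, tolerance = 1e-6)
})

test_that("male excess acceleration is recovered in direction", {
  # inject a sex effect directly in the acceleration table and check the
  # fitted sex difference
  cc <- smallCohort(seed = 64, nFamilies = 60, generations = 2)
  qc <- runQC(cc$sim$mset)
  acc <- computeAcceleration(qc$mset, cc$sim$clocks$horvath,
                             cc$sim$clocks$hannum)
  ph <- cc$phen$phenotypes
  male <- ph$sex[match(acc$accel$sample_id, ph$id)] == "male"
  acc$accel$ieaa <- acc$accel$ieaa + ifelse(male, 0.9, -0.9)
  diffHat <- mean(acc$accel$ieaa[male]) - mean(acc$accel$ieaa[!male])
  expect_gt(diffHat, 0)
})
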