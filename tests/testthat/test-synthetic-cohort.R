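test_that("degenerate pedigree is a founder couple", {
  ped <- simulatePedigree(1, 1, seed = 1)
  d <- as.data.frame(ped)
  expect_equal(nrow(d), 2)
  expect_true(all(is.na(d$sire) & is.na(d$dam)))
  expect_setequal(d$sex, c("male", "female"))
  expect_error(simulatePedigree(0, 1), "positive")
})

test_that("pedigree simulation is seed-deterministic", {
  expect_identical(as.data.frame(simulatePedigree(5, 2, seed = 1)),
                   as.data.frame(simulatePedigree(5, 2, seed = 1)))
  expect_false(identical(as.data.frame(simulatePedigree(5, 2, seed = 1)),
                         as.data.frame(simulatePedigree(5, 2, seed = 2))))
})

test_that("simulated pedigrees pass an independent parent-walk validator", {
  for (seed in 1:10) {
    d <- as.data.frame(simulatePedigree(4, 3, seed = seed))
    pos <- setNames(seq_len(nrow(d)), d$id)
    for (i in seq_len(nrow(d))) {
      # walk every ancestor chain: no self-ancestry, parents stored earlier
      frontier <- c(d$sire[i], d$dam[i])
      seen <- character()
      while (length(frontier)) {
        a <- frontier[1]; frontier <- frontier[-1]
        if (is.na(a)) next
        expect_false(a == d$id[i])
        expect_lt(pos[a], pos[d$id[i]])
        if (a %in% seen) next
        seen <- c(seen, a)
        k <- pos[a]
        frontier <- c(frontier, d$sire[k], d$dam[k])
      }
      if (!is.na(d$sire[i])) expect_equal(d$sex[pos[d$sire[i]]], "male")
      if (!is.na(d$dam[i])) expect_equal(d$sex[pos[d$dam[i]]], "female")
    }
  }
})

test_that("null effect table leaves traits uncorrelated with latent acceleration", {
  ped <- simulatePedigree(150, 2, seed = 4)
  cfg <- simulationConfig(nFamilies = 150, generations = 2,
                          effectTable = nullEffectTable(), seed = 4)
  phen <- simulatePhenotypes(ped, cfg)
  n <- nrow(phen$phenotypes)
  lim <- 3 / sqrt(n)
  for (f in c("bmi", "hdl", "total_chol", "chol_ratio", "simd_rank",
              "education", "prs")) {
    expect_lt(abs(cor(phen$phenotypes[[f]], phen$latent$accelI)), lim)
    expect_lt(abs(cor(phen$phenotypes[[f]], phen$latent$accelE)), lim)
  }
})

test_that("an injected BMI effect is recovered from the generated cohort", {
  et <- nullEffectTable()
  et$ieaa[et$factor == "bmi"] <- 0.089
  ped <- simulatePedigree(500, 2, seed = 5)
  cfg <- simulationConfig(nFamilies = 500, generations = 2,
                          effectTable = et, seed = 5)
  phen <- simulatePhenotypes(ped, cfg)
  slope <- coef(lm(scale(phen$latent$accelI) ~ scale(phen$phenotypes$bmi)))[2]
  expect_lt(abs(slope - 0.089), 0.05)
})

test_that("heritability 0.5 gives full-sib correlation near h2/2", {
  et <- nullEffectTable()
  ped <- simulatePedigree(400, 2, seed = 6)
  cfg <- simulationConfig(nFamilies = 400, generations = 2,
                          effectTable = et, heritability = 0.5, seed = 6)
  phen <- simulatePhenotypes(ped, cfg)
  d <- as.data.frame(ped)
  key <- paste(d$sire, d$dam)
  sibsets <- split(seq_len(nrow(d)), key)
  sibsets <- sibsets[!grepl("NA", names(sibsets)) & lengths(sibsets) >= 2]
  pairs <- do.call(rbind, lapply(sibsets, function(s) t(combn(s, 2))))
  expect_gt(nrow(pairs), 500)
  z <- scale(phen$phenotypes$bmi)
  r <- cor(z[pairs[, 1]], z[pairs[, 2]])
  expect_lt(abs(r - 0.25), 0.07)
})

test_that("methylation encodes the clocks exactly at zero noise", {
  cc <- smallCohort(seed = 7, noiseSd = 0)
  ages <- cc$phen$phenotypes$age
  hv <- predictAge(cc$sim$mset, cc$sim$clocks$horvath)
  hn <- predictAge(cc$sim$mset, cc$sim$clocks$hannum)
  expect_equal(unname(hv), ages + cc$phen$latent$accelI, tolerance = 1e-8)
  expect_equal(unname(hn), ages + cc$phen$latent$accelE, tolerance = 1e-8)
})

test_that("injected QC failures are found, betas/beadcounts are in range", {
  cc <- smallCohort(seed = 8, nFamilies = 20,
                    qcFail = list(samples = 3, detectionProbes = 2,
                                  beadcountProbes = 2, sexSwaps = 2))
  flagged <- filterSamplesByDetection(cc$sim$mset)
  expect_setequal(flagged, cc$sim$injected$failedSamples)
  expect_length(flagged, 3)
  b <- betas(cc$sim$mset)
  expect_true(all(b >= 0 & b <= 1))
  bc <- beadcounts(cc$sim$mset)
  expect_true(all(bc > 0 & bc == round(bc)))
  expect_true(all(probeChromosomes(cc$sim$mset)[grep("^cgX", rownames(b))] ==
                    "chrX"))
})

test_that("methylation and phenotype generation are seed-deterministic", {
  a <- smallCohort(seed = 9)
  b <- smallCohort(seed = 9)
  expect_identical(betas(a$sim$mset), betas(b$sim$mset))
  expect_identical(detectionP(a$sim$mset), detectionP(b$sim$mset))
  expect_identical(a$phen$phenotypes, b$phen$phenotypes)
  expect_identical(a$sim$cellTruth, b$sim$cellTruth)
})

test_that("genotype blocks have high within- and low between-block LD", {
  g1 <- simulateGenotypes(200, nSnps = 40, ldBlockSize = 1, seed = 10)
  C <- abs(cor(g1$dosages))
  expect_lt(mean(C[upper.tri(C)]), 0.1)
  expect_true(all(g1$dosages %in% 0:2))
  freq <- colMeans(g1$dosages) / 2
  expect_true(all(freq > 0.05 & freq < 0.95))

  g5 <- simulateGenotypes(200, nSnps = 40, ldBlockSize = 5, seed = 10)
  # designated pairs: each block's first and second SNP share the copy
  for (b in 0:7) {
    r2 <- cor(g5$dosages[, b * 5 + 1], g5$dosages[, b * 5 + 2])^2
    expect_gt(r2, 0.25)
  }
  expect_identical(simulateGenotypes(50, 10, 2, seed = 3)$dosages,
                   simulateGenotypes(50, 10, 2, seed = 3)$dosages)
})

test_that("config validation rejects bad inputs", {
  expect_error(simulationConfig(heritability = 1.5))
  expect_error(simulationConfig(noiseSd = -1))
  et <- defaultEffectTable()
  et$factor[1] <- "not_a_factor"
  expect_error(simulationConfig(effectTable = et), "unknown risk factor")
  ped <- simulatePedigree(2, 1, seed = 1)
  expect_error(
    simulatePhenotypes(ped, simulationConfig(heritability = 0.99)),
    "environmental variance")
})
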