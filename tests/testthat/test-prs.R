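test_that("clumping keeps the more significant of two SNPs in tight LD", {
  withr::with_seed(50, {
    n <- 100
    root <- rbinom(n, 2, 0.3)
    D <- cbind(rsA = root, rsB = root)
    s <- data.frame(snp = c("rsA", "rsB"), chr = "chr1",
                    pos = c(100000, 110000), p = c(0.01, 0.5))
    expect_identical(ldClump(s, D), "rsA")
    # vacuous filter: r^2 > 1 is impossible
    expect_setequal(ldClump(s, D, r2Threshold = 1), c("rsA", "rsB"))
    # outside the window the pair survives
    s2 <- s; s2$pos <- c(100000, 400000)
    expect_setequal(ldClump(s2, D), c("rsA", "rsB"))
  })
})

test_that("clumping equals the brute-force greedy oracle on an LD fixture", {
  g <- simulateGenotypes(300, nSnps = 100, ldBlockSize = 5, seed = 51)
  got <- ldClump(g$summary, g$dosages)
  oracle <- clumpOracle(g$summary, g$dosages)
  expect_identical(sort(got), sort(oracle))
  # and the result is invariant to input row order
  perm <- withr::with_seed(51, sample.int(nrow(g$summary)))
  got2 <- ldClump(g$summary[perm, ], g$dosages)
  expect_setequal(got2, got)
})

test_that("monomorphic SNPs are skipped with a warning", {
  D <- cbind(rsA = c(0, 1, 2, 1), rsB = rep(2, 4))
  s <- data.frame(snp = c("rsA", "rsB"), chr = "chr1",
                  pos = c(1e5, 2e5), p = c(0.1, 0.01))
  expect_warning(kept <- ldClump(s, D), "monomorphic")
  expect_identical(kept, "rsA")
})

test_that("region exclusion honours the closed-left open-right flank", {
  s <- data.frame(snp = paste0("rs", 1:5), chr = "chr19",
                  pos = c(45000000,        # region midpoint
                          44409106,        # exactly start - flank
                          45912650,        # exactly end + flank
                          46512650,        # 600 kb beyond the flank edge
                          44909106),       # region start
                  p = 0.5)
  out <- excludeRegion(s, "chr19", 44909106, 45412650, flank = 500000)
  expect_setequal(out$snp, c("rs3", "rs4"))
  expect_warning(same <- excludeRegion(s, "chrZ", 1, 2), "not present")
  expect_identical(same, s)
})

test_that("PRS equals hand arithmetic and the matrix-product oracle", {
  D1 <- matrix(2, 1, 1, dimnames = list("S1", "rsA"))
  s1 <- data.frame(snp = "rsA", chr = "chr1", pos = 1, a1 = "A", a2 = "G",
                   beta = 0.2, p = 0.5)
  expect_equal(computePRS(D1, s1)$score, 0.4)
  expect_equal(computePRS(D1 * 0, s1)$score, 0)

  g <- simulateGenotypes(80, nSnps = 50, ldBlockSize = 5, seed = 52)
  res <- computePRS(g$dosages, g$summary)
  oracle <- as.vector(g$dosages %*% g$summary$beta)
  expect_equal(res$score, oracle, tolerance = 1e-12)
  expect_lt(abs(mean(res$score_std)), 1e-12)
  expect_equal(sd(res$score_std), 1, tolerance = 1e-12)
})

test_that("allele alignment flips swapped panels and drops mismatches", {
  D <- matrix(c(0, 1, 2, 2, 2, 2, 1, 0, 1), 3, 3,
              dimnames = list(paste0("S", 1:3), c("rs1", "rs2", "rs3")))
  s <- data.frame(snp = c("rs1", "rs2", "rs3"), chr = "chr1",
                  pos = 1:3, a1 = c("A", "C", "T"), a2 = c("G", "T", "A"),
                  beta = c(0.5, -1, 2), p = 0.5)
  panel <- data.frame(snp = c("rs1", "rs2", "rs3"),
                      a1 = c("A", "T", "C"),     # rs2 swapped, rs3 mismatch
                      a2 = c("G", "C", "G"))
  expect_warning(res <- computePRS(D, s, panelAlleles = panel), NA)
  expect_equal(attr(res, "n_dropped"), 1)
  oracle <- D[, "rs1"] * 0.5 + (2 - D[, "rs2"]) * (-1)
  expect_equal(res$score, unname(oracle))
})

test_that("score is linear in additive dosage decompositions", {
  g <- simulateGenotypes(40, nSnps = 20, ldBlockSize = 2, seed = 53)
  D <- g$dosages
  D1 <- floor(D / 2)
  D2 <- D - D1
  s <- g$summary
  expect_equal(computePRS(D, s)$score,
               computePRS(D1, s)$score + computePRS(D2, s)$score,
               tolerance = 1e-12)
})

test_that("PRS-liability correlation rises with the causal set size", {
  withr::with_seed(54, {
    n <- 400
    g <- simulateGenotypes(n, nSnps = 60, ldBlockSize = 1, seed = 54)
    bTrue <- rnorm(60, 0, 0.2)
    liability <- as.vector(scale(g$dosages) %*% bTrue) + rnorm(n, 0, 0.5)
    s <- g$summary
    s$beta <- bTrue
    cors <- sapply(c(5, 25, 60), function(k) {
      cor(computePRS(g$dosages, s, retained = s$snp[seq_len(k)])$score,
          liability)
    })
    expect_true(all(diff(cors) > 0))
  })
})
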