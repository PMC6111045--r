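fakeCells <- function(n, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rgamma(n * 7, shape = 3), n, 7)
    p <- x / rowSums(x)
    colnames(p) <- bloodCellTypes()
    p
  })
}

test_that("IEAA is zero when clock age equals chronological age", {
  n <- 40
  age <- seq(20, 70, length.out = n)
  cells <- fakeCells(n)
  expect_lt(max(abs(computeIEAA(age, age, cells))), 1e-10)
})

test_that("IEAA residuals are orthogonal to all design columns", {
  withr::with_seed(18, {
    n <- 120
    age <- runif(n, 20, 80)
    cells <- fakeCells(n, seed = 2)
    clockAge <- age + rnorm(n, 0, 5) + 10 * cells[, "CD8T.naive"]
    ie <- computeIEAA(clockAge, age, cells)
    expect_lt(abs(mean(ie)), 1e-8 * sd(ie))
    expect_lt(abs(cor(ie, age)), 1e-8)
    for (ct in bloodCellTypes())  # incl. the dropped granulocyte column
      expect_lt(abs(cor(ie, cells[, ct])), 1e-6)
  })
})

test_that("IEAA matches the explicit normal-equations oracle", {
  withr::with_seed(19, {
    n <- 10
    age <- runif(n, 25, 75)
    cells <- fakeCells(n, seed = 3)
    clockAge <- age + rnorm(n, 0, 4)
    X <- cbind(1, age, cells[, setdiff(bloodCellTypes(), "granulocyte")])
    oracle <- clockAge - X %*% solve(t(X) %*% X, t(X) %*% clockAge)
    expect_equal(computeIEAA(clockAge, age, cells), as.vector(oracle),
                 tolerance = 1e-10)
  })
})

test_that("KDM weights recover exact and noisy linear biomarkers", {
  age <- seq(20, 60, by = 1)
  w <- fitKdmWeights(cbind(b1 = 2 * age + 3), age)
  expect_equal(unname(unlist(w[1, c("k", "q", "s")])), c(2, 3, 0))
  expect_error(fitKdmWeights(cbind(flat = rep(1, length(age))), age),
               "no age slope")
  withr::with_seed(20, {
    y <- -0.5 * age + 7 + rnorm(length(age), 0, 0.3)
    w2 <- fitKdmWeights(cbind(b = y), age)
    ols <- lm(y ~ age)
    expect_equal(w2$k, unname(coef(ols)[2]), tolerance = 1e-10)
    expect_equal(w2$q, unname(coef(ols)[1]), tolerance = 1e-10)
    expect_equal(w2$s, summary(ols)$sigma, tolerance = 1e-10)
  })
})

test_that("KDM combination closed forms hold", {
  # single biomarker: BA = (x - q) / k
  w1 <- data.frame(biomarker = "b", k = 2, q = 3, s = 1)
  x <- matrix(c(13, 23), 2, 1, dimnames = list(NULL, "b"))
  expect_equal(kdmCombine(x, w1), c(5, 10), tolerance = 1e-12)
  # consistent biomarkers: combined estimate is the common implied age
  w4 <- data.frame(biomarker = paste0("b", 1:4), k = c(1, 2, -0.5, 0.1),
                   q = c(0, 5, 10, -2), s = c(1, 2, 0.5, 0.2))
  b <- 37.25
  x4 <- matrix(w4$q + w4$k * b, 1, dimnames = list(NULL, w4$biomarker))
  expect_equal(kdmCombine(x4, w4), b, tolerance = 1e-12)
})

test_that("KDM combination matches a direct formula oracle on 4 biomarkers", {
  withr::with_seed(21, {
    w <- data.frame(biomarker = paste0("b", 1:4),
                    k = c(0.8, 1.3, -0.4, 0.05),
                    q = c(2, -1, 20, 0.4), s = c(3, 1.5, 0.8, 0.1))
    x <- matrix(rnorm(5 * 4, mean = 30, sd = 10), 5, 4,
                dimnames = list(NULL, w$biomarker))
    oracle <- sapply(seq_len(5), function(i)
      sum((x[i, ] - w$q) * w$k / w$s^2) / sum(w$k^2 / w$s^2))
    expect_equal(kdmCombine(x, w), oracle, tolerance = 1e-12)
  })
})

test_that("the chronological-age anchored KDM variant shifts toward age", {
  w <- data.frame(biomarker = "b", k = 1, q = 0, s = 2)
  x <- matrix(60, 1, dimnames = list(NULL, "b"))
  plain <- kdmCombine(x, w)
  anchored <- kdmCombine(x, w, anchorAge = 40, anchorSd = 2)
  expect_equal(plain, 60)
  expect_equal(anchored, 50)  # equal precision -> midpoint
})

test_that("EEAA vanishes for affine biomarker ages and matches the OLS oracle", {
  age <- seq(30, 60, length.out = 12)
  expect_lt(max(abs(computeEEAA(5 + 1.2 * age, age))), 1e-10)
  withr::with_seed(22, {
    n <- 10
    a <- runif(n, 20, 80)
    wa <- a + rnorm(n, 0, 3)
    fit <- lm(wa ~ a)
    expect_equal(computeEEAA(wa, a), unname(residuals(fit)),
                 tolerance = 1e-10)
    ee <- computeEEAA(wa, a)
    expect_lt(abs(mean(ee)), 1e-10)
    expect_lt(abs(cor(ee, a)), 1e-8)
  })
})

test_that("IEAA ignores, and EEAA tracks, age-drifting cell composition", {
  cc <- smallCohort(seed = 23, nFamilies = 40)
  qc <- runQC(cc$sim$mset)
  acc <- computeAcceleration(qc$mset, cc$sim$clocks$horvath,
                             cc$sim$clocks$hannum)
  drift <- acc$cells[, "CD8T.naive"]
  for (ct in bloodCellTypes())
    expect_lt(abs(cor(acc$accel$ieaa, acc$cells[, ct])), 1e-6)
  expect_gt(abs(cor(acc$accel$eeaa, drift)), 0.2)
  # clocks strongly track chronological age on the default cohort
  expect_gt(cor(acc$accel$horvath_style_age, acc$accel$age), 0.9)
  expect_gt(cor(acc$accel$hannum_style_age, acc$accel$age), 0.9)
})
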