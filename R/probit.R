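## Bayesian probit mixed model for binary risk factors.
##
## Latent-liability augmentation: y_i = 1(z_i > 0),
## z = X beta + a + e, e ~ N(0, 1) (residual variance fixed at 1 for
## identifiability), a ~ N(0, sigmaA2 A). Gibbs updates cycle over the
## truncated-normal liabilities, the fixed effects (flat prior), the rotated
## random effects (diagonal conditional via the eigendecomposition of A) and
## sigmaA2 (weakly informative inverse-gamma prior).

rtruncnorm1 <- function(mu, positive) {
  # inverse-cdf draw from N(mu, 1) truncated to z > 0 (positive) or z < 0
  p0 <- pnorm(0, mu)
  lo <- ifelse(positive, p0, 0)
  hi <- ifelse(positive, 1, p0)
  u <- lo + runif(length(mu)) * (hi - lo)
  mu + qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Fit a Gaussian mixed model by Gibbs sampling
#'
#' Conjugate Gibbs sampler for `y = X beta + a + e` with the same prior
#' structure as [fitBinaryMixed()] plus an inverse-gamma prior on the
#' residual variance. Exists as the stochastic counterpart of
#' [fitGaussianLMM()] for fidelity runs; the REML path is the deterministic
#' default.
#'
#' @inheritParams fitBinaryMixed
#' @return As [fitBinaryMixed()], plus `sigmaE2`.
#' @export
fitGaussianGibbs <- function(y, X, A = NULL, decomp = NULL, nIter = 3000,
                             burnin = 500, seed = 1L,
                             priorShape = 0.001, priorRate = 0.001) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nIter > burnin)
  if (is.null(decomp)) {
    if (is.null(A)) stop("supply A or its decomposition")
    decomp <- relationshipDecomposition(A)
  }
  U <- decomp$vectors
  d <- decomp$values
  XtXinv <- solve(crossprod(X))
  XtXinvChol <- chol(XtXinv)
  withr::with_seed(seed, {
    beta <- drop(XtXinv %*% crossprod(X, y))
    a <- numeric(n)
    sigmaA2 <- 0.1
    sigmaE2 <- var(y) / 2
    keep <- matrix(NA_real_, nIter - burnin, p)
    for (it in seq_len(nIter)) {
      bhat <- drop(XtXinv %*% crossprod(X, y - a))
      beta <- bhat + sqrt(sigmaE2) * drop(t(XtXinvChol) %*% rnorm(p))
      r <- y - drop(X %*% beta)
      mrot <- drop(crossprod(U, r))
      prec <- 1 / sigmaE2 + 1 / (sigmaA2 * d)
      at <- (mrot / sigmaE2) / prec + rnorm(n) / sqrt(prec)
      a <- drop(U %*% at)
      sigmaA2 <- 1 / rgamma(1, shape = priorShape + n / 2,
                            rate = priorRate + sum(at^2 / d) / 2)
      e <- r - a
      sigmaE2 <- 1 / rgamma(1, shape = priorShape + n / 2,
                            rate = priorRate + sum(e^2) / 2)
      if (it > burnin) keep[it - burnin, ] <- beta
    }
    nk <- nrow(keep)
    colnames(keep) <- colnames(X)
    post <- colMeans(keep)
    ci <- apply(keep, 2, quantile, probs = c(0.025, 0.975))
    tail2 <- vapply(seq_len(p), function(j) {
      pr <- mean(keep[, j] > 0)
      max(2 * min(pr, 1 - pr), 1 / nk)
    }, numeric(1))
    nm <- colnames(X)
    list(beta = setNames(post, nm),
         ciLow = setNames(ci[1, ], nm), ciHigh = setNames(ci[2, ], nm),
         p = setNames(tail2, nm), sigmaA2 = NA_real_, sigmaE2 = sigmaE2,
         samples = keep, separation = FALSE)
  })
}

#' Fit a probit mixed model by Gibbs sampling
#'
#' Posterior inference for a binary trait with a pedigree random effect.
#' Reports, per fixed effect, the posterior mean on the latent (liability)
#' scale, an equal-tailed 95% credible interval, and a two-sided tail
#' probability (the MCMC analogue of a p-value:
#' `2 * min(Pr(beta > 0), Pr(beta < 0))`, floored at `1/nKept`).
#'
#' @param y 0/1 outcome vector (both classes must be present).
#' @param X fixed-effect design matrix (with intercept).
#' @param A relationship matrix (or pass `decomp`).
#' @param decomp optional [relationshipDecomposition()] of `A`.
#' @param nIter total Gibbs iterations (default 3000).
#' @param burnin discarded initial iterations (default 500).
#' @param seed integer seed; fixed seed gives reproducible chains.
#' @param priorShape,priorRate inverse-gamma prior on `sigmaA2`
#'   (default 0.001/0.001, weakly informative).
#' @param fixSigmaA2 optional fixed value for the genetic variance (e.g. `0`
#'   to drop the random effect).
#' @return List: `beta`, `ciLow`, `ciHigh`, `p` (tail probabilities),
#'   `sigmaA2` (posterior mean), `samples` (kept draws of the fixed
#'   effects), `separation` (logical warning flag).
#' @export
fitBinaryMixed <- function(y, X, A = NULL, decomp = NULL, nIter = 3000,
                           burnin = 500, seed = 1L,
                           priorShape = 0.001, priorRate = 0.001,
                           fixSigmaA2 = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(all(y %in% 0:1), nrow(X) == n, nIter > burnin, burnin >= 0)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  if (is.null(decomp)) {
    if (is.null(A)) stop("supply A or its decomposition")
    decomp <- relationshipDecomposition(A)
  }
  U <- decomp$vectors
  d <- decomp$values
  XtXinvChol <- chol(solve(crossprod(X)))
  positive <- y == 1

  withr::with_seed(seed, {
    beta <- numeric(p)
    a <- numeric(n)
    sigmaA2 <- if (is.null(fixSigmaA2)) 0.1 else fixSigmaA2
    keep <- matrix(NA_real_, nIter - burnin, p)
    keepS <- numeric(nIter - burnin)
    z <- ifelse(positive, 0.5, -0.5)
    for (it in seq_len(nIter)) {
      mu <- drop(X %*% beta) + a
      z <- rtruncnorm1(mu, positive)
      ## fixed effects: flat prior
      bhat <- drop(solve(crossprod(X), crossprod(X, z - a)))
      beta <- bhat + drop(t(XtXinvChol) %*% rnorm(p))
      ## random effects in the rotated basis: diagonal conditional
      if (sigmaA2 > 0) {
        m <- drop(crossprod(U, z - drop(X %*% beta)))
        prec <- 1 + 1 / (sigmaA2 * d)
        at <- m / prec + rnorm(n) / sqrt(prec)
        a <- drop(U %*% at)
        if (is.null(fixSigmaA2)) {
          quad <- sum(at^2 / d)
          sigmaA2 <- 1 / rgamma(1, shape = priorShape + n / 2,
                                rate = priorRate + quad / 2)
        }
      } else {
        a[] <- 0
      }
      if (it > burnin) {
        keep[it - burnin, ] <- beta
        keepS[it - burnin] <- sigmaA2
      }
    }
    nk <- nrow(keep)
    colnames(keep) <- colnames(X)
    post <- colMeans(keep)
    ci <- apply(keep, 2, quantile, probs = c(0.025, 0.975))
    tail2 <- vapply(seq_len(p), function(j) {
      pr <- mean(keep[, j] > 0)
      max(2 * min(pr, 1 - pr), 1 / nk)
    }, numeric(1))
    separation <- any(abs(post) > 8) || any(apply(keep, 2, sd) > 8)
    if (separation)
      warning("possible separation: a fixed-effect chain is diverging")
    nm <- colnames(X)
    list(beta = setNames(post, nm),
         ciLow = setNames(ci[1, ], nm), ciHigh = setNames(ci[2, ], nm),
         p = setNames(tail2, nm), sigmaA2 = mean(keepS),
         samples = keep, separation = separation)
  })
}
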