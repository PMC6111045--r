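## Gaussian animal-model mixed regression.
##
## Model: y = X beta + a + e, a ~ N(0, sigmaA2 * A), e ~ N(0, sigmaE2 * I),
## A the pedigree additive relationship matrix. A single eigendecomposition
## A = U D U' rotates the model so the covariance is diagonal in
## lambda = sigmaA2 / sigmaE2, making each REML evaluation O(n p). The
## restricted likelihood is profiled over sigmaE2 and optimised over
## log(lambda).

#' Eigendecompose a relationship matrix for repeated mixed-model fits
#'
#' @param A symmetric PSD relationship matrix.
#' @param ridge small diagonal addition applied when the smallest eigenvalue
#'   falls below `-1e-8` times the largest; eigenvalues are clamped at zero
#'   otherwise.
#' @return List with `vectors` and `values`, usable as the `decomp` argument
#'   of [fitGaussianLMM()].
#' @export
relationshipDecomposition <- function(A, ridge = 1e-8) {
  eg <- eigen(A, symmetric = TRUE)
  lo <- min(eg$values)
  if (lo < -1e-8 * max(eg$values))
    stop("relationship matrix is not positive semidefinite ",
         "(min eigenvalue ", signif(lo, 3), ")")
  eg$values <- pmax(eg$values, ridge)
  eg
}

#' Fit a Gaussian linear mixed model with a pedigree random effect
#'
#' REML estimation of `y = X beta + a + e` with `a ~ N(0, sigmaA2 A)`. Fixed
#' effects are the generalized-least-squares solution at the REML optimum;
#' their standard errors come from `(X' V^-1 X)^-1` and two-sided p-values
#' from a t reference with `n - p` degrees of freedom. Supplying
#' `fixedVarComp` skips estimation and returns the GLS fit at those variance
#' components (with `sigmaA2 = 0` this is exactly ordinary least squares).
#'
#' @param y outcome vector.
#' @param X fixed-effect design matrix (full column rank, including any
#'   intercept).
#' @param A relationship matrix (ignored when `decomp` is given).
#' @param decomp optional precomputed [relationshipDecomposition()]; pass it
#'   when fitting many outcomes on one pedigree.
#' @param fixedVarComp optional `c(sigmaA2, sigmaE2)` to fix the variance
#'   components.
#' @param lambdaBounds search interval for `log(sigmaA2 / sigmaE2)`.
#' @return List: `beta`, `se`, `tstat`, `p`, `ciLow`, `ciHigh` (95% Wald),
#'   `sigmaA2`, `sigmaE2`, `logLikREML`, `df`, `converged`.
#' @export
fitGaussianLMM <- function(y, X, A = NULL, decomp = NULL,
                           fixedVarComp = NULL,
                           lambdaBounds = c(-12, 12)) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, n > p)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")
  if (is.null(decomp)) {
    if (is.null(A)) stop("supply A or its decomposition")
    stopifnot(nrow(A) == n)
    decomp <- relationshipDecomposition(A)
  }
  U <- decomp$vectors
  d <- decomp$values
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  glsAt <- function(lambda) {
    v <- lambda * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    list(beta = drop(beta), XtWX = XtWX, rss = rss, logv = sum(log(v)))
  }
  ## -2 * restricted log-likelihood, profiled over sigmaE2
  neg2REML <- function(logLambda) {
    g <- glsAt(exp(logLambda))
    sigmaE2 <- g$rss / (n - p)
    (n - p) * log(2 * pi * sigmaE2) + g$logv +
      determinant(g$XtWX, logarithm = TRUE)$modulus + (n - p)
  }

  if (is.null(fixedVarComp)) {
    opt <- optimize(neg2REML, lambdaBounds, tol = 1e-9)
    cand <- c(opt$minimum, lambdaBounds[1])  # allow the boundary (lambda ~ 0)
    vals <- c(opt$objective, neg2REML(lambdaBounds[1]))
    logLambda <- cand[which.min(vals)]
    lambda <- exp(logLambda)
    g <- glsAt(lambda)
    sigmaE2 <- g$rss / (n - p)
    sigmaA2 <- lambda * sigmaE2
    logLik <- -0.5 * min(vals)
    converged <- abs(opt$minimum - lambdaBounds[2]) > 1e-3
  } else {
    sigmaA2 <- fixedVarComp[1]; sigmaE2 <- fixedVarComp[2]
    lambda <- sigmaA2 / sigmaE2
    g <- glsAt(lambda)
    logLik <- -0.5 * ((n - p) * log(2 * pi * sigmaE2) + g$logv +
                        determinant(g$XtWX, logarithm = TRUE)$modulus +
                        g$rss / sigmaE2)
    converged <- TRUE
  }
  covBeta <- sigmaE2 * solve(g$XtWX)
  se <- sqrt(diag(covBeta))
  tstat <- g$beta / se
  df <- n - p
  pval <- 2 * pt(-abs(tstat), df)
  crit <- qt(0.975, df)
  nm <- colnames(X)
  res <- list(beta = setNames(g$beta, nm), se = setNames(se, nm),
              tstat = setNames(tstat, nm), p = setNames(pval, nm),
              ciLow = setNames(g$beta - crit * se, nm),
              ciHigh = setNames(g$beta + crit * se, nm),
              sigmaA2 = as.numeric(sigmaA2), sigmaE2 = as.numeric(sigmaE2),
              logLikREML = as.numeric(logLik), df = df,
              converged = converged)
  class(res) <- "lmmFit"
  res
}

#' Restricted log-likelihood by dense evaluation
#'
#' Direct evaluation of the REML criterion at given variance components,
#' using full `n x n` matrices (log-determinants and an explicit projection).
#' Exists as an independent check of the profiled eigenvalue implementation;
#' quadratic cost, use on small problems.
#'
#' @param y,X,A as in [fitGaussianLMM()].
#' @param sigmaA2,sigmaE2 variance components.
#' @return Restricted log-likelihood (scalar).
#' @export
denseREMLLogLik <- function(y, X, A, sigmaA2, sigmaE2) {
  X <- as.matrix(X)
  n <- length(y)
  V <- sigmaA2 * A + sigmaE2 * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       quad + (n - ncol(X)) * log(2 * pi)))
}
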