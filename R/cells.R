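## Reference-based blood cell deconvolution.
##
## Per sample we minimise || R p - b ||^2 subject to p >= 0 and sum(p) = 1
## (R = reference betas on shared probes). With only seven cell types the
## convex program is solved exactly by enumerating candidate support sets:
## for each nonempty subset of cell types, solve the equality-constrained
## least squares via its KKT system, keep feasible solutions, and take the
## best. This guarantees the global optimum without an external QP solver.

solveSupport <- function(RtR, Rtb, support) {
  k <- length(support)
  K <- rbind(cbind(RtR[support, support, drop = FALSE], 1),
             c(rep(1, k), 0))
  rhs <- c(Rtb[support], 1)
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  sol[seq_len(k)]
}

#' Estimate blood cell proportions by constrained least squares
#'
#' Projects each sample's betas (on the probes shared with the reference)
#' onto the simplex of cell-type mixtures: non-negative proportions summing
#' to one that minimise the squared deviation from the reference profiles.
#'
#' @param m a [MethylationSet] or probes-x-samples beta matrix.
#' @param ref a [CellReference]; needs at least 7 shared probes and full
#'   column rank on them.
#' @return Samples x 7 matrix of proportions (rows sum to 1 within 1e-6).
#' @examples
#' ref <- defaultCellReference()
#' b <- referenceBetas(ref)[, "NK", drop = FALSE]  # a pure NK sample
#' colnames(b) <- "S1"
#' estimateCellProportions(b, ref)
#' @export
estimateCellProportions <- function(m, ref) {
  stopifnot(is(ref, "CellReference"))
  b <- if (is(m, "MethylationSet")) betas(m) else m
  R <- referenceBetas(ref)
  shared <- intersect(rownames(R), rownames(b))
  if (length(shared) < ncol(R))
    stop("need at least ", ncol(R), " probes shared with the reference")
  R <- R[shared, , drop = FALSE]
  if (qr(R)$rank < ncol(R))
    stop("reference is rank-deficient on the shared probes; ",
         "cell profiles are not separable")
  b <- b[shared, , drop = FALSE]
  RtR <- crossprod(R)
  nTypes <- ncol(R)
  supports <- lapply(seq_len(2^nTypes - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(nTypes) - 1)) > 0))
  out <- matrix(0, ncol(b), nTypes,
                dimnames = list(colnames(b), colnames(R)))
  for (s in seq_len(ncol(b))) {
    Rtb <- drop(crossprod(R, b[, s]))
    # fast path: the unconstrained-on-the-simplex solution, when feasible,
    # is already the optimum
    pFull <- solveSupport(RtR, Rtb, seq_len(nTypes))
    if (!is.null(pFull) && all(pFull >= -1e-9)) {
      pFull <- pmax(pFull, 0)
      out[s, ] <- pFull / sum(pFull)
      next
    }
    best <- NULL; bestRss <- Inf
    for (sup in supports) {
      p <- solveSupport(RtR, Rtb, sup)
      if (is.null(p) || any(p < -1e-9)) next
      full <- numeric(nTypes); full[sup] <- p
      rss <- sum((R %*% full - b[, s])^2)
      if (rss < bestRss - 1e-12) { bestRss <- rss; best <- full }
    }
    if (is.null(best)) stop("deconvolution failed for sample ", colnames(b)[s])
    best <- pmax(best, 0)
    out[s, ] <- best / sum(best)
  }
  out
}
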