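## Risk factor x age acceleration association suite.
##
## Model direction follows the study design: the risk factor is the outcome;
## chronological age, sex and the acceleration measure are fixed effects; the
## pedigree enters as a random effect. Continuous outcomes use the REML
## linear mixed model, binary outcomes the probit Gibbs sampler. Numeric
## variables are z-scored; Bonferroni correction is applied separately per
## exposure with m = 12.

#' z-score a numeric vector
#'
#' Centers to mean zero and scales to unit variance (denominator `n - 1`).
#' Refuses constant input.
#'
#' @param x numeric vector.
#' @return Standardized vector.
#' @export
standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Bonferroni adjustment
#'
#' @param p vector of p-values in (0, 1\].
#' @param m number of tests (default 12, the risk-factor roster size); must
#'   be at least `length(p)`.
#' @param alpha family-wise error rate for the reported threshold.
#' @return List: `p_adjusted` (`min(1, m * p)`), `threshold` (`alpha / m`
#'   rounded to 4 decimals), `m`, `alpha`.
#' @examples
#' bonferroniAdjust(c(0.001, 0.02))$p_adjusted  # 0.012 0.240
#' bonferroniAdjust(0.5)$threshold              # 0.0042
#' @export
bonferroniAdjust <- function(p, m = 12, alpha = 0.05) {
  stopifnot(all(is.na(p) | (p > 0 & p <= 1)), m >= 1)
  if (m < length(p)) stop("m must be at least the number of p-values")
  list(p_adjusted = pmin(1, m * p), threshold = round(alpha / m, 4),
       m = m, alpha = alpha)
}

#' Run the 12-factor x 2-exposure association suite
#'
#' For each risk factor in the roster and each acceleration exposure (IEAA,
#' EEAA), fits the mixed model `factor ~ age + sex + exposure + (pedigree)`.
#' Continuous factors and both exposures (and age) are z-scored before
#' fitting, so continuous effects are in SD units; binary factors keep their
#' 0/1 coding and are fitted on the latent probit scale. `education` is
#' treated as numeric-ordinal and z-scored unless `educationPerUnit = TRUE`.
#'
#' @param phenotypes data.frame with `id`, `sex`, `age` and the 12 roster
#'   columns (see [riskFactorRoster()]).
#' @param accel data.frame with `sample_id`, `ieaa`, `eeaa` (see
#'   [computeAcceleration()]).
#' @param A relationship matrix over the phenotype ids (or a superset).
#' @param m number of tests for Bonferroni (default 12, kept fixed even when
#'   the roster is subset).
#' @param alpha family-wise error rate (default 0.05).
#' @param roster risk factors to test (default the full 12).
#' @param educationPerUnit keep education on its 0-10 per-unit scale instead
#'   of z-scoring.
#' @param chain list of probit sampler settings (`nIter`, `burnin`, `seed`).
#' @param gaussianSampler fit continuous outcomes with the conjugate Gibbs
#'   sampler ([fitGaussianGibbs()]) instead of REML; the deterministic REML
#'   path is the default.
#' @return data.frame of class `AssociationResult`: one row per factor x
#'   exposure with `risk_factor`, `family`, `exposure`, `beta`, `ci_low`,
#'   `ci_high`, `p`, `p_adjusted`, `n_used`; the Bonferroni threshold is in
#'   `attr(, "threshold")`.
#' @export
runAssociationSuite <- function(phenotypes, accel, A, m = 12, alpha = 0.05,
                                roster = riskFactorRoster(),
                                educationPerUnit = FALSE,
                                chain = list(nIter = 3000, burnin = 500,
                                             seed = 1L),
                                gaussianSampler = FALSE) {
  et <- defaultEffectTable()
  missingCols <- setdiff(roster, names(phenotypes))
  if (length(missingCols))
    stop("missing phenotype columns: ", paste(missingCols, collapse = ", "))
  ids <- intersect(phenotypes$id, accel$sample_id)
  ph <- phenotypes[match(ids, phenotypes$id), ]
  ac <- accel[match(ids, accel$sample_id), ]
  stopifnot(all(ids %in% rownames(A)))
  Ai <- A[ids, ids]
  decomp <- relationshipDecomposition(Ai)

  ageZ <- standardize(ph$age)
  sex01 <- as.integer(ph$sex == "male")
  rows <- list()
  chainSeed <- if (is.null(chain$seed)) 1L else as.integer(chain$seed)
  k <- 0L
  for (exposure in c("ieaa", "eeaa")) {
    expZ <- standardize(ac[[exposure]])
    X <- cbind(intercept = 1, age = ageZ, sex = sex01, exposure = expZ)
    for (f in roster) {
      k <- k + 1L
      fam <- et$family[et$factor == f]
      yRaw <- ph[[f]]
      if (fam == "gaussian") {
        y <- if (f == "education" && educationPerUnit) yRaw
             else standardize(yRaw)
        fit <- if (gaussianSampler)
          fitGaussianGibbs(y, X, decomp = decomp, nIter = chain$nIter,
                           burnin = chain$burnin, seed = chainSeed + k)
        else fitGaussianLMM(y, X, decomp = decomp)
      } else if (length(unique(yRaw)) < 2) {
        warning("binary outcome '", f, "' is monomorphic in this cohort; ",
                "reporting NA")
        fit <- list(beta = c(exposure = NA_real_),
                    ciLow = c(exposure = NA_real_),
                    ciHigh = c(exposure = NA_real_),
                    p = c(exposure = NA_real_))
      } else {
        fit <- fitBinaryMixed(y = yRaw, X, decomp = decomp,
                              nIter = chain$nIter, burnin = chain$burnin,
                              seed = chainSeed + k)
      }
      rows[[k]] <- data.frame(
        risk_factor = f, family = fam, exposure = exposure,
        beta = unname(fit$beta["exposure"]),
        ci_low = unname(fit$ciLow["exposure"]),
        ci_high = unname(fit$ciHigh["exposure"]),
        p = unname(fit$p["exposure"]),
        n_used = length(yRaw), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  adj <- numeric(nrow(out))
  for (exposure in c("ieaa", "eeaa")) {
    sel <- out$exposure == exposure
    adj[sel] <- bonferroniAdjust(out$p[sel], m = m, alpha = alpha)$p_adjusted
  }
  out$p_adjusted <- adj
  attr(out, "threshold") <- round(alpha / m, 4)
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("AssociationResult", "data.frame")
  out
}
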