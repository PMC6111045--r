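## Age acceleration measures.
##
## IEAA: residual of clock age regressed on chronological age plus the blood
## cell proportions (cell-intrinsic ageing). EEAA: residual, on chronological
## age alone, of a Klemera-Doubal weighted biological age combining the
## Hannum-style clock age with three age-varying immune cell measures
## (naive cytotoxic T, exhausted cytotoxic T, plasmablast), so it keeps the
## immunosenescence signal that IEAA regresses away.

#' Intrinsic epigenetic age acceleration
#'
#' Residuals of the least-squares regression of clock age on chronological
#' age and six free cell proportions (granulocytes are dropped as the
#' reference category; proportions sum to one, so the full set is collinear
#' with the intercept). Residuals are orthogonal to every design column —
#' including, implicitly, the dropped granulocyte fraction.
#'
#' @param clockAges predicted epigenetic ages (years).
#' @param chronological chronological ages (years).
#' @param cells samples x 7 cell proportion matrix (see
#'   [estimateCellProportions()]).
#' @param drop cell type excluded from the design (default `"granulocyte"`).
#' @return Numeric vector of IEAA values (years), mean zero over the cohort.
#' @export
computeIEAA <- function(clockAges, chronological, cells,
                        drop = "granulocyte") {
  stopifnot(length(clockAges) == length(chronological),
            nrow(cells) == length(clockAges),
            drop %in% colnames(cells))
  X <- cbind(1, chronological,
             cells[, setdiff(colnames(cells), drop), drop = FALSE])
  if (nrow(X) <= ncol(X)) stop("need more samples than covariates")
  if (qr(X)$rank < ncol(X))
    warning("IEAA design is rank deficient (collinear cell proportions); ",
            "residuals taken from the pivoted least-squares projection")
  unname(residuals(lm.fit(X, clockAges)))
}

#' Fit Klemera-Doubal biomarker weights
#'
#' Each biomarker is regressed (ordinary least squares) on chronological age,
#' giving a slope `k`, intercept `q`, and residual SD `s` — the ingredients
#' of the Klemera-Doubal weighting. Biomarkers whose age slope is below
#' `minSlope` in magnitude carry no age information and are rejected.
#'
#' @param biomarkers samples x m numeric matrix.
#' @param chronological chronological ages (years).
#' @param minSlope smallest acceptable |slope|.
#' @return data.frame with one row per biomarker: `biomarker`, `k`, `q`, `s`.
#' @examples
#' age <- 20:60
#' fitKdmWeights(cbind(b = 2 * age + 3), age)   # k = 2, q = 3, s = 0
#' @export
fitKdmWeights <- function(biomarkers, chronological, minSlope = 1e-10) {
  biomarkers <- as.matrix(biomarkers)
  stopifnot(nrow(biomarkers) == length(chronological))
  if (var(chronological) == 0) stop("chronological age has zero variance")
  out <- data.frame(biomarker = colnames(biomarkers),
                    k = NA_real_, q = NA_real_, s = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(biomarkers))) {
    y <- biomarkers[, j]
    k <- cov(y, chronological) / var(chronological)
    q <- mean(y) - k * mean(chronological)
    r <- y - (q + k * chronological)
    s <- sqrt(sum(r^2) / max(length(y) - 2, 1))
    if (abs(k) < minSlope)
      stop("biomarker '", colnames(biomarkers)[j],
           "' has no age slope (|k| < ", minSlope, "); rejected")
    out[j, c("k", "q", "s")] <- c(k, q, s)
  }
  out
}

#' Klemera-Doubal weighted biological age
#'
#' Combines biomarkers into a biological age estimate
#' `BA = sum_j (x_j - q_j) k_j / s_j^2  /  sum_j k_j^2 / s_j^2`
#' — a weighted average of the per-biomarker implied ages `(x_j - q_j)/k_j`,
#' each weighted by its precision `k_j^2 / s_j^2`. Residual SDs are floored
#' at `sFloor` so an exactly-linear biomarker (s = 0) does not produce an
#' infinite weight; with one biomarker the estimate reduces to
#' `(x - q) / k` regardless.
#'
#' @param biomarkers samples x m matrix, columns matching `weights` rows.
#' @param weights data.frame from [fitKdmWeights()].
#' @param sFloor lower bound applied to the residual SDs (default 1e-6).
#' @param anchorAge optional chronological ages; when supplied they enter as
#'   an (m+1)-th pseudo-biomarker with unit slope, zero intercept and
#'   residual SD `anchorSd` (the variant of the estimator anchored on
#'   chronological age).
#' @param anchorSd residual SD assigned to the anchor (default 5 years).
#' @return Numeric vector of biological ages (years).
#' @export
kdmCombine <- function(biomarkers, weights, sFloor = 1e-6,
                       anchorAge = NULL, anchorSd = 5) {
  biomarkers <- as.matrix(biomarkers)
  stopifnot(ncol(biomarkers) == nrow(weights))
  if (!is.null(colnames(biomarkers)))
    stopifnot(identical(colnames(biomarkers), weights$biomarker))
  k <- weights$k; q <- weights$q
  s <- pmax(weights$s, sFloor)
  num <- sweep(biomarkers, 2, q) %*% (k / s^2)
  den <- sum(k^2 / s^2)
  if (!is.null(anchorAge)) {
    stopifnot(length(anchorAge) == nrow(biomarkers))
    num <- num + anchorAge / anchorSd^2
    den <- den + 1 / anchorSd^2
  }
  drop(num) / den
}

#' Extrinsic epigenetic age acceleration
#'
#' Residuals of the simple least-squares regression of the weighted
#' biological age on chronological age.
#'
#' @param weightedAge Klemera-Doubal biological ages (years), see
#'   [kdmCombine()].
#' @param chronological chronological ages (years).
#' @return Numeric vector of EEAA values (years), mean zero.
#' @export
computeEEAA <- function(weightedAge, chronological) {
  stopifnot(length(weightedAge) == length(chronological),
            length(weightedAge) >= 3)
  if (var(chronological) == 0) stop("chronological age has zero variance")
  unname(residuals(lm.fit(cbind(1, chronological), weightedAge)))
}

#' Build the per-sample acceleration table
#'
#' Runs the full acceleration pipeline on a QCed methylation set: predicts
#' both clock ages, estimates cell proportions, computes IEAA from the
#' Horvath-style clock with cell adjustment, and EEAA from the
#' Klemera-Doubal combination of the Hannum-style clock age with the naive
#' cytotoxic T, exhausted cytotoxic T and plasmablast proportions (weights
#' fitted on the cohort itself).
#'
#' @param m a [MethylationSet] with `age` in its `colData` (or supply `age`).
#' @param horvathClock,hannumClock [ClockModel]s.
#' @param cellRef a [CellReference].
#' @param age chronological ages; defaults to [sampleAges()] of `m`.
#' @return List with `accel` (data.frame: `sample_id`, `age`,
#'   `horvath_style_age`, `hannum_style_age`, `ieaa`, `eeaa`) and `cells`
#'   (the estimated samples x 7 proportion matrix).
#' @export
computeAcceleration <- function(m, horvathClock, hannumClock,
                                cellRef = defaultCellReference(),
                                age = sampleAges(m)) {
  if (is.null(age)) stop("chronological ages are required")
  horvathAge <- predictAge(m, horvathClock)
  hannumAge <- predictAge(m, hannumClock)
  cells <- estimateCellProportions(m, cellRef)
  ieaa <- computeIEAA(horvathAge, age, cells)
  bio <- cbind(hannum_age = hannumAge,
               cells[, c("CD8T.naive", "CD8T.exhausted", "plasmablast")])
  w <- fitKdmWeights(bio, age)
  eeaa <- computeEEAA(kdmCombine(bio, w), age)
  list(accel = data.frame(sample_id = colnames(m), age = unname(age),
                          horvath_style_age = unname(horvathAge),
                          hannum_style_age = unname(hannumAge),
                          ieaa = ieaa, eeaa = eeaa,
                          stringsAsFactors = FALSE),
       cells = cells)
}
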