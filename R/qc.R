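## Sample and probe quality control for methylation beta matrices.
##
## Boundary semantics are pinned deliberately: the sample rule is inclusive
## (">= 1%" of probes failing), a probe "fails" when its detection p is
## strictly above the p threshold; the beadcount rule is "less than 3"
## (strict) in "more than 5" samples (strict); the probe detection rule is
## inclusive (">= 0.5%" of samples).

#' Flag samples with too many failed detections
#'
#' A sample is excluded when the fraction of its probes with detection
#' p-value strictly greater than `pThreshold` is at least `failFraction`.
#'
#' @param m a [MethylationSet].
#' @param pThreshold detection p-value cutoff (default 0.05, strict `>`).
#' @param failFraction fraction of failing probes that triggers exclusion
#'   (default 0.01, inclusive `>=`).
#' @return Character vector of excluded sample ids.
#' @export
filterSamplesByDetection <- function(m, pThreshold = 0.05,
                                     failFraction = 0.01) {
  stopifnot(is(m, "MethylationSet"),
            pThreshold > 0, pThreshold <= 1,
            failFraction > 0, failFraction <= 1)
  dp <- detectionP(m)
  if (nrow(dp) == 0 || ncol(dp) == 0) stop("empty methylation matrix")
  failFrac <- colMeans(dp > pThreshold)
  colnames(dp)[failFrac >= failFraction]
}

#' Flag probes by beadcount and detection failures
#'
#' A probe is excluded when its beadcount is below `beadcountMin` in strictly
#' more than `beadcountMaxSamples` samples, or when the fraction of samples
#' with detection p strictly above `pThreshold` is at least `failFraction`.
#' When the set has no beadcount assay that rule is skipped with a warning.
#'
#' @param m a [MethylationSet].
#' @param beadcountMin minimum acceptable beadcount (default 3, strict `<`).
#' @param beadcountMaxSamples tolerated number of low-beadcount samples
#'   (default 5, strict `>`).
#' @param pThreshold detection p cutoff (default 0.05, strict `>`).
#' @param failFraction sample fraction triggering exclusion (default 0.005,
#'   inclusive `>=`).
#' @return data.frame with columns `probe` and `reason`
#'   (`"beadcount"`/`"detection"`; beadcount takes precedence when both fire).
#' @export
filterProbes <- function(m, beadcountMin = 3, beadcountMaxSamples = 5,
                         pThreshold = 0.05, failFraction = 0.005) {
  stopifnot(is(m, "MethylationSet"),
            pThreshold > 0, pThreshold <= 1,
            failFraction > 0, failFraction <= 1)
  dp <- detectionP(m)
  bc <- beadcounts(m)
  if (is.null(bc)) {
    warning("no beadcount assay: beadcount rule skipped")
    badBead <- rep(FALSE, nrow(dp))
  } else {
    badBead <- rowSums(bc < beadcountMin) > beadcountMaxSamples
  }
  badDet <- rowMeans(dp > pThreshold) >= failFraction
  sel <- which(badBead | badDet)
  data.frame(
    probe = rownames(dp)[sel],
    reason = as.character(ifelse(badBead[sel], "beadcount", "detection")),
    stringsAsFactors = FALSE)
}

#' Sex concordance check from chrX methylation
#'
#' Predicts sex from the mean beta over X-chromosome probes — females carry
#' two (one partially inactivated) X copies and show intermediate chrX
#' methylation, males hemizygous low — and lists samples whose prediction
#' disagrees with the recorded sex. The decision threshold defaults to the
#' midpoint of the female-like and male-like archetype means.
#'
#' @param m a [MethylationSet].
#' @param chrom probe -> chromosome map (named character); defaults to the
#'   set's `rowData` annotation.
#' @param sex recorded sex per sample (named character); defaults to the
#'   set's `colData`.
#' @param threshold decision threshold on mean chrX beta; predicted female
#'   iff the mean exceeds it.
#' @param femaleMean,maleMean archetype means used for the default midpoint
#'   threshold (0.5 and 0.2).
#' @param sexChrom chromosome token treated as X (default `"chrX"`).
#' @return Character vector of discordant sample ids.
#' @export
checkSexConcordance <- function(m, chrom = probeChromosomes(m),
                                sex = recordedSex(m), threshold = NULL,
                                femaleMean = 0.5, maleMean = 0.2,
                                sexChrom = "chrX") {
  stopifnot(is(m, "MethylationSet"))
  if (is.null(chrom)) stop("no probe chromosome annotation available")
  if (is.null(sex)) stop("no recorded sex available")
  xProbes <- intersect(names(chrom)[chrom == sexChrom], rownames(m))
  if (length(xProbes) == 0) stop("no annotated sex-chromosome probes")
  if (is.null(threshold)) threshold <- (femaleMean + maleMean) / 2
  xMean <- colMeans(betas(m)[xProbes, , drop = FALSE])
  predicted <- ifelse(xMean > threshold, "female", "male")
  ids <- colnames(m)
  ids[predicted != sex[ids]]
}

#' Run the full QC cascade
#'
#' Applies, in order: (1) sample exclusion by detection failures, (2) probe
#' exclusion by beadcount, (3) probe exclusion by detection failures, then
#' (4) the sex-concordance check. Probe-level fractions in steps 2-3 are
#' computed on the samples surviving step 1. Idempotent: re-running on its
#' own output changes nothing.
#'
#' @param m a [MethylationSet].
#' @param chrom,sex see [checkSexConcordance()]; pass `NULL` for either to
#'   skip the sex check.
#' @param pThreshold,sampleFailFraction,probeFailFraction,beadcountMin,beadcountMaxSamples
#'   thresholds, see [filterSamplesByDetection()] and [filterProbes()].
#' @param sexThreshold optional decision threshold for the sex check.
#' @return List with `mset` (the filtered [MethylationSet]) and `report`
#'   (a [QCReport]).
#' @examples
#' sim <- simulateMethylation(
#'   simulatePhenotypes(simulatePedigree(5, 2, seed = 1),
#'                      simulationConfig(nFamilies = 5, generations = 2)))
#' qc <- runQC(sim$mset)
#' qc$report
#' @export
runQC <- function(m, chrom = probeChromosomes(m), sex = recordedSex(m),
                  pThreshold = 0.05, sampleFailFraction = 0.01,
                  probeFailFraction = 0.005, beadcountMin = 3,
                  beadcountMaxSamples = 5, sexThreshold = NULL) {
  stopifnot(is(m, "MethylationSet"))
  before <- c(samples = ncol(m), probes = nrow(m))

  badSamples <- filterSamplesByDetection(m, pThreshold, sampleFailFraction)
  sampleReasons <- rep("detection", length(badSamples))
  m1 <- m[, setdiff(colnames(m), badSamples)]
  if (ncol(m1) == 0) stop("QC excluded every sample")

  badProbes <- filterProbes(m1, beadcountMin, beadcountMaxSamples,
                            pThreshold, probeFailFraction)
  m2 <- m1[setdiff(rownames(m1), badProbes$probe), ]
  if (nrow(m2) == 0) stop("QC excluded every probe")

  if (!is.null(chrom) && !is.null(sex)) {
    mismatched <- checkSexConcordance(m2, chrom, sex,
                                      threshold = sexThreshold)
    badSamples <- c(badSamples, mismatched)
    sampleReasons <- c(sampleReasons, rep("sex_mismatch", length(mismatched)))
    m2 <- m2[, setdiff(colnames(m2), mismatched)]
    if (ncol(m2) == 0) stop("QC excluded every sample")
  }

  report <- methods::new("QCReport",
    excludedSamples = badSamples, sampleReasons = sampleReasons,
    excludedProbes = badProbes$probe, probeReasons = badProbes$reason,
    thresholds = list(pThreshold = pThreshold,
                      sampleFailFraction = sampleFailFraction,
                      probeFailFraction = probeFailFraction,
                      beadcountMin = beadcountMin,
                      beadcountMaxSamples = beadcountMaxSamples),
    countsBefore = before,
    countsAfter = c(samples = ncol(m2), probes = nrow(m2)))
  list(mset = m2, report = report)
}
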