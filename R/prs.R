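## Clumping + thresholding polygenic scores.

#' Greedy LD clumping
#'
#' Greedy clumping by ascending GWAS p-value: the most significant
#' unprocessed SNP becomes an index SNP; every unprocessed SNP on the same
#' chromosome within `window` base pairs whose dosage correlation with the
#' index exceeds `sqrt(r2Threshold)` in square is removed; repeat. Ties on p
#' are broken by position, then id, so the result does not depend on input
#' order. LD is measured as the sample correlation of effect-allele dosages.
#'
#' @param summary data.frame with columns `snp`, `chr`, `pos`, `p`.
#' @param dosages samples x SNPs dosage matrix (columns named by snp id).
#' @param r2Threshold LD squared-correlation threshold, strict `>` (default
#'   0.25).
#' @param window distance threshold in base pairs (default 250000,
#'   inclusive).
#' @return Character vector of retained SNP ids.
#' @export
ldClump <- function(summary, dosages, r2Threshold = 0.25, window = 250000) {
  stopifnot(all(c("snp", "chr", "pos", "p") %in% names(summary)),
            nrow(dosages) >= 2)
  shared <- intersect(summary$snp, colnames(dosages))
  s <- summary[match(shared, summary$snp), ]
  mono <- vapply(shared, function(j) var(dosages[, j]) == 0, logical(1))
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) skipped")
    s <- s[!mono, ]
  }
  s <- s[order(s$p, s$pos, s$snp), ]
  retained <- character()
  alive <- rep(TRUE, nrow(s))
  for (i in seq_len(nrow(s))) {
    if (!alive[i]) next
    idx <- s$snp[i]
    retained <- c(retained, idx)
    alive[i] <- FALSE
    cand <- which(alive & s$chr == s$chr[i] &
                    abs(s$pos - s$pos[i]) <= window)
    if (length(cand)) {
      r <- suppressWarnings(
        cor(dosages[, idx], dosages[, s$snp[cand], drop = FALSE]))
      alive[cand[which(r^2 > r2Threshold)]] <- FALSE
    }
  }
  retained
}

#' Exclude SNPs around a genomic region
#'
#' Removes SNPs on `chrom` with position in `[start - flank, end + flank)`:
#' closed on the left edge, open on the right (a SNP exactly at
#' `start - flank` is removed; one exactly at `end + flank` is retained).
#' Typical use: dropping the *APOE* region (plus a 500 kb flank) before
#' scoring, so the score measures polygenic burden beyond the major locus.
#'
#' @param summary GWAS summary data.frame (`snp`, `chr`, `pos`, ...).
#' @param chrom chromosome token of the region.
#' @param start,end region bounds in base pairs (`start <= end`).
#' @param flank flank added on both sides (default 500000).
#' @return The filtered summary data.frame.
#' @export
excludeRegion <- function(summary, chrom, start, end, flank = 500000) {
  stopifnot(start <= end)
  if (!chrom %in% summary$chr) {
    warning("chromosome '", chrom, "' not present; nothing excluded")
    return(summary)
  }
  drop <- summary$chr == chrom &
    summary$pos >= (start - flank) & summary$pos < (end + flank)
  summary[!drop, , drop = FALSE]
}

#' Compute a polygenic score
#'
#' Raw score per sample: sum over retained SNPs of GWAS effect size times
#' effect-allele dosage. When the dosage panel's allele pair is swapped
#' relative to the summary statistics (`effectAllele`/`otherAllele`
#' columns supplied), the dosage is flipped to `2 - dosage`; SNPs with
#' irreconcilable alleles are dropped and counted. Standardized scores are
#' z-scores across samples.
#'
#' @param dosages samples x SNPs effect-allele dosage matrix in \[0, 2\].
#' @param summary GWAS summary data.frame with `snp`, `beta` and optionally
#'   `a1`/`a2` (effect/other allele).
#' @param retained SNP ids to score (e.g. from [ldClump()]); defaults to all
#'   shared SNPs.
#' @param panelAlleles optional data.frame (`snp`, `a1`, `a2`) describing
#'   the dosage panel's allele orientation, checked against the summary.
#' @param pThreshold optional p-value cutoff applied to the summary before
#'   scoring (default `NULL`: all retained SNPs are used).
#' @return data.frame: `sample_id`, `score`, `score_std`, with
#'   `attr(, "n_snps_used")` and `attr(, "n_dropped")`.
#' @export
computePRS <- function(dosages, summary, retained = NULL,
                       panelAlleles = NULL, pThreshold = NULL) {
  if (!is.null(pThreshold))
    summary <- summary[summary$p <= pThreshold, , drop = FALSE]
  roster <- intersect(summary$snp, colnames(dosages))
  if (!is.null(retained)) roster <- intersect(retained, roster)
  s <- summary[match(roster, summary$snp), ]
  eff <- s$beta
  D <- dosages[, roster, drop = FALSE]
  dropped <- 0L
  if (!is.null(panelAlleles)) {
    pa <- panelAlleles[match(roster, panelAlleles$snp), ]
    same <- pa$a1 == s$a1 & pa$a2 == s$a2
    swapped <- pa$a1 == s$a2 & pa$a2 == s$a1
    bad <- !(same | swapped) | is.na(same)
    if (any(swapped, na.rm = TRUE))
      D[, which(swapped & !bad)] <- 2 - D[, which(swapped & !bad)]
    if (any(bad)) {
      dropped <- sum(bad)
      D <- D[, !bad, drop = FALSE]
      eff <- eff[!bad]
    }
  }
  raw <- drop(D %*% eff)
  s <- if (length(raw) > 1) sd(raw) else 0
  std <- if (is.finite(s) && s > 0) standardize(raw) else raw * 0
  out <- data.frame(sample_id = rownames(dosages), score = raw,
                    score_std = std, stringsAsFactors = FALSE)
  attr(out, "n_snps_used") <- ncol(D)
  attr(out, "n_dropped") <- dropped
  out
}
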