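## Plain-text readers/writers for the pipeline's external formats: wide
## probes-x-samples TSVs for beta/detection-p/beadcount, probe annotation,
## and the tabular stage outputs.

#' Read a MethylationSet from wide TSV files
#'
#' Expects probes as rows and samples as columns, first column the probe id.
#'
#' @param betaFile,detpFile paths to the beta and detection-p TSVs.
#' @param beadFile optional beadcount TSV.
#' @param annotationFile optional probe annotation TSV with columns
#'   `probe_id`, `chrom`.
#' @param sexFile optional sample sex TSV with columns `sample_id`, `sex`.
#' @param ageFile optional TSV with columns `sample_id`, `age`.
#' @return A [MethylationSet].
#' @export
readBetaMatrix <- function(betaFile, detpFile, beadFile = NULL,
                           annotationFile = NULL, sexFile = NULL,
                           ageFile = NULL) {
  readWide <- function(path) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
    as.matrix(d)
  }
  beta <- readWide(betaFile)
  detp <- readWide(detpFile)
  bead <- if (!is.null(beadFile)) readWide(beadFile) else NULL
  chrom <- sex <- age <- NULL
  if (!is.null(annotationFile)) {
    ann <- utils::read.table(annotationFile, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    chrom <- ann$chrom[match(rownames(beta), ann$probe_id)]
  }
  if (!is.null(sexFile)) {
    sx <- utils::read.table(sexFile, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    sex <- sx$sex[match(colnames(beta), sx$sample_id)]
  }
  if (!is.null(ageFile)) {
    ag <- utils::read.table(ageFile, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    age <- ag$age[match(colnames(beta), ag$sample_id)]
  }
  MethylationSet(beta, detp, bead, chrom = chrom, sex = sex, age = age)
}

#' Write a MethylationSet to wide TSV files
#'
#' @param m a [MethylationSet].
#' @param prefix file path prefix; writes `<prefix>_beta.tsv`,
#'   `<prefix>_detp.tsv` and, when present, `<prefix>_beadcount.tsv`.
#' @return Invisibly, the written paths.
#' @export
writeBetaMatrix <- function(m, prefix) {
  writeWide <- function(mat, path) {
    d <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(writeWide(betas(m), paste0(prefix, "_beta.tsv")),
             writeWide(detectionP(m), paste0(prefix, "_detp.tsv")))
  if (!is.null(beadcounts(m)))
    paths <- c(paths, writeWide(beadcounts(m), paste0(prefix, "_beadcount.tsv")))
  invisible(paths)
}

writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a QCReport
#'
#' @param report a [QCReport].
#' @param prefix path prefix; writes `<prefix>.tsv` (excluded items with
#'   reasons) and `<prefix>.json` (thresholds and counts).
#' @return Invisibly, the written paths.
#' @export
writeQCReport <- function(report, prefix) {
  items <- rbind(
    data.frame(kind = "sample", id = report@excludedSamples,
               reason = report@sampleReasons, stringsAsFactors = FALSE),
    data.frame(kind = "probe", id = report@excludedProbes,
               reason = report@probeReasons, stringsAsFactors = FALSE))
  writeTsv(items, paste0(prefix, ".tsv"))
  jsonlite::write_json(
    list(thresholds = report@thresholds,
         counts_before = as.list(report@countsBefore),
         counts_after = as.list(report@countsAfter)),
    paste0(prefix, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paste0(prefix, c(".tsv", ".json")))
}
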