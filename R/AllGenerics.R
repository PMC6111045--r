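#' Assay accessors for MethylationSet
#'
#' @param object a [MethylationSet].
#' @return The corresponding probes-x-samples matrix (`beadcounts()` returns
#'   `NULL` when no beadcount assay is present).
#' @export
setGeneric("betas", function(object) standardGeneric("betas"))

#' @rdname betas
#' @export
setGeneric("detectionP", function(object) standardGeneric("detectionP"))

#' @rdname betas
#' @export
setGeneric("beadcounts", function(object) standardGeneric("beadcounts"))

#' @rdname betas
setMethod("betas", "MethylationSet", function(object)
  SummarizedExperiment::assay(object, "beta"))

#' @rdname betas
setMethod("detectionP", "MethylationSet", function(object)
  SummarizedExperiment::assay(object, "detectionP"))

#' @rdname betas
setMethod("beadcounts", "MethylationSet", function(object) {
  if ("beadcount" %in% SummarizedExperiment::assayNames(object))
    SummarizedExperiment::assay(object, "beadcount")
  else NULL
})

#' Probe chromosome annotation
#' @param object a [MethylationSet].
#' @return Named character vector probe -> chromosome, or `NULL`.
#' @export
probeChromosomes <- function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!"chrom" %in% colnames(rd)) return(NULL)
  stats::setNames(as.character(rd$chrom), rownames(object))
}

#' Recorded sex of each sample
#' @param object a [MethylationSet].
#' @return Named character vector sample -> sex, or `NULL`.
#' @export
recordedSex <- function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"sex" %in% colnames(cd)) return(NULL)
  stats::setNames(as.character(cd$sex), colnames(object))
}

#' Chronological age of each sample
#' @param object a [MethylationSet].
#' @return Named numeric vector sample -> age in years, or `NULL`.
#' @export
sampleAges <- function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"age" %in% colnames(cd)) return(NULL)
  stats::setNames(as.numeric(cd$age), colnames(object))
}
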