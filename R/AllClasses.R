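#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef cor cov lm lm.fit median optimize pnorm pt qt qnorm
#'   quantile residuals rnorm runif rbinom rpois sd var rgamma setNames
#' @importFrom utils read.table write.table modifyList
NULL

#' Canonical blood cell types
#'
#' The seven leukocyte populations used for cell-composition adjustment of
#' epigenetic age: naive and exhausted (CD28-CD45RA-) cytotoxic T cells,
#' plasmablasts, helper T cells, natural killer cells, monocytes and
#' granulocytes. All cell-profile objects in this package use exactly these
#' labels, in this order.
#'
#' @return Character vector of length 7.
#' @export
bloodCellTypes <- function() {
  c("CD8T.naive", "CD8T.exhausted", "plasmablast",
    "CD4T", "NK", "monocyte", "granulocyte")
}

## ---------------------------------------------------------------------------
## MethylationSet
## ---------------------------------------------------------------------------

#' MethylationSet: beta values with QC companion matrices
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' methylation beta matrix (probes x samples, values in \[0,1\]) together with
#' its per-measurement quality companions: a detection p-value matrix and,
#' optionally, a beadcount matrix. Probe chromosome annotation lives in
#' `rowData` (column `chrom`); recorded sex and chronological age, when known,
#' live in `colData` (columns `sex`, `age`).
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @aliases MethylationSet-class
#' @exportClass MethylationSet
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("beta", "detectionP") %in% an))
    msg <- c(msg, "assays 'beta' and 'detectionP' are required")
  if ("beta" %in% an) {
    b <- SummarizedExperiment::assay(object, "beta")
    if (any(!is.na(b) & (b < 0 | b > 1)))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if ("detectionP" %in% an) {
    p <- SummarizedExperiment::assay(object, "detectionP")
    if (any(!is.na(p) & (p < 0 | p > 1)))
      msg <- c(msg, "detection p-values must lie in [0, 1]")
  }
  if ("beadcount" %in% an) {
    bc <- SummarizedExperiment::assay(object, "beadcount")
    if (any(!is.na(bc) & (bc < 0 | bc != round(bc))))
      msg <- c(msg, "beadcounts must be non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationSet
#'
#' @param beta numeric matrix, probes as rows and samples as columns, in \[0,1\].
#' @param detectionP numeric matrix of detection p-values, same shape as `beta`.
#' @param beadcount optional integer matrix of bead counts, same shape.
#' @param chrom optional character vector of probe chromosomes (length
#'   `nrow(beta)`), e.g. `"chr1"`, `"chrX"`.
#' @param sex optional character vector of recorded sexes (`"male"`/`"female"`)
#'   per sample.
#' @param age optional numeric vector of chronological ages (years) per sample.
#'
#' @return A `MethylationSet`.
#' @examples
#' b <- matrix(runif(20), 4, 5,
#'             dimnames = list(paste0("cg", 1:4), paste0("S", 1:5)))
#' ms <- MethylationSet(b, matrix(0, 4, 5, dimnames = dimnames(b)))
#' dim(ms)
#' @export
MethylationSet <- function(beta, detectionP, beadcount = NULL,
                           chrom = NULL, sex = NULL, age = NULL) {
  if (is.null(dimnames(beta)) || is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("'beta' must have probe rownames and sample colnames")
  stopifnot(identical(dim(beta), dim(detectionP)))
  assays <- list(beta = beta, detectionP = detectionP)
  if (!is.null(beadcount)) {
    stopifnot(identical(dim(beta), dim(beadcount)))
    assays$beadcount <- beadcount
  }
  rd <- S4Vectors::DataFrame(row.names = rownames(beta))
  if (!is.null(chrom)) rd$chrom <- chrom
  cd <- S4Vectors::DataFrame(row.names = colnames(beta))
  if (!is.null(sex)) cd$sex <- sex
  if (!is.null(age)) cd$age <- age
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = cd)
  methods::new("MethylationSet", se)
}

## ---------------------------------------------------------------------------
## ClockModel
## ---------------------------------------------------------------------------

#' ClockModel: a linear epigenetic clock
#'
#' An epigenetic clock is a linear predictor of age from beta values at a
#' fixed probe set, with an optional nonlinear age calibration. The model is
#' `transformed_age = intercept + sum_j weight_j * beta_j`, inverted through
#' the calibration to give years.
#'
#' @slot name clock label, e.g. `"horvath_style"`.
#' @slot intercept numeric intercept on the transformed-age scale.
#' @slot weights named numeric vector of per-probe coefficients.
#' @slot transform `"identity"` or `"log_linear"`.
#' @slot adultAge adulthood anchor (years) for the log-linear calibration.
#' @aliases ClockModel-class
#' @exportClass ClockModel
setClass("ClockModel",
  representation(name = "character", intercept = "numeric",
                 weights = "numeric", transform = "character",
                 adultAge = "numeric"),
  prototype(transform = "identity", adultAge = 20))

setValidity("ClockModel", function(object) {
  msg <- character()
  if (!all(is.finite(object@weights)))
    msg <- c(msg, "clock weights must be finite")
  if (is.null(names(object@weights)) && length(object@weights) > 0)
    msg <- c(msg, "clock weights must be named by probe id")
  if (!object@transform %in% c("identity", "log_linear"))
    msg <- c(msg, "transform must be 'identity' or 'log_linear'")
  if (object@transform == "log_linear" && object@adultAge <= 0)
    msg <- c(msg, "adultAge must be > 0 for the log-linear transform")
  if (length(msg)) msg else TRUE
})

#' @param name,intercept,weights,transform,adultAge see slot documentation.
#' @rdname ClockModel-class
#' @export
ClockModel <- function(name, intercept, weights,
                       transform = c("identity", "log_linear"),
                       adultAge = 20) {
  methods::new("ClockModel", name = name, intercept = intercept,
               weights = weights, transform = match.arg(transform),
               adultAge = adultAge)
}

setMethod("show", "ClockModel", function(object) {
  cat("ClockModel '", object@name, "': ", length(object@weights),
      " probes, intercept ", signif(object@intercept, 4),
      ", transform ", object@transform, "\n", sep = "")
})

#' Clock accessors
#' @param clock a [ClockModel].
#' @return `clockWeights`: named numeric vector; `clockIntercept`: numeric.
#' @export
clockWeights <- function(clock) clock@weights

#' @rdname clockWeights
#' @export
clockIntercept <- function(clock) clock@intercept

## ---------------------------------------------------------------------------
## CellReference
## ---------------------------------------------------------------------------

#' CellReference: reference methylation profiles of the seven cell types
#'
#' Beta profiles (probes x cell types) of purified leukocyte populations used
#' for reference-based deconvolution of whole-blood methylation.
#'
#' @slot referenceBetas numeric matrix, probes as rows, the seven canonical
#'   cell types (see [bloodCellTypes()]) as columns, values in \[0,1\].
#' @aliases CellReference-class
#' @exportClass CellReference
setClass("CellReference", representation(referenceBetas = "matrix"))

setValidity("CellReference", function(object) {
  m <- object@referenceBetas
  msg <- character()
  if (!identical(colnames(m), bloodCellTypes()))
    msg <- c(msg, "columns must be exactly bloodCellTypes(), in order")
  if (any(m < 0 | m > 1))
    msg <- c(msg, "reference betas must lie in [0, 1]")
  if (is.null(rownames(m)))
    msg <- c(msg, "reference probes must be named")
  if (length(msg)) msg else TRUE
})

#' @param referenceBetas see slot documentation.
#' @rdname CellReference-class
#' @export
CellReference <- function(referenceBetas) {
  methods::new("CellReference", referenceBetas = referenceBetas)
}

#' @rdname CellReference-class
#' @param ref a `CellReference`.
#' @export
referenceBetas <- function(ref) ref@referenceBetas

setMethod("show", "CellReference", function(object) {
  cat("CellReference:", nrow(object@referenceBetas), "probes x",
      ncol(object@referenceBetas), "cell types\n")
})

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Pedigree: individuals with parent links and sex
#'
#' Individuals are stored parents-before-offspring; founders have `NA`
#' parents. Sires are male, dams are female, and no individual may be its own
#' ancestor — all enforced by the validity method.
#'
#' @slot id character individual identifiers (unique).
#' @slot sire character sire ids (`NA` if unknown).
#' @slot dam character dam ids (`NA` if unknown).
#' @slot sex `"male"` or `"female"` per individual.
#' @slot family character family labels (bookkeeping only).
#' @aliases Pedigree-class
#' @exportClass Pedigree
setClass("Pedigree",
  representation(id = "character", sire = "character", dam = "character",
                 sex = "character", family = "character"))

setValidity("Pedigree", function(object) {
  id <- object@id; sire <- object@sire; dam <- object@dam; sex <- object@sex
  n <- length(id)
  msg <- character()
  if (length(sire) != n || length(dam) != n || length(sex) != n)
    return("id, sire, dam, sex must have equal length")
  if (anyDuplicated(id)) msg <- c(msg, "duplicated individual ids")
  if (!all(sex %in% c("male", "female")))
    msg <- c(msg, "sex must be 'male' or 'female'")
  pos <- match(id, id)
  sirePos <- match(sire, id)
  damPos <- match(dam, id)
  if (any(!is.na(sire) & is.na(sirePos)))
    msg <- c(msg, "sire referenced but not present as an individual")
  if (any(!is.na(dam) & is.na(damPos)))
    msg <- c(msg, "dam referenced but not present as an individual")
  ok <- !is.na(sirePos)
  if (any(sex[sirePos[ok]] != "male")) msg <- c(msg, "a sire is not male")
  if (any(sirePos[ok] >= seq_len(n)[ok]))
    msg <- c(msg, "a sire is stored at or after its offspring")
  ok <- !is.na(damPos)
  if (any(sex[damPos[ok]] != "female")) msg <- c(msg, "a dam is not female")
  if (any(damPos[ok] >= seq_len(n)[ok]))
    msg <- c(msg, "a dam is stored at or after its offspring")
  if (length(msg)) msg else TRUE
})

#' @param id,sire,dam,sex,family see slot documentation.
#' @rdname Pedigree-class
#' @export
Pedigree <- function(id, sire, dam, sex, family = rep(NA_character_, length(id))) {
  methods::new("Pedigree", id = as.character(id), sire = as.character(sire),
               dam = as.character(dam), sex = as.character(sex),
               family = as.character(family))
}

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@sire) & is.na(object@dam))
  cat("Pedigree:", length(object@id), "individuals (", nf, "founders ) in",
      length(unique(object@family)), "families\n")
})

#' @rdname Pedigree-class
#' @param x a `Pedigree`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "Pedigree", function(x, ...) {
  data.frame(id = x@id, sire = x@sire, dam = x@dam, sex = x@sex,
             family = x@family, stringsAsFactors = FALSE)
})

#' Number of individuals in a pedigree
#' @param ped a [Pedigree].
#' @export
pedigreeSize <- function(ped) length(ped@id)

#' @rdname pedigreeSize
#' @export
pedigreeIds <- function(ped) ped@id

## ---------------------------------------------------------------------------
## QCReport
## ---------------------------------------------------------------------------

#' QCReport: bookkeeping of sample/probe exclusions
#'
#' Records which samples and probes were removed by [runQC()], the reason for
#' each, the thresholds used, and before/after counts.
#'
#' @slot excludedSamples character vector of removed sample ids.
#' @slot sampleReasons character vector (`"detection"` or `"sex_mismatch"`)
#'   parallel to `excludedSamples`.
#' @slot excludedProbes character vector of removed probe ids.
#' @slot probeReasons character vector (`"beadcount"` or `"detection"`)
#'   parallel to `excludedProbes`.
#' @slot thresholds named list of threshold values applied.
#' @slot countsBefore,countsAfter named integer vectors (`samples`, `probes`).
#' @aliases QCReport-class
#' @exportClass QCReport
setClass("QCReport",
  representation(excludedSamples = "character", sampleReasons = "character",
                 excludedProbes = "character", probeReasons = "character",
                 thresholds = "list", countsBefore = "integer",
                 countsAfter = "integer"))

setValidity("QCReport", function(object) {
  msg <- character()
  if (length(object@excludedSamples) != length(object@sampleReasons))
    msg <- c(msg, "sample reasons must parallel excluded samples")
  if (length(object@excludedProbes) != length(object@probeReasons))
    msg <- c(msg, "probe reasons must parallel excluded probes")
  cb <- object@countsBefore; ca <- object@countsAfter
  if (length(cb) == 2 && length(ca) == 2) {
    if (cb["samples"] - length(unique(object@excludedSamples)) != ca["samples"])
      msg <- c(msg, "sample counts do not reconcile")
    if (cb["probes"] - length(unique(object@excludedProbes)) != ca["probes"])
      msg <- c(msg, "probe counts do not reconcile")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  cat("  samples:", object@countsBefore["samples"], "->",
      object@countsAfter["samples"],
      sprintf("(%d excluded)\n", length(object@excludedSamples)))
  cat("  probes: ", object@countsBefore["probes"], "->",
      object@countsAfter["probes"],
      sprintf("(%d excluded)\n", length(object@excludedProbes)))
  if (length(object@excludedSamples))
    cat("  sample reasons:",
        paste(sprintf("%s=%d", names(table(object@sampleReasons)),
                      table(object@sampleReasons)), collapse = ", "), "\n")
  if (length(object@excludedProbes))
    cat("  probe reasons: ",
        paste(sprintf("%s=%d", names(table(object@probeReasons)),
                      table(object@probeReasons)), collapse = ", "), "\n")
})

#' QCReport accessors
#' @param report a [QCReport].
#' @return character vectors of excluded ids, or a named list/vector.
#' @export
excludedSamples <- function(report) report@excludedSamples

#' @rdname excludedSamples
#' @export
excludedProbes <- function(report) report@excludedProbes

#' @rdname excludedSamples
#' @export
qcThresholds <- function(report) report@thresholds

#' @rdname excludedSamples
#' @export
qcCounts <- function(report) {
  list(before = report@countsBefore, after = report@countsAfter)
}
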