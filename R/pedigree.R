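## Pedigree simulation and the additive relationship matrix.

#' Simulate a multi-generation family structure
#'
#' Builds `nFamilies` independent families. Each family starts from a founder
#' couple; in every later generation each couple produces 2-3 offspring, and
#' offspring who go on to reproduce are paired with an unrelated founder
#' spouse. With `generations = 1` a family is just its two founders. The
#' result is stored parents-before-offspring, as required by the tabular
#' relationship-matrix construction.
#'
#' @param nFamilies number of independent families (>= 1).
#' @param generations number of generations including the founders (>= 1).
#' @param seed integer seed; the same seed reproduces the pedigree exactly.
#' @return A [Pedigree].
#' @examples
#' ped <- simulatePedigree(3, 2, seed = 1)
#' head(as.data.frame(ped))
#' @export
simulatePedigree <- function(nFamilies, generations, seed = 1L) {
  if (nFamilies < 1 || generations < 1)
    stop("nFamilies and generations must be positive")
  withr::with_seed(seed, {
    id <- sire <- dam <- sex <- fam <- character()
    for (f in seq_len(nFamilies)) {
      k <- 0L
      newId <- function() {
        k <<- k + 1L
        sprintf("F%03d_I%03d", f, k)
      }
      addInd <- function(s, d, sx) {
        i <- newId()
        id <<- c(id, i); sire <<- c(sire, s); dam <<- c(dam, d)
        sex <<- c(sex, sx); fam <<- c(fam, sprintf("F%03d", f))
        i
      }
      m0 <- addInd(NA_character_, NA_character_, "male")
      f0 <- addInd(NA_character_, NA_character_, "female")
      couples <- list(c(m0, f0))
      if (generations > 1) {
        for (g in 2:generations) {
          nextCouples <- list()
          for (cp in couples) {
            noff <- sample(2:3, 1)
            for (o in seq_len(noff)) {
              sx <- sample(c("male", "female"), 1)
              child <- addInd(cp[1], cp[2], sx)
              # first offspring of each couple founds the next generation
              if (g < generations && o == 1L) {
                spouseSex <- if (sx == "male") "female" else "male"
                spouse <- addInd(NA_character_, NA_character_, spouseSex)
                nextCouples <- c(nextCouples, list(
                  if (sx == "male") c(child, spouse) else c(spouse, child)))
              }
            }
          }
          couples <- nextCouples
        }
      }
    }
    Pedigree(id, sire, dam, sex, fam)
  })
}

#' Additive relationship matrix by the tabular method
#'
#' Computes the expected additive genetic relationship matrix `A` (twice the
#' kinship matrix) from a pedigree with the classical tabular recursion:
#' `A[i,i] = 1 + A[sire_i, dam_i] / 2` and, for `j < i`,
#' `A[i,j] = (A[j, sire_i] + A[j, dam_i]) / 2`, with missing parents
#' contributing zero. Requires parents to precede offspring, which
#' [Pedigree()] validity guarantees. `A` is the covariance structure of the
#' pedigree random effect in the association models.
#'
#' @param ped a [Pedigree].
#' @return Symmetric numeric matrix with individual ids as dimnames;
#'   diagonal `>= 1` (`> 1` for inbred individuals).
#' @examples
#' ped <- simulatePedigree(1, 2, seed = 1)
#' buildRelationshipMatrix(ped)[1:3, 1:3]
#' @export
buildRelationshipMatrix <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  methods::validObject(ped)
  n <- length(ped@id)
  sp <- match(ped@sire, ped@id)
  dp <- match(ped@dam, ped@id)
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (i in seq_len(n)) {
    s <- sp[i]; d <- dp[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as <- if (is.na(s)) 0 else A[j, s]
      ad <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * (as + ad)
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A
}

#' Read / write pedigree files
#'
#' Four-column tab-separated files `(id, sire, dam, sex)` with `0` or `NA`
#' marking unknown parents; an optional fifth `family` column is preserved.
#'
#' @param path file path.
#' @return `readPedigree`: a [Pedigree]; `writePedigree`: invisibly, the path.
#' @export
readPedigree <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", "0"))
  fam <- if ("family" %in% names(d)) d$family else rep(NA_character_, nrow(d))
  Pedigree(d$id, d$sire, d$dam, d$sex, fam)
}

#' @rdname readPedigree
#' @param ped a [Pedigree].
#' @export
writePedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "0")
  invisible(path)
}
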