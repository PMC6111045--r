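## Synthetic cohort generation: phenotypes, clock-structured methylation with
## injected QC failures, and toy genotypes. Every generator is deterministic
## under a fixed seed and exposes the simulation truth it used, so downstream
## stages (QC, age prediction, deconvolution, association) can be validated
## against known parameters.

#' Default risk-factor effect table
#'
#' Standardized effects of latent intrinsic (IEAA) and extrinsic (EEAA) age
#' acceleration on each risk factor in the twelve-factor roster. Defaults are
#' typical reported magnitudes for a large adult cohort (e.g. 0.089 SD of BMI
#' per SD of intrinsic acceleration). The total:HDL cholesterol ratio is a
#' derived trait (`total_chol / hdl`, exact); its row is carried for roster
#' completeness but not used in generation.
#'
#' @return data.frame with columns `factor`, `family` (`gaussian`/`binary`),
#'   `ieaa`, `eeaa` (standardized effect sizes), `prevalence` (binary traits
#'   only, NA otherwise).
#' @export
defaultEffectTable <- function() {
  data.frame(
    factor = c("simd_rank", "education", "t2d", "hbp", "bmi", "pack_years",
               "hdl", "total_chol", "chol_ratio", "prs", "family_history",
               "apoe_e4"),
    family = c("gaussian", "gaussian", "binary", "binary", "gaussian",
               "gaussian", "gaussian", "gaussian", "gaussian", "gaussian",
               "binary", "binary"),
    ieaa = c(-0.005, 0.0398, 0.178, 0.105, 0.089, 0.031,
             -0.028, 0.036, 0.047, -0.002, 0.06, -0.107),
    eeaa = c(-0.056, -0.041, 0.142, 0.177, 0.061, 0.059,
             -0.022, -0.027, 0.014, -0.007, -0.007, -0.103),
    prevalence = c(NA, NA, 171 / 5001, 768 / 5598, NA, NA, NA, NA, NA, NA,
                   834 / 5001, 1358 / 4909),
    stringsAsFactors = FALSE)
}

#' Risk factor roster
#' @return Character vector of the 12 risk-factor column names.
#' @export
riskFactorRoster <- function() defaultEffectTable()$factor

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generators. Defaults describe
#' the emulated study conditions: a family-structured adult cohort, latent
#' acceleration with SD 4.5 years, risk-factor effects at typical reported
#' magnitudes, moderate trait heritability, array-scale measurement noise and
#' a handful of injected QC failures.
#'
#' @param nFamilies,generations pedigree structure passed to
#'   [simulatePedigree()].
#' @param ageRange numeric length-2, uniform chronological age range (years).
#' @param nProbes total probes on the simulated panel (clock, cell-reference,
#'   sex and filler blocks; must accommodate the clock/cell/sex blocks).
#' @param nClockProbes probes per toy clock (Horvath-style block; the
#'   Hannum-style block uses `nClockProbes - 5`).
#' @param cellTypes the seven cell labels; fixed to [bloodCellTypes()].
#' @param noiseSd beta-scale measurement noise SD; `0` makes the methylation
#'   (and cell mixtures) an exact deterministic function of age and latent
#'   acceleration.
#' @param accelSd SD (years) of the latent intrinsic and extrinsic
#'   acceleration components.
#' @param effectTable risk-factor effect table, see [defaultEffectTable()].
#' @param heritability narrow-sense heritability applied to every risk factor
#'   (scalar in \[0,1\], or named vector by factor).
#' @param qcFail named list of injected failures: `samples` (whole-sample
#'   detection failures), `detectionProbes`, `beadcountProbes`, `sexSwaps`.
#' @param seed root integer seed; fixed seed implies byte-identical outputs.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nFamilies = 40, generations = 3,
                             ageRange = c(18, 80), nProbes = 500,
                             nClockProbes = 30,
                             cellTypes = bloodCellTypes(),
                             noiseSd = 0.02, accelSd = 4.5,
                             effectTable = defaultEffectTable(),
                             heritability = 0.4,
                             qcFail = list(samples = 2, detectionProbes = 2,
                                           beadcountProbes = 2, sexSwaps = 1),
                             seed = 1L) {
  stopifnot(nFamilies >= 1, generations >= 1, length(ageRange) == 2,
            noiseSd >= 0, accelSd >= 0, all(is.finite(effectTable$ieaa)),
            all(is.finite(effectTable$eeaa)),
            all(heritability >= 0 & heritability <= 1))
  if (!identical(cellTypes, bloodCellTypes()))
    stop("cellTypes is fixed to the seven canonical labels")
  unknown <- setdiff(effectTable$factor, riskFactorRoster())
  if (length(unknown))
    stop("unknown risk factors in effect table: ",
         paste(unknown, collapse = ", "))
  cfg <- list(nFamilies = nFamilies, generations = generations,
              ageRange = ageRange, nProbes = nProbes,
              nClockProbes = nClockProbes, cellTypes = cellTypes,
              noiseSd = noiseSd, accelSd = accelSd,
              effectTable = effectTable, heritability = heritability,
              qcFail = qcFail, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

## additive genetic values down a pedigree: founders ~ N(0, s2), offspring
## mid-parent + Mendelian sampling N(0, s2/2); parents precede offspring.
geneticValues <- function(ped, nTraits, s2) {
  n <- length(ped@id)
  sp <- match(ped@sire, ped@id)
  dp <- match(ped@dam, ped@id)
  g <- matrix(0, n, nTraits)
  sdF <- sqrt(s2)
  sdM <- sqrt(s2 / 2)
  for (i in seq_len(n)) {
    if (is.na(sp[i]) || is.na(dp[i])) {
      g[i, ] <- rnorm(nTraits, 0, sdF)
    } else {
      g[i, ] <- 0.5 * (g[sp[i], ] + g[dp[i], ]) + rnorm(nTraits, 0, sdM)
    }
  }
  g
}

## cut a standard-normal latent into the 0..10 education ordinal
educationFromLatent <- function(z) {
  probs <- c(0.01, 0.02, 0.07, 0.15, 0.20, 0.15, 0.15, 0.10, 0.07, 0.05, 0.03)
  breaks <- qnorm(cumsum(probs)[-length(probs)])
  findInterval(z, breaks)
}

#' Simulate risk-factor phenotypes with known acceleration effects
#'
#' Draws, per individual, latent intrinsic and extrinsic acceleration
#' (independent Gaussians, SD `config$accelSd` years), then generates each
#' risk factor conditional on them: standardized trait liability =
#' `ieaa_effect * z(accelI) + eeaa_effect * z(accelE) + genetic + environment`,
#' with the additive genetic part following the pedigree at the configured
#' heritability and the components scaled so the liability has unit variance.
#' Continuous traits are mapped to natural units (BMI in kg/m^2, cholesterol
#' in mmol/L, a deprivation rank, an ordinal education level, zero-inflated
#' smoking pack years); binary traits are thresholded at their configured
#' prevalence (liability-threshold model). The total:HDL ratio is computed
#' exactly as `total_chol / hdl`.
#'
#' @param ped a [Pedigree].
#' @param config a [simulationConfig()].
#' @return List of class `SyntheticPhenotypes`: `phenotypes` (data.frame, one
#'   row per individual, the 12-factor roster plus `id`, `family`, `sex`,
#'   `age`) and `latent` (data.frame `id`, `accelI`, `accelE` — the true
#'   acceleration in years).
#' @export
simulatePhenotypes <- function(ped, config = simulationConfig()) {
  stopifnot(is(ped, "Pedigree"), inherits(config, "SimulationConfig"))
  et <- config$effectTable
  gen <- et[et$factor != "chol_ratio", ]  # ratio is derived
  h2 <- config$heritability
  if (length(h2) == 1) h2 <- setNames(rep(h2, nrow(gen)), gen$factor)
  h2 <- h2[gen$factor]
  if (anyNA(h2)) stop("heritability must cover every generated factor")
  envVar <- 1 - gen$ieaa^2 - gen$eeaa^2 - h2
  if (any(envVar <= 0))
    stop("effect sizes and heritability leave no environmental variance")
  withr::with_seed(config$seed + 1L, {
    n <- length(ped@id)
    age <- runif(n, config$ageRange[1], config$ageRange[2])
    accelI <- rnorm(n, 0, config$accelSd)
    accelE <- rnorm(n, 0, config$accelSd)
    zI <- if (config$accelSd > 0) accelI / config$accelSd else accelI
    zE <- if (config$accelSd > 0) accelE / config$accelSd else accelE
    g <- sweep(geneticValues(ped, nrow(gen), 1), 2, sqrt(h2), `*`)
    e <- matrix(rnorm(n * nrow(gen)), n) %*% diag(sqrt(envVar), nrow(gen))
    z <- outer(zI, gen$ieaa) + outer(zE, gen$eeaa) + g + e
    colnames(z) <- gen$factor
    ph <- data.frame(id = ped@id, family = ped@family, sex = ped@sex,
                     age = age, stringsAsFactors = FALSE)
    ph$bmi <- 27.03 + 5.37 * z[, "bmi"]
    ph$hdl <- pmax(1.49 + 0.42 * z[, "hdl"], 0.3)
    ph$total_chol <- pmax(5.13 + 1.09 * z[, "total_chol"], 1.5)
    ph$chol_ratio <- ph$total_chol / ph$hdl
    everSmoker <- z[, "pack_years"] > qnorm(1 - 0.48)
    ph$pack_years <- ifelse(everSmoker,
                            exp(2.3 + 0.6 * z[, "pack_years"]), 0)
    ph$simd_rank <- as.integer(round(
      (rank(z[, "simd_rank"], ties.method = "first") - 0.5) / n * 6504 + 1))
    ph$education <- educationFromLatent(z[, "education"])
    ph$prs <- as.numeric(scale(z[, "prs"]))
    for (f in gen$factor[gen$family == "binary"]) {
      prev <- gen$prevalence[gen$factor == f]
      ph[[f]] <- as.integer(z[, f] > qnorm(1 - prev))
    }
    ph <- ph[, c("id", "family", "sex", "age", riskFactorRoster())]
    list(phenotypes = ph,
         latent = data.frame(id = ped@id, accelI = accelI, accelE = accelE,
                             stringsAsFactors = FALSE)) |>
      structure(class = "SyntheticPhenotypes")
  })
}

#' Construct a toy linear clock
#'
#' Builds a [ClockModel] with weights of alternating sign and common
#' magnitude over the given probes, anchored so that betas of the form
#' `0.5 + weight_j / sum(weight^2) * (t - 50)` predict exactly `t`. Used by
#' [simulateMethylation()] to embed an invertible clock signal while keeping
#' betas comfortably inside \[0,1\].
#'
#' @param name clock label.
#' @param probeIds probe identifiers carrying the clock signal.
#' @param weight absolute coefficient magnitude.
#' @return A [ClockModel] with identity transform.
#' @export
makeToyClock <- function(name, probeIds, weight = 8) {
  w <- weight * rep_len(c(1, -1), length(probeIds))
  names(w) <- probeIds
  ClockModel(name = name, intercept = 50 - 0.5 * sum(w), weights = w)
}

#' Built-in synthetic cell-type reference
#'
#' A deterministic reference panel of 35 probes (five distinctive
#' hypermethylated markers per cell type, beta 0.85 against a 0.10
#' background) covering the seven canonical blood cell types. Full column
#' rank by construction.
#'
#' @return A [CellReference].
#' @export
defaultCellReference <- function() {
  types <- bloodCellTypes()
  probes <- sprintf("cgCELL%02d", seq_len(35))
  m <- matrix(0.10, 35, 7, dimnames = list(probes, types))
  for (k in seq_len(7)) m[(k - 1) * 5 + seq_len(5), k] <- 0.85
  CellReference(m)
}

#' Expected blood cell proportions at a given biological age
#'
#' The mean mixture used by the synthetic cohort: naive cytotoxic T cells and
#' helper T cells decline linearly with biological age while exhausted
#' cytotoxic T cells, plasmablasts and NK cells expand (immunosenescence
#' drift); granulocytes absorb the remainder. Biological age here is
#' chronological age plus the extrinsic acceleration component, so the
#' mixture tracks EEAA but not IEAA.
#'
#' @param t biological age in years (vector).
#' @return Matrix `length(t)` x 7, rows summing to 1.
#' @export
expectedCellProportions <- function(t) {
  p <- cbind(
    CD8T.naive = 0.12 - 8e-4 * t,
    CD8T.exhausted = 0.02 + 1e-3 * t,
    plasmablast = 0.015 + 2e-4 * t,
    CD4T = 0.22 - 4e-4 * t,
    NK = 0.07 + 2e-4 * t,
    monocyte = rep(0.09, length(t)))
  cbind(p, granulocyte = 1 - rowSums(p))
}

#' Simulate clock-structured methylation with QC companions
#'
#' Builds a [MethylationSet] whose probe panel has five blocks: a
#' Horvath-style clock block encoding chronological age plus intrinsic
#' acceleration, a Hannum-style clock block encoding age plus extrinsic
#' acceleration, the cell-reference probes carrying each sample's cell
#' mixture, a chrX block with sex-dependent means (0.5 female-like vs 0.2
#' male-like), and filler probes. At `noiseSd = 0` the construction is exact:
#' `predictAge()` on either clock returns chronological age plus the
#' respective latent acceleration. Detection-p and beadcount matrices are
#' generated clean and then seeded with the configured number of failing
#' samples (2% of probes failing detection), failing probes, low-beadcount
#' probes, and recorded-sex swaps.
#'
#' @param phen a `SyntheticPhenotypes` list from [simulatePhenotypes()].
#' @param horvathClock,hannumClock toy [ClockModel]s whose probes are
#'   embedded; defaults are created from the config's probe budget.
#' @param cellRef a [CellReference]; defaults to [defaultCellReference()].
#' @param config a [simulationConfig()].
#' @return List of class `SyntheticMethylation`: `mset` (a [MethylationSet]
#'   with `chrom`, recorded `sex` and `age` annotation), `cellTruth`
#'   (samples x 7 true proportions), `clocks` (the two embedded clocks),
#'   `trueSex`, and `injected` (ids of the seeded QC failures).
#' @export
simulateMethylation <- function(phen, horvathClock = NULL, hannumClock = NULL,
                                cellRef = defaultCellReference(),
                                config = simulationConfig()) {
  stopifnot(inherits(phen, "SyntheticPhenotypes"),
            inherits(config, "SimulationConfig"))
  ph <- phen$phenotypes
  n <- nrow(ph)
  if (is.null(horvathClock))
    horvathClock <- makeToyClock(
      "horvath_style", sprintf("cgH%04d", seq_len(config$nClockProbes)))
  if (is.null(hannumClock))
    hannumClock <- makeToyClock(
      "hannum_style", sprintf("cgA%04d", seq_len(max(config$nClockProbes - 5, 4))),
      weight = 10)
  refB <- referenceBetas(cellRef)
  nSex <- 20L
  sexProbes <- sprintf("cgX%04d", seq_len(nSex))
  core <- c(names(clockWeights(horvathClock)), names(clockWeights(hannumClock)),
            rownames(refB), sexProbes)
  if (anyDuplicated(core)) stop("clock, cell and sex probe blocks must be disjoint")
  nFill <- config$nProbes - length(core)
  if (nFill < 0) stop("nProbes too small for the clock/cell/sex blocks")
  probes <- c(core, sprintf("cgF%05d", seq_len(nFill)))

  withr::with_seed(config$seed + 2L, {
    tH <- ph$age + phen$latent$accelI
    tA <- ph$age + phen$latent$accelE
    beta <- matrix(NA_real_, length(probes), n,
                   dimnames = list(probes, ph$id))
    clockBlock <- function(clock, t) {
      w <- clockWeights(clock)
      0.5 + outer(w / sum(w^2), t - 50)
    }
    beta[names(clockWeights(horvathClock)), ] <- clockBlock(horvathClock, tH)
    beta[names(clockWeights(hannumClock)), ] <- clockBlock(hannumClock, tA)
    cellTruth <- expectedCellProportions(tA)
    if (config$noiseSd > 0) {
      conc <- cellTruth * 300
      draw <- matrix(rgamma(n * 7, shape = as.vector(conc)), n, 7)
      cellTruth <- draw / rowSums(draw)
      colnames(cellTruth) <- bloodCellTypes()
    }
    rownames(cellTruth) <- ph$id
    beta[rownames(refB), ] <- refB %*% t(cellTruth)
    trueSex <- setNames(ph$sex, ph$id)
    beta[sexProbes, ] <- matrix(
      rep(ifelse(ph$sex == "female", 0.5, 0.2), each = nSex), nSex, n)
    if (nFill > 0) {
      fillMean <- runif(nFill, 0.1, 0.9)
      beta[sprintf("cgF%05d", seq_len(nFill)), ] <-
        matrix(fillMean, nFill, n)
    }
    if (config$noiseSd > 0)
      beta <- beta + matrix(rnorm(length(beta), 0, config$noiseSd),
                            nrow(beta))
    beta <- pmin(pmax(beta, 0), 1)

    detp <- matrix(runif(length(beta), 0, 0.01), nrow(beta),
                   dimnames = dimnames(beta))
    bead <- matrix(3L + rpois(length(beta), 12), nrow(beta),
                   dimnames = dimnames(beta))

    qf <- config$qcFail
    injected <- list(failedSamples = character(), detectionProbes = character(),
                     beadcountProbes = character(), sexSwaps = character())
    fillerIds <- if (nFill > 0) sprintf("cgF%05d", seq_len(nFill)) else character()
    if (qf$samples > 0) {
      bad <- sample(ph$id, qf$samples)
      for (s in bad) {
        k <- ceiling(0.02 * length(probes))
        detp[sample(probes, k), s] <- 0.5
      }
      injected$failedSamples <- sort(bad)
    }
    cleanSamples <- setdiff(ph$id, injected$failedSamples)
    if (qf$detectionProbes > 0) {
      if (length(fillerIds) < qf$detectionProbes + qf$beadcountProbes)
        stop("not enough filler probes to host injected probe failures")
      badP <- fillerIds[seq_len(qf$detectionProbes)]
      k <- max(1L, ceiling(0.006 * length(cleanSamples)))
      for (p in badP) detp[p, sample(cleanSamples, k)] <- 0.5
      injected$detectionProbes <- badP
    }
    if (qf$beadcountProbes > 0) {
      badP <- fillerIds[qf$detectionProbes + seq_len(qf$beadcountProbes)]
      for (p in badP) bead[p, sample(cleanSamples, 6)] <- 2L
      injected$beadcountProbes <- badP
    }
    recSex <- trueSex
    if (qf$sexSwaps > 0) {
      sw <- sample(cleanSamples, qf$sexSwaps)
      recSex[sw] <- ifelse(recSex[sw] == "male", "female", "male")
      injected$sexSwaps <- sort(sw)
    }

    chrom <- rep(paste0("chr", 1 + (seq_along(probes) - 1) %% 22),
                 length.out = length(probes))
    chrom[match(sexProbes, probes)] <- "chrX"
    mset <- MethylationSet(beta, detp, bead, chrom = chrom,
                           sex = recSex[ph$id], age = ph$age)
    structure(list(mset = mset, cellTruth = cellTruth,
                   clocks = list(horvath = horvathClock, hannum = hannumClock),
                   trueSex = trueSex, injected = injected),
              class = "SyntheticMethylation")
  })
}

#' Simulate LD-blocked genotype dosages and GWAS summary statistics
#'
#' SNPs are laid out in blocks along chr1 (block starts 1 Mb apart, 10 kb
#' between SNPs in a block, so different blocks fall outside a 250 kb
#' clumping window). The first SNP of each block is drawn binomially at a
#' random allele frequency; the rest copy it with a small per-sample
#' resampling probability, giving high within-block and near-zero
#' between-block dosage correlation. Summary statistics come from a marginal
#' regression of a simulated polygenic liability on each SNP, so the table
#' carries realistic effect/p columns.
#'
#' @param n number of individuals.
#' @param nSnps number of SNPs (>= 1).
#' @param ldBlockSize SNPs per block (1 = independent SNPs).
#' @param seed integer seed.
#' @return List: `dosages` (n x nSnps matrix in \{0,1,2\}), `summary`
#'   (data.frame `snp`, `chr`, `pos`, `a1`, `a2`, `beta`, `p`), `causal`
#'   (logical truth vector).
#' @export
simulateGenotypes <- function(n, nSnps = 100, ldBlockSize = 5, seed = 1L) {
  stopifnot(n >= 2, nSnps >= 1, ldBlockSize >= 1)
  withr::with_seed(seed, {
    nBlocks <- ceiling(nSnps / ldBlockSize)
    G <- matrix(0L, n, nSnps)
    pos <- integer(nSnps)
    idx <- 1L
    for (b in seq_len(nBlocks)) {
      maf <- runif(1, 0.1, 0.4)
      root <- rbinom(n, 2, maf)
      for (j in seq_len(ldBlockSize)) {
        if (idx > nSnps) break
        if (j == 1) {
          G[, idx] <- root
        } else {
          snp <- root
          flip <- runif(n) < 0.1
          snp[flip] <- rbinom(sum(flip), 2, maf)
          G[, idx] <- snp
        }
        pos[idx] <- b * 1000000L + (j - 1L) * 10000L
        idx <- idx + 1L
      }
    }
    snpIds <- sprintf("rs%05d", seq_len(nSnps))
    colnames(G) <- snpIds
    rownames(G) <- sprintf("S%04d", seq_len(n))
    causal <- runif(nSnps) < 0.2
    bTrue <- ifelse(causal, rnorm(nSnps, 0, 0.25), 0)
    liability <- as.vector(scale(G) %*% bTrue) + rnorm(n)
    bHat <- pHat <- numeric(nSnps)
    for (j in seq_len(nSnps)) {
      if (var(G[, j]) == 0) { bHat[j] <- 0; pHat[j] <- 1; next }
      fit <- summary(lm(liability ~ G[, j]))$coefficients
      bHat[j] <- fit[2, 1]; pHat[j] <- fit[2, 4]
    }
    summaryStats <- data.frame(
      snp = snpIds, chr = "chr1", pos = pos, a1 = "A", a2 = "G",
      beta = bHat, p = pmax(pHat, .Machine$double.xmin),
      stringsAsFactors = FALSE)
    list(dosages = G, summary = summaryStats, causal = causal)
  })
}
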