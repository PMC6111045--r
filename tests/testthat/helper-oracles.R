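# Independent oracles and fixture builders used across the suite.

# Recursive kinship coefficient phi(i, j); A = 2 * phi. Walks parent links
# top-down with memoisation — independent of the iterative tabular method.
kinshipOracle <- function(pedDf) {
  n <- nrow(pedDf)
  sp <- match(pedDf$sire, pedDf$id)
  dp <- match(pedDf$dam, pedDf$id)
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 + 0.5 * phi(sp[i], dp[i])
    } else {
      # recurse through the parents of whichever individual is stored later
      # (its parents are guaranteed to precede it)
      y <- max(i, j); o <- min(i, j)
      0.5 * (phi(sp[y], o) + phi(dp[y], o))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(pedDf$id, pedDf$id))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- 2 * phi(i, j)
  A
}

# Random pedigree with possible inbreeding: later individuals pick parents
# among earlier individuals (or are founders), so validity is maintained.
randomPedigree <- function(n, seed) {
  withr::with_seed(seed, {
    id <- sprintf("I%02d", seq_len(n))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    sex[1] <- "male"; sex[2] <- "female"
    sire <- dam <- rep(NA_character_, n)
    for (i in 3:n) {
      if (runif(1) < 0.25) next  # founder
      males <- which(sex[seq_len(i - 1)] == "male")
      females <- which(sex[seq_len(i - 1)] == "female")
      if (!length(males) || !length(females)) next
      sire[i] <- id[males[sample.int(length(males), 1)]]
      dam[i] <- id[females[sample.int(length(females), 1)]]
    }
    Pedigree(id, sire, dam, sex)
  })
}

# Brute-force greedy clumping: explicit pair-by-pair evaluation.
clumpOracle <- function(summary, dosages, r2Threshold = 0.25,
                        window = 250000) {
  s <- summary[order(summary$p, summary$pos, summary$snp), ]
  s <- s[sapply(s$snp, function(j) var(dosages[, j]) > 0), ]
  removed <- character()
  kept <- character()
  for (i in seq_len(nrow(s))) {
    if (s$snp[i] %in% removed) next
    kept <- c(kept, s$snp[i])
    for (j in seq_len(nrow(s))) {
      if (j == i || s$snp[j] %in% removed || s$snp[j] %in% kept) next
      if (s$chr[j] != s$chr[i]) next
      if (abs(s$pos[j] - s$pos[i]) > window) next
      if (cor(dosages[, s$snp[i]], dosages[, s$snp[j]])^2 > r2Threshold)
        removed <- c(removed, s$snp[j])
    }
  }
  kept
}

# Small hand-built MethylationSet with full control over failures.
makeMset <- function(nProbes, nSamples, beta = 0.5, detp = 0.001,
                     bead = 10L, chrom = NULL, sex = NULL) {
  pn <- sprintf("cg%04d", seq_len(nProbes))
  sn <- sprintf("S%03d", seq_len(nSamples))
  mk <- function(v) matrix(v, nProbes, nSamples, dimnames = list(pn, sn))
  MethylationSet(mk(beta), mk(detp), mk(bead), chrom = chrom, sex = sex)
}

# A deterministic small cohort used by several files.
smallCohort <- function(seed = 1, nFamilies = 10, generations = 2,
                        noiseSd = 0.02, accelSd = 4.5,
                        qcFail = list(samples = 0, detectionProbes = 0,
                                      beadcountProbes = 0, sexSwaps = 0),
                        effectTable = defaultEffectTable(),
                        heritability = 0.4) {
  cfg <- simulationConfig(nFamilies = nFamilies, generations = generations,
                          noiseSd = noiseSd, accelSd = accelSd,
                          qcFail = qcFail, effectTable = effectTable,
                          heritability = heritability, seed = seed)
  ped <- simulatePedigree(nFamilies, generations, seed = seed)
  phen <- simulatePhenotypes(ped, cfg)
  sim <- simulateMethylation(phen, config = cfg)
  list(cfg = cfg, ped = ped, phen = phen, sim = sim)
}

nullEffectTable <- function() {
  et <- defaultEffectTable()
  et$ieaa <- 0
  et$eeaa <- 0
  et
}
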