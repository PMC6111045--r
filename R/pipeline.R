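## End-to-end orchestration: simulate -> qc -> age -> assoc (-> prs), with a
## run manifest and a human-readable report. All randomness flows from one
## root seed, expanded with fixed offsets per stage, so a config reproduces
## its outputs byte for byte.

#' Pipeline configuration
#'
#' @param nFamilies,generations,nProbes,noiseSd,accelSd,heritability,effectTable,qcFail,seed
#'   forwarded to [simulationConfig()].
#' @param outputDir directory for stage outputs (created if needed).
#' @param alpha family-wise error rate (default 0.05).
#' @param mTests Bonferroni test count (default 12).
#' @param runPrs also simulate genotypes and compute a polygenic score.
#' @param nSnps,ldBlockSize genotype panel shape when `runPrs`.
#' @param chain probit sampler settings (`nIter`, `burnin`).
#' @return List of class `PipelineConfig`.
#' @export
pipelineConfig <- function(nFamilies = 40, generations = 3, nProbes = 500,
                           noiseSd = 0.02, accelSd = 4.5,
                           heritability = 0.4,
                           effectTable = defaultEffectTable(),
                           qcFail = list(samples = 2, detectionProbes = 2,
                                         beadcountProbes = 2, sexSwaps = 1),
                           seed = 1L, outputDir = tempfile("methylaccel_run_"),
                           alpha = 0.05, mTests = 12, runPrs = FALSE,
                           nSnps = 100, ldBlockSize = 5,
                           chain = list(nIter = 2000, burnin = 400)) {
  cfg <- list(nFamilies = nFamilies, generations = generations,
              nProbes = nProbes, noiseSd = noiseSd, accelSd = accelSd,
              heritability = heritability, effectTable = effectTable,
              qcFail = qcFail, seed = as.integer(seed),
              outputDir = outputDir, alpha = alpha, mTests = mTests,
              runPrs = runPrs, nSnps = nSnps, ldBlockSize = ldBlockSize,
              chain = chain)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; unknown keys
#' are rejected. `effect_table` may be given as a mapping
#' `factor: [ieaa, eeaa]` overriding the default effects.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading (e.g. from CLI flags).
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(pipelineConfig))
  et <- NULL
  if (!is.null(raw$effect_table)) {
    et <- defaultEffectTable()
    for (f in names(raw$effect_table)) {
      if (!f %in% et$factor) stop("unknown risk factor in config: ", f)
      et[et$factor == f, c("ieaa", "eeaa")] <- as.list(raw$effect_table[[f]])
    }
    raw$effect_table <- NULL
    raw$effectTable <- et
  }
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, raw)
}

stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Simulates a pedigreed cohort, applies QC, computes the acceleration
#' table, runs the 24-row association suite (and optionally the polygenic
#' score stage), writing every intermediate as TSV plus a JSON run manifest
#' and a text report under `config$outputDir`.
#'
#' @param config a [pipelineConfig()] (or a YAML path understood by
#'   [readPipelineConfig()]).
#' @return Invisibly, a list bundle: `pedigree`, `phenotypes`, `latent`,
#'   `qc` (report), `accel`, `cells`, `association`, `prs` (or NULL),
#'   `manifest`, `outputDir`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outputDir, f)
  counts <- list()

  simCfg <- simulationConfig(
    nFamilies = config$nFamilies, generations = config$generations,
    nProbes = config$nProbes, noiseSd = config$noiseSd,
    accelSd = config$accelSd, heritability = config$heritability,
    effectTable = config$effectTable, qcFail = config$qcFail,
    seed = config$seed)

  stage <- "simulate"
  bundle <- tryCatch({
    ped <- simulatePedigree(config$nFamilies, config$generations,
                            seed = config$seed)
    phen <- simulatePhenotypes(ped, simCfg)
    sim <- simulateMethylation(phen, config = simCfg)
    A <- buildRelationshipMatrix(ped)
    counts$simulate <- c(samples = ncol(sim$mset), probes = nrow(sim$mset))
    stageLog(stage, "%d individuals, %d probes", ncol(sim$mset),
             nrow(sim$mset))
    writePedigree(ped, out("pedigree.tsv"))
    writeTsv(phen$phenotypes, out("phenotypes.tsv"))
    writeTsv(phen$latent, out("latent_acceleration.tsv"))

    stage <- "qc"
    qc <- runQC(sim$mset)
    counts$qc <- c(samples = ncol(qc$mset), probes = nrow(qc$mset))
    stageLog(stage, "samples %d -> %d, probes %d -> %d",
             ncol(sim$mset), ncol(qc$mset), nrow(sim$mset), nrow(qc$mset))
    writeQCReport(qc$report, out("qc_report"))

    stage <- "age"
    acc <- computeAcceleration(qc$mset, sim$clocks$horvath,
                               sim$clocks$hannum)
    counts$age <- c(samples = nrow(acc$accel))
    stageLog(stage, "acceleration computed for %d samples", nrow(acc$accel))
    writeTsv(acc$accel, out("acceleration.tsv"))

    stage <- "assoc"
    assoc <- runAssociationSuite(
      phen$phenotypes, acc$accel, A, m = config$mTests,
      alpha = config$alpha,
      chain = c(config$chain, list(seed = config$seed + 10L)))
    counts$assoc <- c(rows = nrow(assoc))
    stageLog(stage, "%d association rows", nrow(assoc))
    writeTsv(as.data.frame(assoc), out("association.tsv"))

    prs <- NULL
    if (isTRUE(config$runPrs)) {
      stage <- "prs"
      geno <- simulateGenotypes(nrow(phen$phenotypes), config$nSnps,
                                config$ldBlockSize,
                                seed = config$seed + 20L)
      rownames(geno$dosages) <- phen$phenotypes$id
      kept <- ldClump(geno$summary, geno$dosages)
      prs <- computePRS(geno$dosages, geno$summary, kept)
      counts$prs <- c(snps_retained = length(kept))
      stageLog(stage, "%d of %d SNPs retained after clumping",
               length(kept), config$nSnps)
      writeTsv(prs, out("prs.tsv"))
    }
    list(pedigree = ped, phenotypes = phen$phenotypes, latent = phen$latent,
         qc = qc$report, accel = acc$accel, cells = acc$cells,
         association = assoc, prs = prs)
  }, error = function(e) {
    jsonlite::write_json(list(failed_stage = stage, counts = counts,
                              error = conditionMessage(e)),
                         out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfgForHash <- config
  cfgForHash$outputDir <- NULL
  cfgFile <- out("config_resolved.json")
  jsonlite::write_json(cfgForHash, cfgFile, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  outputs <- setdiff(list.files(config$outputDir, full.names = TRUE),
                     out("manifest.json"))
  checksums <- tools::md5sum(sort(outputs))
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfgFile)),
    stage_counts = counts,
    output_checksums = as.list(checksums))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  bundle$manifest <- manifest
  bundle$outputDir <- config$outputDir
  bundle$alpha <- config$alpha
  bundle$mTests <- config$mTests
  writeReport(bundle, out("report.txt"))
  invisible(bundle)
}

#' Write a human-readable run report
#'
#' Summarises QC counts and the association table, states the Bonferroni
#' threshold (`alpha / m`, 4 decimals) and flags rows below it.
#'
#' @param bundle result list from [runPipeline()] (needs at least
#'   `association`; `qc` optional).
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeReport <- function(bundle, path) {
  alpha <- if (!is.null(bundle$alpha)) bundle$alpha else 0.05
  m <- if (!is.null(bundle$mTests)) bundle$mTests else 12
  thr <- round(alpha / m, 4)
  lines <- c("methylaccel run report",
             "======================", "")
  if (!is.null(bundle$qc)) {
    cb <- bundle$qc@countsBefore; ca <- bundle$qc@countsAfter
    lines <- c(lines,
               sprintf("QC: samples %d -> %d, probes %d -> %d",
                       cb["samples"], ca["samples"], cb["probes"],
                       ca["probes"]), "")
  }
  assoc <- bundle$association
  lines <- c(lines,
             sprintf("Bonferroni threshold: alpha/m = %.2f/%d = %.4f",
                     alpha, m, thr), "")
  if (is.null(assoc) || nrow(assoc) == 0) {
    lines <- c(lines, "No tests were run.")
  } else {
    sig <- assoc$p_adjusted < alpha
    lines <- c(lines,
               sprintf("%-16s %-5s %8s %18s %9s %9s %s",
                       "risk_factor", "exp", "beta", "95% CI", "p",
                       "p_adj", ""),
               sprintf("%-16s %-5s %8.3f [%7.3f, %7.3f] %9.2g %9.2g %s",
                       assoc$risk_factor, assoc$exposure, assoc$beta,
                       assoc$ci_low, assoc$ci_high, assoc$p,
                       assoc$p_adjusted, ifelse(sig, "*", "")),
               "",
               sprintf("%d of %d associations significant at adjusted p < %.2f",
                       sum(sig), nrow(assoc), alpha))
  }
  writeLines(lines, path)
  invisible(path)
}
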