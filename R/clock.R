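## Epigenetic clock prediction and the log-linear age calibration.

#' Log-linear age calibration
#'
#' Clocks trained across childhood and adulthood commonly regress on a
#' transformed age that is logarithmic up to an adulthood anchor and linear
#' beyond it:
#' `F(age) = log(age + 1) - log(adultAge + 1)` for `age <= adultAge`, and
#' `F(age) = (age - adultAge) / (adultAge + 1)` otherwise. `F` is continuous,
#' strictly increasing, zero at `adultAge`, and exactly invertible.
#'
#' @param age age in years (> -1).
#' @param adultAge adulthood anchor in years (> 0), default 20.
#' @return Transformed age (or years for the inverse).
#' @examples
#' inverseAgeTransform(ageTransform(37.5))  # 37.5
#' @export
ageTransform <- function(age, adultAge = 20) {
  stopifnot(adultAge > 0)
  if (any(age <= -1)) stop("age must exceed -1")
  ifelse(age <= adultAge,
         log(age + 1) - log(adultAge + 1),
         (age - adultAge) / (adultAge + 1))
}

#' @rdname ageTransform
#' @param x transformed age value.
#' @export
inverseAgeTransform <- function(x, adultAge = 20) {
  stopifnot(adultAge > 0)
  ifelse(x <= 0,
         exp(x + log(adultAge + 1)) - 1,
         x * (adultAge + 1) + adultAge)
}

#' Predict epigenetic age from a clock
#'
#' Computes `intercept + sum_j weight_j * beta_j` per sample and maps it back
#' to years through the clock's calibration. Clock probes absent from the
#' matrix are, under the default `"mean-impute"` policy, filled with the
#' cohort mean beta of the present clock probes; prediction is refused when
#' more than `maxMissing` of the clock probes are absent.
#'
#' @param m a [MethylationSet] or a probes-x-samples beta matrix.
#' @param clock a [ClockModel].
#' @param missingPolicy `"mean-impute"` (default) or `"error"`.
#' @param maxMissing maximum tolerated fraction of absent clock probes
#'   (default 0.2).
#' @return Named numeric vector of ages in years, one per sample.
#' @export
predictAge <- function(m, clock, missingPolicy = c("mean-impute", "error"),
                       maxMissing = 0.2) {
  missingPolicy <- match.arg(missingPolicy)
  b <- if (is(m, "MethylationSet")) betas(m) else m
  w <- clockWeights(clock)
  present <- intersect(names(w), rownames(b))
  missing <- setdiff(names(w), rownames(b))
  if (length(w) == 0)
    return(setNames(rep(
      if (clock@transform == "log_linear")
        inverseAgeTransform(clockIntercept(clock), clock@adultAge)
      else clockIntercept(clock), ncol(b)), colnames(b)))
  if (length(missing) / length(w) > maxMissing)
    stop(sprintf("%d of %d clock probes missing (> %.0f%% tolerated)",
                 length(missing), length(w), 100 * maxMissing))
  if (length(missing) > 0 && missingPolicy == "error")
    stop("clock probes missing: ", paste(missing, collapse = ", "))
  score <- drop(crossprod(b[present, , drop = FALSE], w[present]))
  if (length(missing) > 0) {
    # cohort mean of each sample's present clock betas stands in per probe
    imputed <- mean(b[present, , drop = FALSE])
    score <- score + sum(w[missing]) * imputed
  }
  lin <- clockIntercept(clock) + score
  out <- if (clock@transform == "log_linear")
    inverseAgeTransform(lin, clock@adultAge) else lin
  setNames(out, colnames(b))
}

#' Fit a toy clock by penalized regression
#'
#' Elastic-net regression of (optionally transformed) age on betas, the
#' standard recipe for training methylation clocks. Intended for building
#' self-contained test clocks, not for re-deriving published coefficient
#' sets.
#'
#' @param m a [MethylationSet] or beta matrix (probes x samples).
#' @param age chronological ages (years) per sample.
#' @param name clock label.
#' @param transform `"identity"` or `"log_linear"`.
#' @param adultAge anchor for the log-linear calibration.
#' @param alpha elastic-net mixing parameter (0 ridge .. 1 lasso).
#' @return A [ClockModel] with the nonzero coefficients.
#' @export
fitClockModel <- function(m, age, name = "fitted_clock",
                          transform = c("identity", "log_linear"),
                          adultAge = 20, alpha = 0.5) {
  transform <- match.arg(transform)
  b <- if (is(m, "MethylationSet")) betas(m) else m
  y <- if (transform == "log_linear") ageTransform(age, adultAge) else age
  fit <- glmnet::cv.glmnet(t(b), y, alpha = alpha, nfolds = 5)
  cf <- as.matrix(coef(fit, s = "lambda.min"))
  w <- cf[-1, 1]
  w <- w[w != 0]
  ClockModel(name = name, intercept = cf[1, 1], weights = w,
             transform = transform, adultAge = adultAge)
}

#' Read / write clock coefficient tables
#'
#' CSV with columns `probe_id, weight` preceded by metadata comment lines
#' `# name: ...`, `# intercept: ...`, `# transform: ...`, `# adult_age: ...`.
#'
#' @param path file path.
#' @return `readClockModel`: a [ClockModel].
#' @export
readClockModel <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key, default = NULL) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(".*:", "", hit[1]))
  }
  d <- utils::read.csv(text = lines[!grepl("^#", lines)],
                       stringsAsFactors = FALSE)
  ClockModel(
    name = getMeta("name", "clock"),
    intercept = as.numeric(getMeta("intercept", "0")),
    weights = setNames(d$weight, d$probe_id),
    transform = getMeta("transform", "identity"),
    adultAge = as.numeric(getMeta("adult_age", "20")))
}

#' @rdname readClockModel
#' @param clock a [ClockModel].
#' @export
writeClockModel <- function(clock, path) {
  header <- c(sprintf("# name: %s", clock@name),
              sprintf("# intercept: %.17g", clock@intercept),
              sprintf("# transform: %s", clock@transform),
              sprintf("# adult_age: %.17g", clock@adultAge),
              "probe_id,weight")
  body <- sprintf("%s,%.17g", names(clock@weights), clock@weights)
  writeLines(c(header, body), path)
  invisible(path)
}
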