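#' Evaluate a growth standard
#'
#' Mean Gompertz curve and interpolated sigma at given ages.
#'
#' @param standard a [GrowthStandard-class].
#' @param ageDays ages in days.
#' @return numeric vector.
#' @export
growthMean <- function(standard, ageDays)
  standard@A * exp(-standard@b * exp(-standard@k * ageDays))

#' @rdname growthMean
#' @export
growthSigma <- function(standard, ageDays)
  stats::approx(standard@sigmaTable$age, standard@sigmaTable$sigma,
                xout = ageDays, rule = 2)$y

#' Fit a normal growth standard from reference measurements
#'
#' Least-squares Gompertz fit `A exp(-b exp(-k t))` for the mean curve,
#' with `sigma(t)` estimated as the residual standard deviation in age
#' bins of at least `binMin` animals, linearly interpolated between bin
#' centers.
#'
#' @param data data.frame: `ageDays`, `value` (one row per animal
#'   measurement; >= 10 distinct ages).
#' @param measurement,sexClass labels for the standard.
#' @param binMin minimum animals per sigma bin (default 20).
#' @return A [GrowthStandard-class].
#' @export
fitGrowthStandard <- function(data, measurement, sexClass,
                              binMin = 20L) {
  if (length(unique(data$ageDays)) < 10L)
    stop("need measurements at >= 10 distinct ages")
  A0 <- max(data$value) * 1.05
  y0 <- stats::quantile(data$value, 0.05)
  b0 <- max(0.1, -log(max(y0, 1e-3) / A0))
  fit <- tryCatch(
    minpack.lm::nlsLM(value ~ A * exp(-b * exp(-k * ageDays)), data = data,
                      start = list(A = A0, b = b0, k = 0.005),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Gompertz fit did not converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  resid_ <- data$value - cf["A"] * exp(-cf["b"] * exp(-cf["k"] * data$ageDays))
  ord <- order(data$ageDays)
  nBins <- max(1L, floor(nrow(data) / binMin))
  binId <- ceiling(seq_along(ord) / (length(ord) / nBins))
  ages <- tapply(data$ageDays[ord], binId, mean)
  sds <- tapply(resid_[ord], binId, stats::sd)
  sds[is.na(sds) | sds < 1e-8] <- 1e-8   # noise-free reference data
  sigmaTable <- data.frame(age = as.numeric(ages), sigma = as.numeric(sds))
  if (nrow(sigmaTable) == 1L)       # constant sigma: duplicate the point
    sigmaTable <- rbind(sigmaTable,
                        transform(sigmaTable, age = age + 1))
  growthStandard(measurement, sexClass, cf["A"], cf["b"], cf["k"],
                 sigmaTable, range(data$ageDays))
}

.DAYS_PER_MONTH <- 30.4375

#' Deviation from the normal growth curve, in sigma units
#'
#' `(value - mean(age)) / sigma(age)` using the standard selected by the
#' sex/age rule: steers younger than 10 months are scored against the
#' sire standard, steers of 10 months and older against the steer
#' standard, females against the female standard.
#'
#' @param value raw measurement.
#' @param ageDays age in days.
#' @param sex `"M"` (steer/male) or `"F"`.
#' @param measurement measurement name.
#' @param standards list of [GrowthStandard-class]; each entry's
#'   `measurement`/`sexClass` slots are matched.
#' @return numeric sigma deviation.
#' @export
deviation <- function(value, ageDays, sex, measurement, standards) {
  cls <- if (sex == "F") "female"
         else if (ageDays < 10 * .DAYS_PER_MONTH) "sire" else "steer"
  std <- NULL
  for (s in standards)
    if (s@measurement == measurement && s@sexClass == cls) std <- s
  if (is.null(std))
    stop(sprintf("no applicable %s standard for %s at %d days", cls,
                 measurement, round(ageDays)))
  if (ageDays < std@ageRange[1] || ageDays > std@ageRange[2])
    stop("age outside the standard's validity range")
  (value - growthMean(std, ageDays)) / growthSigma(std, ageDays)
}

#' Classify a deviation record into dysproportion flags
#'
#' * `A` (poor development): at least two present deviations below -2
#'   sigma, or an external poor-development diagnosis on record;
#' * `B` (disproportionately narrow chest width):
#'   chest depth - chest width > 1 sigma;
#' * `C` (disproportionately wide thurl width):
#'   thurl width - pin-bone width > 1 sigma.
#'
#' Flags are independent; a pair with a missing member leaves its flag
#' unevaluable (reported in `unevaluable`).  "Below -2 sigma" reads the
#' published deficit convention: the deviations of flagged animals are
#' negative.
#'
#' @param deviations named numeric vector of sigma deviations (names
#'   include `chest_depth`, `chest_width`, `thurl_width`,
#'   `pinbone_width`; others count toward rule A); `NA` = missing.
#' @param externalDiagnosis was the animal externally diagnosed as poorly
#'   developed?
#' @return list: `flags` (character subset of A/B/C), `unevaluable`
#'   (named character of skipped flags and reasons).
#' @export
classifyAnimal <- function(deviations, externalDiagnosis = FALSE) {
  flags <- character(0)
  unev <- character(0)
  present <- deviations[!is.na(deviations)]
  if (sum(present < -2) >= 2L || isTRUE(externalDiagnosis))
    flags <- c(flags, "A")
  pair <- function(hi, lo, flag) {
    if (is.na(deviations[hi]) || is.na(deviations[lo]))
      return(stats::setNames("pair member missing", flag))
    if (deviations[hi] - deviations[lo] > 1) flags <<- c(flags, flag)
    NULL
  }
  u1 <- pair("chest_depth", "chest_width", "B")
  u2 <- pair("thurl_width", "pinbone_width", "C")
  list(flags = flags, unevaluable = c(u1, u2))
}

#' Summarize dysproportion classifications over animals
#'
#' Collapses repeated observations of one animal by flag union, then
#' counts poorly developed animals (A) among all, and B/C among the
#' animals without A (the convention of the source cohort summaries).
#'
#' @param records data.frame with columns `id`, `chest_depth`,
#'   `chest_width`, `thurl_width`, `pinbone_width`, optional further
#'   deviation columns, and optional logical `externalDiagnosis`.
#' @return list: `nA`, `nB`, `nC`, `nAnimals`, `perAnimal` (data.frame
#'   id + flag indicator columns).
#' @export
summarizeClassifications <- function(records) {
  stopifnot(nrow(records) >= 1L)
  devCols <- setdiff(names(records),
                     c("id", "sex", "months", "externalDiagnosis"))
  ids <- unique(records$id)
  per <- data.frame(id = ids, A = FALSE, B = FALSE, C = FALSE)
  for (i in seq_along(ids)) {
    rows <- which(records$id == ids[i])
    for (r in rows) {
      dv <- unlist(records[r, devCols, drop = FALSE])
      names(dv) <- devCols
      ext <- isTRUE(records$externalDiagnosis[r])
      cl <- classifyAnimal(dv, ext)
      per$A[i] <- per$A[i] || "A" %in% cl$flags
      per$B[i] <- per$B[i] || "B" %in% cl$flags
      per$C[i] <- per$C[i] || "C" %in% cl$flags
    }
  }
  list(nA = sum(per$A), nB = sum(per$B & !per$A), nC = sum(per$C & !per$A),
       nAnimals = length(ids), perAnimal = per)
}

#' Interpolate a longitudinal series on a regular age grid
#'
#' Natural cubic spline through the observations, evaluated at 4-week
#' intervals from `start` days of age; grid points outside the observed
#' age range are returned missing (no extrapolation).
#'
#' @param ageDays,value the observed series (>= 4 observations).
#' @param start first grid age in days (default 270).
#' @param stepDays grid step (default 28).
#' @param end last grid age (default: last observed age).
#' @return data.frame `ageDays`, `value` on the grid.
#' @export
interpolateSeries <- function(ageDays, value, start = 270, stepDays = 28,
                              end = max(ageDays)) {
  if (length(ageDays) < 4L) stop("need >= 4 observations")
  ord <- order(ageDays)
  ageDays <- ageDays[ord]; value <- value[ord]
  grid <- seq(start, end, by = stepDays)
  out <- rep(NA_real_, length(grid))
  inside <- grid >= min(ageDays) & grid <= max(ageDays)
  if (any(inside))
    out[inside] <- stats::spline(ageDays, value, xout = grid[inside],
                                 method = "natural")$y
  data.frame(ageDays = grid, value = out)
}

#' Genotype-group contrasts of a phenotype
#'
#' Three modes mirroring the analyses a dosage-dependent trait calls for:
#' `"ttest"` compares two genotype groups with an equal-variance
#' two-sample t-test; `"anova"` compares three (or more) groups by
#' one-way ANOVA with pairwise t-tests; `"regression"` fits
#' `y ~ dosage + age` and reports the allele-substitution effect (the
#' dosage coefficient), its SE and p-value, and the percent variance
#' explained `100 * SS_dosage / SS_total` with dosage entered after the
#' age covariate (sequential sums of squares; the label records the
#' formula used).
#'
#' @param y phenotype vector.
#' @param dosage genotype group / allele dosage vector.
#' @param age optional age covariate (regression mode).
#' @param mode `"ttest"`, `"anova"` or `"regression"`.
#' @return list of results; see details per mode.
#' @export
groupContrasts <- function(y, dosage, age = NULL,
                           mode = c("regression", "ttest", "anova")) {
  mode <- match.arg(mode)
  if (mode == "ttest") {
    gs <- sort(unique(dosage))
    if (length(gs) != 2L) stop("t-test mode needs exactly two groups")
    g1 <- y[dosage == gs[1]]; g2 <- y[dosage == gs[2]]
    if (length(g1) < 2L || length(g2) < 2L)
      stop("need >= 2 observations per group")
    if (stats::var(g1) == 0 && stats::var(g2) == 0 &&
        mean(g1) == mean(g2))
      return(list(t = 0, p = 1, meanDiff = 0))
    tt <- stats::t.test(g2, g1, var.equal = TRUE)
    return(list(t = unname(tt$statistic), p = tt$p.value,
                meanDiff = mean(g2) - mean(g1)))
  }
  if (mode == "anova") {
    f <- factor(dosage)
    if (nlevels(f) < 2L) stop("need >= 2 groups")
    if (any(tapply(y, f, stats::var) == 0))
      stop("zero within-group variance")
    av <- stats::aov(y ~ f)
    s <- summary(av)[[1]]
    lv <- levels(f)
    pw <- list()
    for (i in seq_len(nlevels(f) - 1L))
      for (j in (i + 1L):nlevels(f)) {
        tt <- stats::t.test(y[f == lv[j]], y[f == lv[i]], var.equal = TRUE)
        pw[[paste(lv[j], "vs", lv[i])]] <-
          c(t = unname(tt$statistic), p = tt$p.value)
      }
    return(list(F = s$`F value`[1], p = s$`Pr(>F)`[1], pairwise = pw))
  }
  # regression mode
  dat <- if (is.null(age)) data.frame(y = y, dosage = dosage)
         else data.frame(y = y, dosage = dosage, age = age)
  fm <- if (is.null(age)) y ~ dosage else y ~ age + dosage
  fit <- stats::lm(fm, data = dat)
  cf <- summary(fit)$coefficients["dosage", ]
  an <- stats::anova(fit)            # sequential: age first, dosage second
  pctVar <- 100 * an["dosage", "Sum Sq"] / sum(an[, "Sum Sq"])
  list(effect = unname(cf["Estimate"]), se = unname(cf["Std. Error"]),
       p = unname(cf["Pr(>|t|)"]), pctVar = pctVar,
       pctVarFormula = "100 * SS_dosage / SS_total (sequential, age first)",
       n = length(fit$residuals))
}
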