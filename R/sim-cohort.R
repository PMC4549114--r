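#' Simulate a carcass-trait cohort of carrier and non-carrier steers
#'
#' A single-sire progeny cohort for the regression stage: `nNonCarrier`
#' steers with risk-allele dosage 0 and `nCarrier` with dosage 1, a
#' slaughter-age covariate, and a residual chosen so that the total
#' phenotypic SD matches `sdTotal`:
#'
#' `y = mean + effect * dosage + ageSlope * (age - mean age) + e`
#'
#' with `Var(e) = sdTotal^2 - Var(effect * dosage) - Var(age term)`.
#'
#' @param effect allele substitution effect (kg).
#' @param sdTotal target total phenotypic SD (kg).
#' @param nNonCarrier,nCarrier group sizes.
#' @param meanTrait cohort mean (kg).
#' @param ageMean,ageSd slaughter-age distribution (days).
#' @param ageSlope fixed age effect (kg/day).
#' @param seed RNG seed.
#' @return data.frame: `id`, `dosage`, `ageDays`, `carcassWeight`.
#' @export
simulateCarcassCohort <- function(effect = 33.9, sdTotal = 65.3,
                                  nNonCarrier = 86L, nCarrier = 85L,
                                  meanTrait = 495.9,
                                  ageMean = 900, ageSd = 30,
                                  ageSlope = 0.5, seed = 1L) {
  n <- nNonCarrier + nCarrier
  dosage <- c(rep(0L, nNonCarrier), rep(1L, nCarrier))
  p <- nCarrier / n
  varDosage <- p * (1 - p) * effect^2
  varAge <- (ageSlope * ageSd)^2
  residVar <- sdTotal^2 - varDosage - varAge
  if (residVar <= 0) stop("effect/age terms exceed the total variance")
  set.seed(seed)
  age <- stats::rnorm(n, ageMean, ageSd)
  y <- meanTrait + effect * dosage + ageSlope * (age - ageMean) +
    stats::rnorm(n, 0, sqrt(residVar))
  data.frame(id = sprintf("R-%03d", seq_len(n)), dosage = dosage,
             ageDays = age, carcassWeight = y)
}

#' Read the packaged carcass-trait configuration
#'
#' The fixture mirrors the published carcass-trait summary for the
#' carrier/non-carrier progeny comparison: trait mean, SD, allele
#' substitution effect and group sizes.
#'
#' @param path YAML file; default: the packaged fixture.
#' @return named list.
#' @export
readCarcassConfig <- function(path = system.file(
  "extdata", "carcass_cohort_config.yaml", package = "PositionalQTL")) {
  yaml::read_yaml(path)
}

#' Read the packaged skeletal-deviation table
#'
#' Sigma deviations of chest depth, chest width, thurl width and pin-bone
#' width for risk-allele homozygotes and a non-carrier control, with the
#' published flags and the external poor-development diagnosis indicator.
#'
#' @param path TSV file; default: the packaged fixture.
#' @return data.frame.
#' @export
readDeviationTable <- function(path = system.file(
  "extdata", "skeletal_deviations.tsv", package = "PositionalQTL")) {
  d <- utils::read.delim(path, na.strings = c("NA", ""))
  d$externalDiagnosis <- as.logical(d$externalDiagnosis)
  d
}
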