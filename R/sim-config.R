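#' Simulation configuration
#'
#' Bundles every parameter of the study generator.  Defaults emulate the
#' architecture the mapping stages assume: one founder sire carrying a
#' single QTN haplotype on a BTA8-like chromosome, an additive effect on
#' carcass weight (+33.9 kg per risk allele against a total phenotypic SD
#' of 65.3 kg), a height effect with no effect on chest width, recessive
#' disease expression with configurable penetrance and misdiagnosis rate,
#' and unrelated dams drawn from Beta-distributed founder allele
#' frequencies.
#'
#' @param seed integer master seed.  Each generated table draws from its
#'   own stream seeded at `seed + <fixed offset>`, so adding one table does
#'   not perturb the others.
#' @param nMarkers number of markers on the simulated chromosome.
#' @param chromLengthBp chromosome length in bp.
#' @param cmPerMb genetic map scaling (constant; Haldane, no interference).
#' @param founderAlleleFreqAlpha,founderAlleleFreqBeta Beta parameters for
#'   founder allele frequencies.
#' @param qtnPositionBp physical position of the planted QTN (default:
#'   76% of the chromosome length, the relative position of the mapped
#'   candidate region on the BTA8-like template).
#' @param qtnEffectKg allele substitution effect on carcass weight (kg).
#' @param qtnHeightEffectCm allele effect on withers height (cm); chest
#'   width gets none.
#' @param chestDeficitSd chest-width deficit of QTN homozygotes, in sigma
#'   units of the growth standard (negative).
#' @param polygenicVar,residualVar variance components of carcass weight
#'   (kg^2).
#' @param baselineKg intercept of carcass weight.
#' @param ageSlopeKgPerDay fixed slaughter-age effect on carcass weight.
#' @param nSires number of half-sib sires (sons of the founder).
#' @param offspringPerSire offspring per sire family.
#' @param damCarrierFreq probability that a dam carries one copy of the
#'   founder risk haplotype (0 by default; raise it to produce QTN
#'   homozygotes for the recessive-disease stages).
#' @param penetranceHom probability a QTN homozygote is labelled affected.
#' @param misdiagnosisRate probability a non-homozygote is labelled
#'   affected anyway (cf. discordant diagnoses in the field data).
#' @param fixedEffects named list mapping factor names to named numeric
#'   vectors of level offsets (e.g. slaughter year, slaughterhouse).
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nMarkers = 400L,
                      chromLengthBp = 1.13e8,
                      cmPerMb = 1.0,
                      founderAlleleFreqAlpha = 2,
                      founderAlleleFreqBeta = 2,
                      qtnPositionBp = round(0.76 * chromLengthBp),
                      qtnEffectKg = 33.9,
                      qtnHeightEffectCm = 2.0,
                      chestDeficitSd = -2.5,
                      polygenicVar = 1200,
                      residualVar = 3000,
                      baselineKg = 495.9,
                      ageSlopeKgPerDay = 0.5,
                      nSires = 3L,
                      offspringPerSire = 60L,
                      damCarrierFreq = 0,
                      penetranceHom = 1.0,
                      misdiagnosisRate = 0,
                      fixedEffects = list()) {
  cfg <- list(seed = as.integer(seed), nMarkers = as.integer(nMarkers),
              chromLengthBp = chromLengthBp, cmPerMb = cmPerMb,
              founderAlleleFreqAlpha = founderAlleleFreqAlpha,
              founderAlleleFreqBeta = founderAlleleFreqBeta,
              qtnPositionBp = qtnPositionBp, qtnEffectKg = qtnEffectKg,
              qtnHeightEffectCm = qtnHeightEffectCm,
              chestDeficitSd = chestDeficitSd,
              polygenicVar = polygenicVar, residualVar = residualVar,
              baselineKg = baselineKg,
              ageSlopeKgPerDay = ageSlopeKgPerDay,
              nSires = as.integer(nSires),
              offspringPerSire = as.integer(offspringPerSire),
              damCarrierFreq = damCarrierFreq,
              penetranceHom = penetranceHom,
              misdiagnosisRate = misdiagnosisRate,
              fixedEffects = fixedEffects)
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (cfg$chromLengthBp <= 0) stop("configuration error: non-positive chromosome length")
  if (cfg$qtnPositionBp <= 0 || cfg$qtnPositionBp > cfg$chromLengthBp)
    stop("configuration error: QTN outside the chromosome")
  if (cfg$polygenicVar < 0 || cfg$residualVar < 0)
    stop("configuration error: negative variance")
  for (r in c(cfg$penetranceHom, cfg$misdiagnosisRate, cfg$damCarrierFreq))
    if (r < 0 || r > 1) stop("configuration error: rate outside [0, 1]")
  if (cfg$nMarkers < 2L) stop("configuration error: need >= 2 markers")
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `readSimConfig` returns a `SimConfig`; `writeSimConfig` its path,
#'   invisibly.
#' @export
readSimConfig <- function(path) {
  do.call(simConfig, yaml::read_yaml(path))
}

#' @rdname readSimConfig
#' @param config a `SimConfig`.
#' @export
writeSimConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
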