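#' Assemble a SireFamily from a simulated study
#'
#' Pulls one sire's phased haplotypes, its offspring genotypes, a
#' phenotype column and covariate columns out of a [simulateStudy()]
#' result.
#'
#' @param study the list returned by [simulateStudy()].
#' @param sireId the sire (e.g. `"S1"`).
#' @param trait phenotype column of `study$phenotypes`.
#' @param covariates covariate column names (default slaughter age).
#' @return A [SireFamily-class].
#' @export
familyFromStudy <- function(study, sireId, trait = "carcassWeight",
                            covariates = "ageDays") {
  ped <- study$pedigree
  off <- ped$id[!is.na(ped$sire) & ped$sire == sireId]
  off <- intersect(off, individualIds(study$panel))
  if (!length(off)) stop("no genotyped offspring for sire ", sireId)
  p <- study$panel
  offPanel <- genotypePanel(study$map,
                            p@a1[off, , drop = FALSE],
                            p@a2[off, , drop = FALSE], phased = FALSE)
  idx <- match(off, study$phenotypes$id)
  sireFamily(sireId,
             p@a1[sireId, ], p@a2[sireId, ],
             offPanel,
             study$phenotypes[[trait]][idx],
             study$phenotypes[idx, covariates, drop = FALSE])
}
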