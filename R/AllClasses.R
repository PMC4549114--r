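#' @import methods
NULL

#' Marker map
#'
#' Ordered marker coordinates on one or more chromosomes: physical position
#' in base pairs (1-based) and genetic position in centimorgans.  Physical
#' positions must be strictly increasing within a chromosome and genetic
#' positions non-decreasing.
#'
#' @slot chrom character, chromosome id per marker.
#' @slot name character, unique marker names.
#' @slot pos numeric, 1-based physical position (bp).
#' @slot cm numeric, genetic position (cM).
#' @exportClass MarkerMap
setClass("MarkerMap",
  representation(chrom = "character", name = "character",
                 pos = "numeric", cm = "numeric"))

setValidity("MarkerMap", function(object) {
  n <- length(object@pos)
  if (length(object@chrom) != n || length(object@name) != n ||
      length(object@cm) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@name))
    return("duplicated marker name")
  for (ch in unique(object@chrom)) {
    i <- object@chrom == ch
    if (is.unsorted(object@pos[i], strictly = TRUE))
      return(sprintf("positions not strictly increasing on chromosome %s", ch))
    if (is.unsorted(object@cm[i]))
      return(sprintf("genetic positions decrease on chromosome %s", ch))
  }
  TRUE
})

#' Construct a MarkerMap
#'
#' @param chrom chromosome id (recycled if scalar).
#' @param name marker names; defaults to `M1..Mn`.
#' @param pos physical positions, bp (1-based).
#' @param cm genetic positions, cM; defaults to `pos * cmPerMb / 1e6`.
#' @param cmPerMb map scaling used when `cm` is missing.
#' @return A [MarkerMap-class] object.
#' @export
markerMap <- function(chrom, pos, name = NULL, cm = NULL, cmPerMb = 1.0) {
  n <- length(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (is.null(name)) name <- paste0("M", seq_len(n))
  if (is.null(cm)) cm <- pos * cmPerMb / 1e6
  new("MarkerMap", chrom = as.character(chrom), name = as.character(name),
      pos = as.numeric(pos), cm = as.numeric(cm))
}

#' Diploid genotype panel
#'
#' Genotypes for a set of individuals over a [MarkerMap-class].  The two
#' allele matrices hold one allele each (individuals x markers, character;
#' `NA` = missing).  When `phased` is `TRUE` the `a1`/`a2` slots are
#' haplotypes; otherwise allele order within a genotype is normalized
#' lexicographically so genotype equality is well defined.
#'
#' @slot map a [MarkerMap-class].
#' @slot a1,a2 character matrices, individuals x markers, rownames = ids.
#' @slot phased logical scalar.
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  representation(map = "MarkerMap", a1 = "matrix", a2 = "matrix",
                 phased = "logical"))

setValidity("GenotypePanel", function(object) {
  m <- length(object@map@pos)
  if (ncol(object@a1) != m || ncol(object@a2) != m)
    return("allele matrices do not match the marker map")
  if (!identical(dim(object@a1), dim(object@a2)))
    return("allele matrices differ in dimension")
  if (is.null(rownames(object@a1)))
    return("individual ids (rownames) required")
  if (anyDuplicated(rownames(object@a1)))
    return("duplicated individual id")
  TRUE
})

#' Construct a GenotypePanel
#'
#' @param map a [MarkerMap-class].
#' @param a1,a2 allele matrices (individuals x markers); rownames are ids.
#' @param phased logical; are `a1`/`a2` haplotypes?
#' @return A [GenotypePanel-class].
#' @export
genotypePanel <- function(map, a1, a2, phased = FALSE) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "character"; storage.mode(a2) <- "character"
  rownames(a2) <- rownames(a1)
  if (!phased) {
    swap <- !is.na(a1) & !is.na(a2) & a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  new("GenotypePanel", map = map, a1 = a1, a2 = a2, phased = phased)
}

#' Phased haplotype panel with founder-origin labels
#'
#' Extends [GenotypePanel-class] (always phased) with per-allele
#' founder-origin labels (strings such as `"X.1"`, meaning haplotype 1 of
#' founder X) and per-haplotype QTN carrier flags.
#'
#' @slot origin1,origin2 character matrices parallel to `a1`/`a2`.
#' @slot qtn1,qtn2 logical vectors, one per individual: does that haplotype
#'   carry the planted QTN allele?
#' @exportClass HaplotypePanel
setClass("HaplotypePanel", contains = "GenotypePanel",
  representation(origin1 = "matrix", origin2 = "matrix",
                 qtn1 = "logical", qtn2 = "logical"))

setValidity("HaplotypePanel", function(object) {
  if (!object@phased) return("haplotype panel must be phased")
  if (!identical(dim(object@origin1), dim(object@a1)) ||
      !identical(dim(object@origin2), dim(object@a2)))
    return("origin matrices do not match allele matrices")
  n <- nrow(object@a1)
  if (length(object@qtn1) != n || length(object@qtn2) != n)
    return("QTN carrier flags do not match individuals")
  TRUE
})

#' Half-open genomic interval
#'
#' A segment `[start, end)` in bp on one chromosome.  All interval logic in
#' the package (confidence intervals, IBD segments, risk haplotypes) uses
#' this one convention; marker coordinates stay 1-based.
#'
#' @slot chrom character scalar.
#' @slot start,end numeric, `0 <= start <= end`.
#' @exportClass GenomicInterval
setClass("GenomicInterval",
  representation(chrom = "character", start = "numeric", end = "numeric"))

setValidity("GenomicInterval", function(object) {
  if (length(object@chrom) != 1L) return("one chromosome per interval")
  if (object@start < 0 || object@end < object@start)
    return("need 0 <= start <= end")
  TRUE
})

#' Construct a GenomicInterval
#' @param chrom chromosome id.
#' @param start,end half-open bounds in bp.
#' @return A [GenomicInterval-class].
#' @export
genomicInterval <- function(chrom, start, end)
  new("GenomicInterval", chrom = as.character(chrom),
      start = as.numeric(start), end = as.numeric(end))

#' Haplotype segment shared identical-by-descent
#'
#' @slot carriers ids of the individuals carrying the segment.
#' @slot interval inner bound: [GenomicInterval-class] spanning the outermost
#'   agreeing markers.
#' @slot outer conservative outer bound extended to the flanking markers.
#' @slot alleles consensus allele per marker inside the segment.
#' @slot markerIndex integer range (first, last) of matched markers.
#' @exportClass SharedSegment
setClass("SharedSegment",
  representation(carriers = "character", interval = "GenomicInterval",
                 outer = "GenomicInterval", alleles = "character",
                 markerIndex = "integer"))

#' One paternal half-sib family
#'
#' The unit of within-family interval mapping: a phased sire and its
#' offspring with phenotype and fixed-effect covariates.
#'
#' @slot sireId character scalar.
#' @slot hap1,hap2 sire haplotypes over `offspring@map`.
#' @slot offspring a [GenotypePanel-class] of the offspring.
#' @slot phenotype numeric, one value per offspring.
#' @slot covariates data.frame of fixed effects (may have zero columns).
#' @exportClass SireFamily
setClass("SireFamily",
  representation(sireId = "character", hap1 = "character", hap2 = "character",
                 offspring = "GenotypePanel", phenotype = "numeric",
                 covariates = "data.frame"))

setValidity("SireFamily", function(object) {
  m <- length(object@offspring@map@pos)
  n <- nrow(object@offspring@a1)
  if (length(object@hap1) != m || length(object@hap2) != m)
    return("sire haplotypes do not match the marker map")
  if (length(object@phenotype) != n)
    return("phenotype length does not match offspring")
  if (nrow(object@covariates) != n && ncol(object@covariates) > 0)
    return("covariate rows do not match offspring")
  TRUE
})

#' Construct a SireFamily
#' @param sireId sire id.
#' @param hap1,hap2 phased sire haplotypes.
#' @param offspring offspring [GenotypePanel-class].
#' @param phenotype numeric phenotype per offspring.
#' @param covariates data.frame of fixed-effect covariates (optional).
#' @return A [SireFamily-class].
#' @export
sireFamily <- function(sireId, hap1, hap2, offspring, phenotype,
                       covariates = data.frame()) {
  if (nrow(covariates) == 0 && ncol(covariates) == 0)
    covariates <- data.frame(row.names = rownames(offspring@a1))
  new("SireFamily", sireId = as.character(sireId),
      hap1 = as.character(hap1), hap2 = as.character(hap2),
      offspring = offspring, phenotype = as.numeric(phenotype),
      covariates = covariates)
}

#' Result of a within-family QTL scan
#'
#' @slot profile data.frame: `cm`, `bp`, `F`, `effect` per grid position.
#' @slot peakCm,peakBp,peakF,effect,pctVar scalars describing the peak.
#' @slot residDf residual degrees of freedom of the full model.
#' @slot thresholds named numeric, chromosome-wise permutation thresholds
#'   (empty until [permutationThreshold()] is run).
#' @slot ci the 95% bootstrap [GenomicInterval-class] or `NULL`.
#' @slot ciReliable logical; `FALSE` when the peak is below the 5% threshold.
#' @exportClass QtlScan
setClass("QtlScan",
  representation(profile = "data.frame", peakCm = "numeric",
                 peakBp = "numeric", peakF = "numeric", effect = "numeric",
                 pctVar = "numeric", residDf = "numeric",
                 thresholds = "numeric", ci = "ANY",
                 ciReliable = "logical"))

setValidity("QtlScan", function(object) {
  if (any(object@profile$F < -1e-8, na.rm = TRUE)) return("negative F")
  if (length(object@pctVar) &&
      (object@pctVar < 0 || object@pctVar > 100))
    return("% variance explained outside [0, 100]")
  TRUE
})

#' Normal growth standard for one measurement
#'
#' Gompertz mean curve `A * exp(-b * exp(-k * t))` over age `t` in days,
#' with an age-dependent standard deviation given as a piecewise-linear
#' table.
#'
#' @slot measurement,sexClass character; sexClass is one of
#'   `"sire"`, `"female"`, `"steer"`.
#' @slot A,b,k Gompertz parameters (`A` = adult asymptote, units of the
#'   measurement; `k` in 1/day).
#' @slot sigmaTable data.frame `age`, `sigma` for linear interpolation.
#' @slot ageRange numeric(2), validity range in days.
#' @exportClass GrowthStandard
setClass("GrowthStandard",
  representation(measurement = "character", sexClass = "character",
                 A = "numeric", b = "numeric", k = "numeric",
                 sigmaTable = "data.frame", ageRange = "numeric"))

setValidity("GrowthStandard", function(object) {
  if (object@A <= 0 || object@k <= 0) return("need A > 0 and k > 0")
  if (any(object@sigmaTable$sigma <= 0)) return("sigma(t) must be positive")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    return("invalid age range")
  TRUE
})

#' Construct a GrowthStandard
#' @param measurement measurement name (e.g. `"withers_height"`).
#' @param sexClass `"sire"`, `"female"` or `"steer"`.
#' @param A,b,k Gompertz mean-curve parameters.
#' @param sigmaTable data.frame with columns `age` (days) and `sigma`.
#' @param ageRange validity range in days.
#' @return A [GrowthStandard-class].
#' @export
growthStandard <- function(measurement, sexClass, A, b, k, sigmaTable,
                           ageRange) {
  new("GrowthStandard", measurement = measurement, sexClass = sexClass,
      A = as.numeric(A), b = as.numeric(b), k = as.numeric(k),
      sigmaTable = as.data.frame(sigmaTable), ageRange = as.numeric(ageRange))
}

#' Coding gene model
#'
#' Ordered CDS exons of one gene; exon coordinates are 1-based inclusive
#' genomic bp (as in GFF3), stored in genomic order.  `strand` decides the
#' reading direction.
#'
#' @slot geneId character scalar.
#' @slot chrom character scalar.
#' @slot strand `"+"` or `"-"`.
#' @slot exons data.frame with columns `start`, `end` (1-based inclusive).
#' @exportClass GeneModel
setClass("GeneModel",
  representation(geneId = "character", chrom = "character",
                 strand = "character", exons = "data.frame"))

setValidity("GeneModel", function(object) {
  ex <- object@exons
  if (!all(c("start", "end") %in% names(ex))) return("exons need start/end")
  if (any(ex$end < ex$start)) return("exon end before start")
  if (nrow(ex) > 1) {
    o <- order(ex$start)
    if (any(ex$start[o][-1] <= ex$end[o][-nrow(ex)]))
      return("exons overlap")
  }
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  TRUE
})

#' Construct a GeneModel
#' @param geneId gene id.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame of CDS exons (`start`, `end`, 1-based inclusive).
#' @return A [GeneModel-class].
#' @export
geneModel <- function(geneId, chrom, strand, exons) {
  exons <- as.data.frame(exons)[order(exons$start), , drop = FALSE]
  new("GeneModel", geneId = geneId, chrom = as.character(chrom),
      strand = strand, exons = exons)
}
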