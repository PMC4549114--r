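#' Number of markers
#' @param x a MarkerMap or GenotypePanel.
#' @return integer.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname nMarkers
#' @export
setMethod("nMarkers", "MarkerMap", function(x) length(x@pos))

#' @rdname nMarkers
#' @export
setMethod("nMarkers", "GenotypePanel", function(x) ncol(x@a1))

#' Number of individuals in a panel
#' @param x a GenotypePanel.
#' @return integer.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname nIndividuals
#' @export
setMethod("nIndividuals", "GenotypePanel", function(x) nrow(x@a1))

#' Individual ids of a panel
#' @param x a GenotypePanel.
#' @return character vector.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname individualIds
#' @export
setMethod("individualIds", "GenotypePanel", function(x) rownames(x@a1))

#' Marker map of an object
#' @param x a GenotypePanel or SireFamily.
#' @return a [MarkerMap-class].
#' @export
setGeneric("getMap", function(x) standardGeneric("getMap"))

#' @rdname getMap
#' @export
setMethod("getMap", "GenotypePanel", function(x) x@map)

#' @rdname getMap
#' @export
setMethod("getMap", "SireFamily", function(x) x@offspring@map)

#' Marker physical positions (bp)
#' @param x a MarkerMap.
#' @return numeric vector.
#' @export
setGeneric("markerPos", function(x) standardGeneric("markerPos"))

#' @rdname markerPos
#' @export
setMethod("markerPos", "MarkerMap", function(x) x@pos)

#' Marker genetic positions (cM)
#' @param x a MarkerMap.
#' @return numeric vector.
#' @export
setGeneric("markerCm", function(x) standardGeneric("markerCm"))

#' @rdname markerCm
#' @export
setMethod("markerCm", "MarkerMap", function(x) x@cm)

#' Marker names
#' @param x a MarkerMap.
#' @return character vector.
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname markerNames
#' @export
setMethod("markerNames", "MarkerMap", function(x) x@name)

#' Genotype alleles
#'
#' Accessors for the two allele matrices of a panel (haplotypes when the
#' panel is phased).
#' @param x a GenotypePanel.
#' @return character matrix, individuals x markers.
#' @export
setGeneric("alleles1", function(x) standardGeneric("alleles1"))

#' @rdname alleles1
#' @export
setMethod("alleles1", "GenotypePanel", function(x) x@a1)

#' @rdname alleles1
#' @export
setGeneric("alleles2", function(x) standardGeneric("alleles2"))

#' @rdname alleles1
#' @export
setMethod("alleles2", "GenotypePanel", function(x) x@a2)

#' Is the panel phased?
#' @param x a GenotypePanel.
#' @return logical scalar.
#' @export
setGeneric("isPhased", function(x) standardGeneric("isPhased"))

#' @rdname isPhased
#' @export
setMethod("isPhased", "GenotypePanel", function(x) x@phased)

#' QTN haplotype dosage of each individual
#'
#' Counts the QTN-carrying haplotypes (0/1/2) recorded in a
#' [HaplotypePanel-class].
#' @param x a HaplotypePanel.
#' @return named integer vector.
#' @export
setGeneric("qtnDosage", function(x) standardGeneric("qtnDosage"))

#' @rdname qtnDosage
#' @export
setMethod("qtnDosage", "HaplotypePanel", function(x) {
  d <- as.integer(x@qtn1) + as.integer(x@qtn2)
  names(d) <- rownames(x@a1)
  d
})

#' QTL scan profile
#' @param x a QtlScan.
#' @return data.frame with `cm`, `bp`, `F`, `effect`.
#' @export
setGeneric("scanProfile", function(x) standardGeneric("scanProfile"))

#' @rdname scanProfile
#' @export
setMethod("scanProfile", "QtlScan", function(x) x@profile)

#' Peak summary of a QTL scan
#' @param x a QtlScan.
#' @return list with `cm`, `bp`, `F`, `effect`, `pctVar`.
#' @export
setGeneric("scanPeak", function(x) standardGeneric("scanPeak"))

#' @rdname scanPeak
#' @export
setMethod("scanPeak", "QtlScan", function(x)
  list(cm = x@peakCm, bp = x@peakBp, F = x@peakF,
       effect = x@effect, pctVar = x@pctVar))

#' Segment carriers
#' @param x a SharedSegment.
#' @return character vector of carrier ids.
#' @export
setGeneric("segmentCarriers", function(x) standardGeneric("segmentCarriers"))

#' @rdname segmentCarriers
#' @export
setMethod("segmentCarriers", "SharedSegment", function(x) x@carriers)

#' Segment interval
#' @param x a SharedSegment.
#' @param outer use the conservative outer (flanking-marker) bound?
#' @return a [GenomicInterval-class].
#' @export
setGeneric("segmentInterval",
           function(x, outer = FALSE) standardGeneric("segmentInterval"))

#' @rdname segmentInterval
#' @export
setMethod("segmentInterval", "SharedSegment",
          function(x, outer = FALSE) if (outer) x@outer else x@interval)

setMethod("show", "MarkerMap", function(object) {
  cat(sprintf("MarkerMap: %d markers on %s; %.3f-%.3f Mb (%.1f cM)\n",
              nMarkers(object), paste(unique(object@chrom), collapse = ","),
              min(object@pos) / 1e6, max(object@pos) / 1e6,
              diff(range(object@cm))))
})

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("%s: %d individuals x %d markers (%s)\n",
              class(object), nIndividuals(object), nMarkers(object),
              if (object@phased) "phased" else "unphased"))
})

setMethod("show", "GenomicInterval", function(object) {
  cat(sprintf("GenomicInterval %s:[%s, %s) (%.3f Mb)\n", object@chrom,
              format(object@start, big.mark = ","),
              format(object@end, big.mark = ","),
              (object@end - object@start) / 1e6))
})

setMethod("show", "SharedSegment", function(object) {
  cat(sprintf("SharedSegment: %d carriers, %d markers\n",
              length(object@carriers),
              if (length(object@markerIndex) == 2L)
                object@markerIndex[2] - object@markerIndex[1] + 1L else 0L))
  show(object@interval)
})

setMethod("show", "SireFamily", function(object) {
  cat(sprintf("SireFamily %s: %d offspring, %d markers, %d covariates\n",
              object@sireId, nIndividuals(object@offspring),
              nMarkers(object@offspring), ncol(object@covariates)))
})

setMethod("show", "QtlScan", function(object) {
  cat(sprintf(
    "QtlScan: peak F = %.2f at %.1f cM (%.2f Mb), effect = %.2f, %%var = %.1f\n",
    object@peakF, object@peakCm, object@peakBp / 1e6, object@effect,
    object@pctVar))
  if (length(object@thresholds))
    cat("  thresholds:",
        paste(sprintf("%s=%.2f", names(object@thresholds),
                      object@thresholds), collapse = ", "), "\n")
  if (!is.null(object@ci)) {
    cat(sprintf("  95%% CI%s: ",
                if (isFALSE(object@ciReliable)) " (unreliable)" else ""))
    show(object@ci)
  }
})

setMethod("show", "GrowthStandard", function(object) {
  cat(sprintf(
    "GrowthStandard %s/%s: Gompertz A=%.1f b=%.3f k=%.5f, ages %d-%d d\n",
    object@measurement, object@sexClass, object@A, object@b, object@k,
    round(object@ageRange[1]), round(object@ageRange[2])))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s%s): %d CDS exons, %d coding bp\n",
              object@geneId, object@chrom, object@strand,
              nrow(object@exons),
              sum(object@exons$end - object@exons$start + 1)))
})
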