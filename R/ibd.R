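# allele of a slot matching consensus?  missing genotypes are wildcards
# (the field's microsatellite panels are sparse).
.matchesAllele <- function(allele, consensus) is.na(allele) | allele == consensus

#' Haplotype shared by a set of individuals around an anchor
#'
#' Finds the maximal interval around `anchorBp` in which one haplotype per
#' individual agrees with a common allele sequence at every non-missing
#' marker, by greedy bidirectional extension breaking at the first marker
#' with no consensus allele.  Each individual's candidate haplotype slots
#' are tracked jointly, so heterozygous individuals stay unresolved as
#' long as either slot fits.
#'
#' @param panel a phased [GenotypePanel-class] (or [HaplotypePanel-class]).
#' @param individuals ids to intersect.
#' @param anchorBp physical position (bp) to anchor the search; the
#'   nearest marker is used.
#' @return A [SharedSegment-class]; zero-length (no markers) when no common
#'   haplotype exists at the anchor.
#' @export
sharedHaplotype <- function(panel, individuals, anchorBp) {
  if (!panel@phased) stop("panel must be phased")
  stopifnot(all(individuals %in% individualIds(panel)))
  map <- panel@map
  pos <- markerPos(map)
  if (anchorBp < min(pos) || anchorBp > max(pos))
    stop("anchor outside the map")
  anchor <- which.min(abs(pos - anchorBp))
  H <- list(panel@a1[individuals, , drop = FALSE],
            panel@a2[individuals, , drop = FALSE])
  n <- length(individuals)
  m <- ncol(H[[1]])
  chrom <- unique(map@chrom)[1]

  # candidate consensus alleles at marker j given per-individual live slots
  consensusAt <- function(j, slots) {
    obs <- unique(stats::na.omit(c(H[[1]][cbind(which(slots[, 1]), j)],
                                   H[[2]][cbind(which(slots[, 2]), j)])))
    ok <- vapply(obs, function(a) {
      all(vapply(seq_len(n), function(i) {
        (slots[i, 1] && .matchesAllele(H[[1]][i, j], a)) ||
          (slots[i, 2] && .matchesAllele(H[[2]][i, j], a))
      }, logical(1)))
    }, logical(1))
    if (!length(obs)) return(NA_character_)   # all missing: wildcard marker
    if (!any(ok)) return(character(0))
    sort(obs[ok])[1]
  }
  updateSlots <- function(j, a, slots) {
    if (is.na(a)) return(slots)
    cbind(slots[, 1] & .matchesAllele(H[[1]][, j], a),
          slots[, 2] & .matchesAllele(H[[2]][, j], a))
  }

  slots <- matrix(TRUE, n, 2)
  a0 <- consensusAt(anchor, slots)
  if (length(a0) == 0L)
    return(new("SharedSegment", carriers = character(0),
               interval = genomicInterval(chrom, pos[anchor], pos[anchor]),
               outer = genomicInterval(chrom, pos[anchor], pos[anchor]),
               alleles = character(0), markerIndex = integer(0)))
  slots <- updateSlots(anchor, a0, slots)
  alleles <- stats::setNames(a0, map@name[anchor])
  lo <- hi <- anchor
  repeat {
    if (lo == 1L) break
    a <- consensusAt(lo - 1L, slots)
    if (length(a) == 0L) break
    slots <- updateSlots(lo - 1L, a, slots)
    lo <- lo - 1L
    alleles <- c(stats::setNames(a, map@name[lo]), alleles)
  }
  repeat {
    if (hi == m) break
    a <- consensusAt(hi + 1L, slots)
    if (length(a) == 0L) break
    slots <- updateSlots(hi + 1L, a, slots)
    hi <- hi + 1L
    alleles <- c(alleles, stats::setNames(a, map@name[hi]))
  }
  inner <- genomicInterval(chrom, pos[lo], pos[hi])
  outer <- genomicInterval(chrom,
                           if (lo > 1L) pos[lo - 1L] else pos[1],
                           if (hi < m) pos[hi + 1L] else pos[m])
  new("SharedSegment", carriers = individuals, interval = inner,
      outer = outer, alleles = unname(alleles),
      markerIndex = c(lo, hi))
}

#' Locate a recombination breakpoint
#'
#' For a haplotype that matches reference `hapA` on the left and `hapB` on
#' the right, returns the interval between the last left-matching and the
#' first right-matching marker, which brackets the crossover.  Missing
#' alleles are wildcards.
#'
#' @param hap the recombinant haplotype.
#' @param hapA,hapB the two reference haplotypes.
#' @param map a [MarkerMap-class].
#' @return A [GenomicInterval-class].
#' @export
locateBreakpoint <- function(hap, hapA, hapB, map) {
  m <- nMarkers(map)
  stopifnot(length(hap) == m, length(hapA) == m, length(hapB) == m)
  matchA <- is.na(hap) | is.na(hapA) | hap == hapA
  matchB <- is.na(hap) | is.na(hapB) | hap == hapB
  if (all(matchA))
    stop("no transition: haplotype matches hapA throughout")
  # last marker distinctively on hapA, first distinctively on hapB
  onlyA <- which(matchA & !matchB)
  onlyB <- which(matchB & !matchA)
  if (!length(onlyA) || !length(onlyB))
    stop("no transition found")
  lastA <- max(onlyA)
  firstB <- min(onlyB[onlyB > lastA], Inf)
  if (!is.finite(firstB)) stop("no transition found")
  if (any(!matchA[seq_len(lastA)] & !matchB[seq_len(lastA)]) ||
      any(!matchB[firstB:m] & !matchA[firstB:m]))
    stop("haplotype is not a single hapA->hapB mosaic")
  pos <- markerPos(map)
  genomicInterval(unique(map@chrom)[1], pos[lastA], pos[firstB])
}

#' Refine a QTL interval from linkage, IBD and recombinant evidence
#'
#' Intersects the family confidence intervals with the shared
#' identical-by-descent segment, then removes regions excluded by
#' recombinant carriers whose phenotype contradicts carriage (e.g. a
#' risk-haplotype tail carried by a non-segregating sire).  The
#' conservative outer bound of the shared segment is used.  If an
#' exclusion splits the interval, the longer piece is kept.
#'
#' @param ciList list of [GenomicInterval-class] confidence intervals.
#' @param sharedQ a [SharedSegment-class] or [GenomicInterval-class].
#' @param exclusions list of [GenomicInterval-class] regions ruled out by
#'   contradictory recombinants (optional).
#' @return A [GenomicInterval-class].
#' @export
refineInterval <- function(ciList, sharedQ, exclusions = list()) {
  shared <- if (is(sharedQ, "SharedSegment"))
    segmentInterval(sharedQ, outer = TRUE) else sharedQ
  cur <- intersectIntervals(c(ciList, list(shared)))
  if (intervalLength(cur) == 0)
    stop("inconsistent evidence: empty intersection")
  for (ex in exclusions) {
    pieces <- subtractInterval(cur, ex)
    if (!length(pieces))
      stop("inconsistent evidence: exclusion removes the whole interval")
    lens <- vapply(pieces, intervalLength, numeric(1))
    cur <- pieces[[which.max(lens)]]
  }
  cur
}
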