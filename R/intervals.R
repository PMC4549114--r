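#' Interval length in bp
#'
#' Length of a half-open interval, `end - start`.
#'
#' @param iv a [GenomicInterval-class].
#' @return numeric, bp.
#' @examples
#' intervalLength(genomicInterval("8", 84180000, 86540000))  # 2.36 Mb
#' @export
intervalLength <- function(iv) {
  stopifnot(is(iv, "GenomicInterval"))
  iv@end - iv@start
}

#' Intersect genomic intervals
#'
#' Intersection of a list of intervals on one chromosome:
#' `[max(starts), min(ends))`.  An empty intersection is reported as a
#' zero-length interval at `max(starts)`.
#'
#' @param ivs list of [GenomicInterval-class] objects (non-empty, same
#'   chromosome).
#' @return a [GenomicInterval-class].
#' @export
intersectIntervals <- function(ivs) {
  if (length(ivs) == 0L) stop("empty interval list")
  stopifnot(all(vapply(ivs, is, logical(1), "GenomicInterval")))
  chroms <- vapply(ivs, function(iv) iv@chrom, character(1))
  if (length(unique(chroms)) > 1L)
    stop("intervals on mixed chromosomes: ",
         paste(unique(chroms), collapse = ", "))
  s <- max(vapply(ivs, function(iv) iv@start, numeric(1)))
  e <- min(vapply(ivs, function(iv) iv@end, numeric(1)))
  genomicInterval(chroms[1], s, max(s, e))
}

#' Subtract one interval from another
#'
#' Set difference `a \ b` of half-open intervals; returns a list of 0, 1 or
#' 2 intervals.
#'
#' @param a,b [GenomicInterval-class] objects on the same chromosome.
#' @return list of [GenomicInterval-class].
#' @export
subtractInterval <- function(a, b) {
  stopifnot(is(a, "GenomicInterval"), is(b, "GenomicInterval"))
  if (a@chrom != b@chrom) return(list(a))
  out <- list()
  if (b@start > a@start)
    out <- c(out, list(genomicInterval(a@chrom, a@start,
                                       min(a@end, b@start))))
  if (b@end < a@end)
    out <- c(out, list(genomicInterval(a@chrom, max(a@start, b@end), a@end)))
  Filter(function(iv) intervalLength(iv) > 0, out)
}
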