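#' Runs of homozygosity for one individual
#'
#' Maximal marker stretches with no heterozygous call, at most
#' `maxMissing` missing calls, and at least `minMarkers` markers.  With a
#' missing-call allowance, maximal valid stretches can overlap; each
#' reported segment is maximal in the sense that it cannot be extended on
#' either side.
#'
#' @param panel a [GenotypePanel-class].
#' @param individual id.
#' @param minMarkers minimum markers per segment (default 20, about 1 Mb
#'   at 50k-chip density).
#' @param maxMissing missing calls tolerated per segment (default 1).
#' @return data.frame: `start`, `end` (marker indices), `startBp`,
#'   `endBp`, `nMarkers`, `nMissing`; zero rows when none.
#' @export
detectRoh <- function(panel, individual, minMarkers = 20L, maxMissing = 1L) {
  stopifnot(individual %in% individualIds(panel))
  a1 <- panel@a1[individual, ]; a2 <- panel@a2[individual, ]
  m <- length(a1)
  miss <- is.na(a1) | is.na(a2)
  het <- !miss & a1 != a2
  segs <- list()
  # blocks between heterozygous calls
  bounds <- c(0L, which(het), m + 1L)
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L; hi <- bounds[b + 1L] - 1L
    if (hi < lo) next
    mpos <- which(miss[lo:hi]) + lo - 1L
    if (length(mpos) <= maxMissing) {
      segs <- c(segs, list(c(lo, hi)))
    } else {
      # windows holding exactly maxMissing missings, extended to the
      # markers flanking the excluded missing calls
      t <- length(mpos)
      for (s in 0:(t - maxMissing)) {
        from <- if (s == 0L) lo else mpos[s] + 1L
        to <- if (s + maxMissing + 1L > t) hi else mpos[s + maxMissing + 1L] - 1L
        segs <- c(segs, list(c(from, to)))
      }
    }
  }
  segs <- Filter(function(s) s[2] - s[1] + 1L >= minMarkers, segs)
  pos <- markerPos(panel@map)
  if (!length(segs))
    return(data.frame(start = integer(0), end = integer(0),
                      startBp = numeric(0), endBp = numeric(0),
                      nMarkers = integer(0), nMissing = integer(0)))
  out <- do.call(rbind, lapply(segs, function(s)
    data.frame(start = s[1], end = s[2], startBp = pos[s[1]],
               endBp = pos[s[2]], nMarkers = s[2] - s[1] + 1L,
               nMissing = sum(miss[s[1]:s[2]]))))
  out[order(out$start, out$end), , drop = FALSE]
}

# control-estimated allele frequency with 0.5 pseudocount (avoids log 0)
controlFreq <- function(panel, controls) {
  a1 <- panel@a1[controls, , drop = FALSE]
  a2 <- panel@a2[controls, , drop = FALSE]
  lapply(seq_len(ncol(a1)), function(j) {
    al <- c(a1[, j], a2[, j])
    al <- al[!is.na(al)]
    tab <- table(al)
    (tab + 0.5) / (sum(tab) + 1)
  })
}

# -log10(fhat^2) weight of allele a at marker j
homWeight <- function(freqs, j, a) {
  f <- freqs[[j]][a]
  if (is.na(f)) f <- 0.5 / 1      # allele unseen in controls
  -2 * log10(as.numeric(f))
}

# cases homozygous at marker j for the modal shared allele
scoredCases <- function(a1, a2, j) {
  hom <- !is.na(a1[, j]) & !is.na(a2[, j]) & a1[, j] == a2[, j]
  if (!any(hom)) return(NULL)
  tab <- sort(table(a1[hom, j]), decreasing = TRUE)
  a <- names(tab)[1]
  if (sum(tab == tab[1]) > 1)      # tie: lexicographically first
    a <- sort(names(tab)[tab == tab[1]])[1]
  list(allele = a, cases = rownames(a1)[hom & a1[, j] == a])
}

# extend the shared homozygous run of case set `cs` around marker j;
# missing calls are wildcards inside the run.  Returns indices and the
# consensus allele per marker.
extendRun <- function(a1, a2, cs, j, alleleJ) {
  m <- ncol(a1)
  consensusOk <- function(k) {
    x1 <- a1[cs, k]; x2 <- a2[cs, k]
    het <- !is.na(x1) & !is.na(x2) & x1 != x2
    if (any(het)) return(NA_character_)
    obs <- unique(x1[!is.na(x1)])
    if (length(obs) == 0L) return("")          # all missing: wildcard
    if (length(obs) > 1L) return(NA_character_)
    obs
  }
  lo <- hi <- j
  alleles <- stats::setNames(alleleJ, j)
  while (lo > 1L) {
    a <- consensusOk(lo - 1L)
    if (is.na(a)) break
    lo <- lo - 1L
    alleles <- c(stats::setNames(a, lo), alleles)
  }
  while (hi < m) {
    a <- consensusOk(hi + 1L)
    if (is.na(a)) break
    hi <- hi + 1L
    alleles <- c(alleles, stats::setNames(a, hi))
  }
  list(lo = lo, hi = hi, alleles = alleles)
}

asshomStat <- function(a1, a2, freqs, contribFilter = NULL) {
  m <- ncol(a1)
  miss <- is.na(a1) | is.na(a2)
  hom <- !miss & a1 == a2
  # precompute each individual's per-marker homozygosity rarity weight
  n <- nrow(a1)
  wHom <- matrix(0, n, m)
  for (r in seq_len(n)) for (k in which(hom[r, ]))
    wHom[r, k] <- homWeight(freqs, k, a1[r, k])
  score <- numeric(m)
  for (j in seq_len(m)) {
    sc <- scoredCases(a1, a2, j)
    if (is.null(sc)) next
    cs <- sc$cases
    if (!is.null(contribFilter)) cs <- contribFilter(cs, j, sc$allele)
    if (!length(cs)) next
    # each case sharing the anchor allele contributes the rarity weights
    # over its own maximal homozygous run around the anchor (missing
    # calls are wildcards contributing no weight)
    for (r in match(cs, rownames(a1))) {
      ok <- miss[r, ] | hom[r, ]
      lo <- j; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
      hi <- j; while (hi < m && ok[hi + 1L]) hi <- hi + 1L
      score[j] <- score[j] + sum(wHom[r, lo:hi])
    }
  }
  score
}

#' Case-control shared-homozygosity scan
#'
#' At each marker, the cases homozygous for the common (modal) allele are
#' scored by the rarity of homozygosity in controls: each such case
#' contributes `-log10(fhat^2)` (control allele frequency with a 0.5
#' pseudocount) summed over the maximal homozygous run it maintains
#' around the marker.  The genome-wide p-value is the fraction of
#' case/control label permutations whose maximum score reaches the
#' observed maximum, with a +1 continuity correction so that p > 0.
#'
#' This score is this package's operationalization of shared-homozygosity
#' mapping; it is designed to localize recessive loci, not to reproduce
#' any external program's numeric values.
#'
#' @param panel a [GenotypePanel-class].
#' @param cases,controls individual ids (>= 3 cases; controls estimate
#'   allele frequencies).
#' @param nPerm label permutations.
#' @param seed RNG seed.
#' @return list: `score` (per marker), `maxScore`, `peakMarker`, `pGenome`,
#'   `permMax`.
#' @export
asshomScan <- function(panel, cases, controls, nPerm = 1000L, seed = 1L) {
  if (length(cases) < 1L) stop("need at least one case")
  if (length(cases) < 3L)
    warning("fewer than 3 cases: the scan has little localizing power")
  stopifnot(all(c(cases, controls) %in% individualIds(panel)))
  obs <- asshomStat(panel@a1[cases, , drop = FALSE],
                    panel@a2[cases, , drop = FALSE],
                    controlFreq(panel, controls))
  set.seed(seed)
  all_ <- c(cases, controls)
  permMax <- vapply(seq_len(nPerm), function(b) {
    pc <- sample(all_, length(cases))
    pk <- setdiff(all_, pc)
    max(asshomStat(panel@a1[pc, , drop = FALSE],
                   panel@a2[pc, , drop = FALSE],
                   controlFreq(panel, pk)))
  }, numeric(1))
  list(score = obs, maxScore = max(obs), peakMarker = which.max(obs),
       pGenome = (1 + sum(permMax >= max(obs))) / (1 + nPerm),
       permMax = permMax)
}

#' Pedigree-consistent autozygosity scan
#'
#' As [asshomScan()], but a case contributes at a marker only if its
#' shared homozygous allele is consistent with descent from its sire:
#' the sire (when genotyped in the panel) must carry that allele on at
#' least one haplotype; ungenotyped or absent sires leave the case
#' unconstrained.
#'
#' @inheritParams asshomScan
#' @param pedigree data.frame `id`, `sire`, `dam` covering every case.
#' @return as [asshomScan()].
#' @export
assistScan <- function(panel, cases, controls, pedigree, nPerm = 1000L,
                       seed = 1L) {
  if (length(cases) < 1L) stop("need at least one case")
  if (!all(cases %in% pedigree$id))
    stop("pedigree missing case(s): ",
         paste(setdiff(cases, pedigree$id), collapse = ", "))
  ids <- individualIds(panel)
  sireOf <- stats::setNames(pedigree$sire, pedigree$id)
  filt <- function(cs, j, a) {
    keep <- vapply(cs, function(c_) {
      s <- sireOf[c_]
      if (is.na(s) || !(s %in% ids)) return(TRUE)   # unconstrained
      s1 <- panel@a1[s, j]; s2 <- panel@a2[s, j]
      if (is.na(s1) && is.na(s2)) return(TRUE)
      isTRUE(s1 == a) || isTRUE(s2 == a)
    }, logical(1))
    cs[keep]
  }
  obs <- asshomStat(panel@a1[cases, , drop = FALSE],
                    panel@a2[cases, , drop = FALSE],
                    controlFreq(panel, controls), contribFilter = filt)
  set.seed(seed)
  all_ <- c(cases, controls)
  permMax <- vapply(seq_len(nPerm), function(b) {
    pc <- sample(all_, length(cases))
    pk <- setdiff(all_, pc)
    pf <- function(cs, j, a) {
      keep <- vapply(cs, function(c_) {
        s <- if (c_ %in% names(sireOf)) sireOf[c_] else NA
        if (is.na(s) || !(s %in% ids)) return(TRUE)
        s1 <- panel@a1[s, j]; s2 <- panel@a2[s, j]
        if (is.na(s1) && is.na(s2)) return(TRUE)
        isTRUE(s1 == a) || isTRUE(s2 == a)
      }, logical(1))
      cs[keep]
    }
    max(asshomStat(panel@a1[pc, , drop = FALSE],
                   panel@a2[pc, , drop = FALSE],
                   controlFreq(panel, pk), contribFilter = pf))
  }, numeric(1))
  list(score = obs, maxScore = max(obs), peakMarker = which.max(obs),
       pGenome = (1 + sum(permMax >= max(obs))) / (1 + nPerm),
       permMax = permMax)
}

#' Maximal shared homozygous risk region among cases
#'
#' Over all anchor markers and alleles, finds the haplotype and maximal
#' interval maximizing the number of cases homozygous for it (missing
#' calls inside the interval are wildcards); ties are broken by the
#' longest interval, then the leftmost.  The reported interval runs from
#' the first to the last agreeing marker (half-open at the last marker
#' position, so its length is the bp distance between the outermost
#' markers).
#'
#' @param panel a [GenotypePanel-class].
#' @param cases >= 2 case ids.
#' @param minShareFraction anchors with a carrier fraction below this are
#'   ignored (default 0: best anywhere).
#' @return list: `segment` (a [SharedSegment-class]), `nSharing`,
#'   `nCases`, `fraction` (percent, 1 decimal).
#' @export
sharedHomozygousRegion <- function(panel, cases, minShareFraction = 0) {
  if (length(cases) < 2L) stop("need at least 2 cases")
  a1 <- panel@a1[cases, , drop = FALSE]
  a2 <- panel@a2[cases, , drop = FALSE]
  m <- ncol(a1)
  pos <- markerPos(panel@map)
  chrom <- unique(panel@map@chrom)[1]
  best <- NULL
  for (j in seq_len(m)) {
    hom <- !is.na(a1[, j]) & !is.na(a2[, j]) & a1[, j] == a2[, j]
    for (a in unique(a1[hom, j])) {
      cs <- cases[hom & a1[, j] == a]
      if (length(cs) < 2L || length(cs) / length(cases) < minShareFraction)
        next
      if (!is.null(best) && length(cs) < best$n) next
      run <- extendRun(a1, a2, cs, j, a)
      len <- pos[run$hi] - pos[run$lo]
      cand <- list(n = length(cs), len = len, lo = run$lo, hi = run$hi,
                   cases = cs, alleles = run$alleles)
      if (is.null(best) ||
          cand$n > best$n ||
          (cand$n == best$n && (cand$len > best$len ||
             (cand$len == best$len && cand$lo < best$lo))))
        best <- cand
    }
  }
  if (is.null(best)) stop("no two cases share homozygosity anywhere")
  seg <- new("SharedSegment", carriers = best$cases,
             interval = genomicInterval(chrom, pos[best$lo], pos[best$hi]),
             outer = genomicInterval(
               chrom,
               if (best$lo > 1L) pos[best$lo - 1L] else pos[1],
               if (best$hi < m) pos[best$hi + 1L] else pos[m]),
             alleles = unname(unlist(best$alleles)),
             markerIndex = c(best$lo, best$hi))
  list(segment = seg, nSharing = best$n, nCases = length(cases),
       fraction = round(100 * best$n / length(cases), 1))
}
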