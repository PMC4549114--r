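#' Three-way segregation filter for candidate variants
#'
#' A record passes iff every animal of `hetGroup` is ref/alt heterozygous,
#' every animal of `homAGroup` is homozygous for one allele, every animal
#' of `homBGroup` is homozygous for the other, and those two alleles
#' differ.  A missing or absent genotype fails the record with reason
#' `"missing genotype"`.
#'
#' @param geno character matrix of genotypes `"A/G"` (variants x animals,
#'   colnames = animal ids; `NA` = missing).
#' @param ref,alt allele vectors, one per variant.
#' @param hetGroup,homAGroup,homBGroup disjoint animal id sets.
#' @return data.frame: `pass` (logical), `reason` (character, `""` when
#'   passing).
#' @export
segregationFilter <- function(geno, ref, alt, hetGroup, homAGroup,
                              homBGroup) {
  groups <- c(hetGroup, homAGroup, homBGroup)
  if (anyDuplicated(groups)) stop("animal groups must be disjoint")
  missingAnimals <- setdiff(groups, colnames(geno))
  nv <- nrow(geno)
  pass <- logical(nv); reason <- character(nv)
  splitGt <- function(g) strsplit(g, "[/|]")
  for (v in seq_len(nv)) {
    gts <- geno[v, ]
    if (length(missingAnimals) || any(is.na(gts[groups]))) {
      reason[v] <- "missing genotype"; next
    }
    al <- splitGt(gts[groups])
    if (any(vapply(al, length, integer(1)) != 2L)) {
      reason[v] <- "malformed genotype"; next
    }
    het <- al[seq_along(hetGroup)]
    homA <- al[length(hetGroup) + seq_along(homAGroup)]
    homB <- al[length(hetGroup) + length(homAGroup) + seq_along(homBGroup)]
    refAlt <- c(ref[v], alt[v])
    hetOk <- all(vapply(het, function(g)
      g[1] != g[2] && all(sort(g) == sort(refAlt)), logical(1)))
    if (!hetOk) { reason[v] <- "het group not ref/alt heterozygous"; next }
    aAl <- unique(unlist(homA)); bAl <- unique(unlist(homB))
    if (length(aAl) != 1L) { reason[v] <- "homA group not uniformly homozygous"; next }
    if (length(bAl) != 1L) { reason[v] <- "homB group not uniformly homozygous"; next }
    if (aAl == bAl) { reason[v] <- "hom groups share the same allele"; next }
    pass[v] <- TRUE
  }
  data.frame(pass = pass, reason = reason)
}

#' Low-coverage gaps within coding regions
#'
#' Maximal sub-intervals of the CDS where an animal's read depth falls
#' below `minDepth` (such regions are the ones a follow-up Sanger pass
#' must cover).  Positions of the regions absent from the depth table are
#' an error.
#'
#' @param depth data.frame: `animal`, `pos`, `depth` (per-base).
#' @param model a [GeneModel-class] whose CDS exons define the regions.
#' @param minDepth threshold (default 4 reads).
#' @return named list per animal of lists of [GenomicInterval-class]
#'   (half-open).
#' @export
coverageGaps <- function(depth, model, minDepth = 4L) {
  cds <- model@exons
  animals <- unique(depth$animal)
  out <- stats::setNames(vector("list", length(animals)), animals)
  for (an in animals) {
    d <- depth[depth$animal == an, ]
    dmap <- stats::setNames(d$depth, d$pos)
    gaps <- list()
    for (e in seq_len(nrow(cds))) {
      ppos <- cds$start[e]:cds$end[e]
      dv <- dmap[as.character(ppos)]
      if (anyNA(dv))
        stop("region outside depth table for animal ", an)
      low <- dv < minDepth
      r <- rle(low)
      endsAt <- cumsum(r$lengths)
      startsAt <- endsAt - r$lengths + 1L
      for (k in which(r$values)) {
        gaps <- c(gaps, list(genomicInterval(
          model@chrom, ppos[startsAt[k]], ppos[endsAt[k]] + 1L)))
      }
    }
    out[[an]] <- gaps
  }
  out
}

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
          Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
          L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
          S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
          `*` = "Ter")

revComp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

translateCodon <- function(codon) {
  aa <- seqinr::translate(strsplit(toupper(codon), "")[[1]])
  aa
}

#' Coding-effect annotation of a variant
#'
#' Translates the codon containing the site before and after substitution,
#' honoring strand.  ATG changed away at codon 1 gives `"start-loss"`;
#' an unchanged residue is `"synonymous"`; otherwise `"non-synonymous"`
#' with a `Xaa-pos-Yaa` label.  Additional substitutions in the same
#' codon (e.g. two SNPs in complete linkage disequilibrium) can be applied
#' jointly via `jointWith`.
#'
#' @param model a [GeneModel-class].
#' @param genomeSeq chromosome sequence as a single character string
#'   (1-based; only the CDS region need be correct).
#' @param pos,ref,alt the variant (SNP: single bases).
#' @param jointWith optional data.frame `pos`, `ref`, `alt` of
#'   substitutions applied in the same codon jointly.
#' @return list: `annotation` (`"none"`, `"synonymous"`,
#'   `"non-synonymous"`, `"start-loss"`, `"indel-unclassified"`),
#'   `label` (e.g. `"His-171-Cys"`), `codonIndex`, `refCodon`,
#'   `altCodon`.
#' @export
annotateCoding <- function(model, genomeSeq, pos, ref, alt,
                           jointWith = NULL) {
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    return(list(annotation = "indel-unclassified", label = NA_character_,
                codonIndex = NA_integer_, refCodon = NA_character_,
                altCodon = NA_character_))
  cds <- model@exons
  cdsPos <- unlist(lapply(seq_len(nrow(cds)), function(e)
    cds$start[e]:cds$end[e]))                  # genomic order
  if (!(pos %in% cdsPos))
    return(list(annotation = "none", label = NA_character_,
                codonIndex = NA_integer_, refCodon = NA_character_,
                altCodon = NA_character_))
  if (model@strand == "-") cdsPos <- rev(cdsPos)
  cdsSeq <- vapply(cdsPos, function(p) substr(genomeSeq, p, p),
                   character(1))
  if (model@strand == "-")
    cdsSeq <- chartr("ACGTacgt", "TGCAtgca", cdsSeq)
  idx <- match(pos, cdsPos)
  subs <- data.frame(pos = pos, ref = ref, alt = alt)
  if (!is.null(jointWith)) subs <- rbind(subs, jointWith)
  altSeq <- cdsSeq
  for (r in seq_len(nrow(subs))) {
    i <- match(subs$pos[r], cdsPos)
    if (is.na(i)) stop("joint substitution outside the CDS")
    expRef <- if (model@strand == "-")
      chartr("ACGT", "TGCA", toupper(subs$ref[r])) else toupper(subs$ref[r])
    if (toupper(cdsSeq[i]) != expRef)
      stop(sprintf("reference mismatch at %d: CDS has %s", subs$pos[r],
                   cdsSeq[i]))
    altSeq[i] <- if (model@strand == "-")
      chartr("ACGT", "TGCA", toupper(subs$alt[r])) else toupper(subs$alt[r])
  }
  codonIdx <- (idx - 1L) %/% 3L + 1L
  cr <- (codonIdx - 1L) * 3L + 1:3
  refCodon <- paste(toupper(cdsSeq[cr]), collapse = "")
  altCodon <- paste(toupper(altSeq[cr]), collapse = "")
  refAA <- translateCodon(refCodon)
  altAA <- translateCodon(altCodon)
  if (codonIdx == 1L && refCodon == "ATG" && altCodon != "ATG") {
    ann <- "start-loss"
    label <- sprintf("Met-1-%s", .AA3[altAA])
  } else if (refAA == altAA) {
    ann <- "synonymous"
    label <- sprintf("%s-%d-%s", .AA3[refAA], codonIdx, .AA3[altAA])
  } else {
    ann <- "non-synonymous"
    label <- sprintf("%s-%d-%s", .AA3[refAA], codonIdx, .AA3[altAA])
  }
  list(annotation = ann, label = unname(label), codonIndex = codonIdx,
       refCodon = refCodon, altCodon = altCodon)
}

#' Read a coding gene model from GFF3
#'
#' Extracts the CDS features of one gene from a GFF3 file.
#'
#' @param path GFF3 file.
#' @param geneId value of the `ID`/`Parent` attribute identifying the
#'   gene or transcript.
#' @return A [GeneModel-class].
#' @export
readGeneModelGff3 <- function(path, geneId) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  owner <- vapply(seq_along(cds), function(i) {
    p <- cds$Parent[[i]]
    any(grepl(geneId, c(as.character(p), cds$ID[i]), fixed = TRUE))
  }, logical(1))
  cds <- cds[owner]
  if (!length(cds)) stop("no CDS found for ", geneId)
  geneModel(geneId,
            as.character(GenomicRanges::seqnames(cds))[1],
            as.character(BiocGenerics::strand(cds))[1],
            data.frame(start = GenomicRanges::start(cds),
                       end = GenomicRanges::end(cds)))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' From phased haplotypes, `r^2 = D^2 / (pA qA pB qB)` with `D` from
#' haplotype counts; from unphased genotypes, haplotype frequencies are
#' first obtained by the standard two-locus EM iterated to a
#' log-likelihood change below `tol`.
#'
#' @param hapA,hapB allele vectors at the two loci: per haplotype when
#'   `phased = TRUE`, else per-individual genotype strings `"A/G"`.
#' @param phased are the inputs phased haplotypes?
#' @param tol EM convergence tolerance on the log-likelihood.
#' @return r-squared (scalar).
#' @export
ldR2 <- function(hapA, hapB, phased = TRUE, tol = 1e-10) {
  if (phased) {
    ok <- !is.na(hapA) & !is.na(hapB)
    a <- hapA[ok]; b <- hapB[ok]
    aA <- sort(unique(a)); aB <- sort(unique(b))
    if (length(aA) != 2L || length(aB) != 2L)
      stop("monomorphic or multi-allelic locus: r2 undefined")
    pA <- mean(a == aA[1]); pB <- mean(b == aB[1])
    pAB <- mean(a == aA[1] & b == aB[1])
    D <- pAB - pA * pB
    return(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  }
  # unphased: EM over the four haplotype frequencies
  gA <- strsplit(hapA, "[/|]"); gB <- strsplit(hapB, "[/|]")
  ok <- !vapply(gA, anyNA, logical(1)) & !vapply(gB, anyNA, logical(1)) &
    !is.na(hapA) & !is.na(hapB)
  gA <- gA[ok]; gB <- gB[ok]
  alA <- sort(unique(unlist(gA))); alB <- sort(unique(unlist(gB)))
  if (length(alA) != 2L || length(alB) != 2L)
    stop("monomorphic or multi-allelic locus: r2 undefined")
  dA <- vapply(gA, function(g) sum(g == alA[1]), numeric(1))  # dosage 0/1/2
  dB <- vapply(gB, function(g) sum(g == alB[1]), numeric(1))
  n <- length(dA)
  # haplotype freqs h = c(AB, Ab, aB, ab)
  pA <- mean(dA) / 2; pB <- mean(dB) / 2
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  h <- pmax(h, 1e-6); h <- h / sum(h)
  cnt <- table(factor(dA, 0:2), factor(dB, 0:2))
  N <- function(i, j) cnt[as.character(i), as.character(j)]
  logLik <- function(h) {
    p <- matrix(0, 3, 3)
    p[3, 3] <- h[1]^2;           p[3, 2] <- 2 * h[1] * h[2]
    p[3, 1] <- h[2]^2;           p[2, 3] <- 2 * h[1] * h[3]
    p[2, 1] <- 2 * h[2] * h[4];  p[1, 3] <- h[3]^2
    p[1, 2] <- 2 * h[3] * h[4];  p[1, 1] <- h[4]^2
    p[2, 2] <- 2 * (h[1] * h[4] + h[2] * h[3])
    s <- 0
    for (i in 0:2) for (j in 0:2)
      if (N(i, j) > 0) s <- s + N(i, j) * log(p[i + 1, j + 1])
    s
  }
  ll <- logLik(h)
  repeat {
    # E-step: only double heterozygotes are phase-ambiguous
    p11 <- h[1] * h[4] / (h[1] * h[4] + h[2] * h[3])
    nAB <- 2 * N(2, 2) + N(2, 1) + N(1, 2) + N(1, 1) * p11
    nAb <- 2 * N(2, 0) + N(2, 1) + N(1, 0) + N(1, 1) * (1 - p11)
    naB <- 2 * N(0, 2) + N(0, 1) + N(1, 2) + N(1, 1) * (1 - p11)
    nab <- 2 * N(0, 0) + N(0, 1) + N(1, 0) + N(1, 1) * p11
    h <- c(nAB, nAb, naB, nab) / (2 * n)
    llNew <- logLik(pmax(h, 1e-12))
    if (abs(llNew - ll) < tol) break
    ll <- llNew
  }
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}
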