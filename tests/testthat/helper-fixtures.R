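# Shared fixture builders.  Everything is generated in code; seeds are
# fixed per call site.

# uniform map of m markers, spacingCm apart, 1 cM/Mb
evenMap <- function(m, spacingCm = 1, chrom = "8") {
  pos <- seq(1e6, by = spacingCm * 1e6, length.out = m)
  markerMap(chrom, pos, cm = pos / 1e6)
}

# panel from explicit haplotype string matrices ("A"/"B" rows per id)
panelFromHaps <- function(map, h1, h2, ids = NULL, phased = TRUE) {
  h1 <- do.call(rbind, h1); h2 <- do.call(rbind, h2)
  if (is.null(ids)) ids <- paste0("I", seq_len(nrow(h1)))
  rownames(h1) <- rownames(h2) <- ids
  genotypePanel(map, h1, h2, phased = phased)
}

# a half-sib family with known sire phase: offspring paternal gametes are
# dropped through the map; dams contribute allele "C" everywhere so every
# marker is fully informative.
informativeFamily <- function(nOff, map, sireH1, sireH2, phenotype = NULL,
                              covariates = NULL, seed = 1) {
  set.seed(seed)
  m <- nMarkers(map)
  pat <- t(vapply(seq_len(nOff), function(i)
    as.character(dropGamete(sireH1, sireH2, map)), character(m)))
  mat <- matrix("C", nOff, m)
  rownames(pat) <- rownames(mat) <- paste0("O", seq_len(nOff))
  off <- genotypePanel(map, pat, mat, phased = FALSE)
  if (is.null(phenotype)) phenotype <- rnorm(nOff)
  if (is.null(covariates))
    covariates <- data.frame(row.names = rownames(pat))
  sireFamily("SIRE", sireH1, sireH2, off, phenotype, covariates)
}

# family with a planted QTL: phenotype = effect * (paternal origin == 1
# at qtlCm) + N(0, sd); returns family plus the true origins
plantedQtlFamily <- function(nOff, m = 40, spacingCm = 1, qtlCm = NULL,
                             effect = 2, sd = 1, seed = 1) {
  map <- evenMap(m, spacingCm)
  cm <- markerCm(map)
  if (is.null(qtlCm)) qtlCm <- stats::median(cm)
  sireH1 <- rep("A", m); sireH2 <- rep("B", m)
  set.seed(seed)
  pat <- matrix("", nOff, m)
  orig <- integer(nOff)
  for (i in seq_len(nOff)) {
    g <- dropGamete(sireH1, sireH2, map)
    pat[i, ] <- g
    og <- attr(g, "origin")
    # origin at qtlCm from the crossover points
    xo <- attr(g, "crossovers")
    start <- og[1]
    k <- findInterval(qtlCm, xo)
    orig[i] <- if (k %% 2 == 0) start else 3L - start
  }
  mat <- matrix("C", nOff, m)
  rownames(pat) <- rownames(mat) <- paste0("O", seq_len(nOff))
  y <- effect * (orig == 1L) + rnorm(nOff, 0, sd)
  fam <- sireFamily("SIRE", sireH1, sireH2,
                    genotypePanel(map, pat, mat, phased = FALSE),
                    y, data.frame(row.names = rownames(pat)))
  list(family = fam, qtlCm = qtlCm, origin = orig)
}

# smallest seed for which the first `k` sires of the simulated study are
# QTN heterozygotes (construction requirement, independent of outcomes)
seedWithCarrierSires <- function(cfg, k = cfg$nSires, from = 1L) {
  for (s in from:(from + 200L)) {
    cfg$seed <- s
    st <- simulateStudy(cfg)
    d <- qtnDosage(st$panel)[paste0("S", seq_len(k))]
    if (all(d == 1L)) return(list(seed = s, study = st))
  }
  stop("no suitable seed found")
}
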