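#' Haldane map function
#'
#' Converts genetic distance to recombination fraction assuming no
#' interference: `r = 0.5 * (1 - exp(-2 d))`.
#'
#' @param d distance in Morgans (non-negative; vectorized).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("negative genetic distance")
  0.5 * (1 - exp(-2 * d))
}

#' Paternal-origin indicators for a half-sib family
#'
#' For each offspring and marker, which sire haplotype (1 or 2) was
#' transmitted, where this is determined by the genotypes alone.  A marker
#' is uninformative (`NA`) for an offspring when the sire is homozygous,
#' the call is missing, or sire and offspring are heterozygous for the
#' same two alleles (dam unknown).
#'
#' @param family a [SireFamily-class] (sire phased).
#' @return integer matrix, offspring x markers, entries 1/2/`NA`.
#' @export
paternalOrigin <- function(family) {
  s1 <- family@hap1; s2 <- family@hap2
  o1 <- family@offspring@a1; o2 <- family@offspring@a2
  m <- length(s1); n <- nrow(o1)
  out <- matrix(NA_integer_, n, m, dimnames = list(rownames(o1), NULL))
  het <- !is.na(s1) & !is.na(s2) & s1 != s2
  for (j in which(het)) {
    x1 <- o1[, j]; x2 <- o2[, j]
    has1 <- (x1 == s1[j]) | (x2 == s1[j])
    has2 <- (x1 == s2[j]) | (x2 == s2[j])
    ok <- !is.na(x1) & !is.na(x2)
    out[ok & has1 & !has2, j] <- 1L
    out[ok & !has1 & has2, j] <- 2L
    # both (sire-het/offspring-het same alleles) or neither: NA
  }
  out
}

# P(paternal origin = 1 at x | flanking origin indicators), Haldane.
# origin: integer matrix from paternalOrigin(); cm: marker genetic
# positions; x: one grid position.  Returns a probability per offspring.
transmissionAt <- function(origin, cm, x) {
  n <- nrow(origin)
  p <- rep(0.5, n)
  for (i in seq_len(n)) {
    inf <- which(!is.na(origin[i, ]))
    if (!length(inf)) next
    lefts <- inf[cm[inf] <= x]
    rights <- inf[cm[inf] >= x]
    L <- if (length(lefts)) lefts[length(lefts)] else NA
    R <- if (length(rights)) rights[1] else NA
    if (!is.na(L) && abs(cm[L] - x) < 1e-9) { p[i] <- 2L - origin[i, L]; next }
    if (!is.na(R) && abs(cm[R] - x) < 1e-9) { p[i] <- 2L - origin[i, R]; next }
    if (!is.na(L) && !is.na(R)) {
      rL <- haldane((x - cm[L]) / 100); rR <- haldane((cm[R] - x) / 100)
      pL <- if (origin[i, L] == 1L) 1 - rL else rL  # P(hap1 at x | left)
      pR <- if (origin[i, R] == 1L) 1 - rR else rR
      qL <- 1 - pL; qR <- 1 - pR
      p[i] <- pL * pR / (pL * pR + qL * qR)
    } else if (!is.na(L)) {
      rL <- haldane((x - cm[L]) / 100)
      p[i] <- if (origin[i, L] == 1L) 1 - rL else rL
    } else {
      rR <- haldane((cm[R] - x) / 100)
      p[i] <- if (origin[i, R] == 1L) 1 - rR else rR
    }
  }
  p
}

#' Transmission probability at a map position
#'
#' Probability that each offspring inherited sire haplotype 1 at `positionCm`,
#' computed from the nearest informative flanking markers under the
#' Haldane model (one-sided at the map ends; 0.5 with no informative
#' flank).
#'
#' @param family a [SireFamily-class].
#' @param positionCm genetic position (cM), inside the map.
#' @return numeric vector in `[0, 1]`, one per offspring.
#' @export
transmissionProb <- function(family, positionCm) {
  cm <- markerCm(getMap(family))
  if (positionCm < min(cm) - 1e-9 || positionCm > max(cm) + 1e-9)
    stop("position outside the marker map")
  if (all(is.na(family@hap1))) stop("unphased sire")
  transmissionAt(paternalOrigin(family), cm, positionCm)
}

#' Infer sire linkage phase from offspring
#'
#' At heterozygous sire markers, alleles are assigned to haplotypes 1/2 by
#' greedy chaining: for each adjacent pair of heterozygous markers the
#' orientation minimizing implied offspring recombinants is chosen by
#' majority vote.  Homozygous markers are phase-neutral.  The first
#' heterozygous marker takes the lexicographically smaller allele on
#' haplotype 1, so output is deterministic up to that global labelling.
#'
#' @param sireGeno1,sireGeno2 the sire's (unphased) allele vectors.
#' @param offspring a [GenotypePanel-class] of offspring.
#' @return list: `hap1`, `hap2` (phased haplotypes) and `linkConfidence`
#'   (per adjacent heterozygous-marker link, the vote fraction supporting
#'   the chosen orientation; `NA` when no offspring voted).
#' @export
inferSirePhase <- function(sireGeno1, sireGeno2, offspring) {
  m <- nMarkers(offspring)
  stopifnot(length(sireGeno1) == m, length(sireGeno2) == m)
  het <- which(!is.na(sireGeno1) & !is.na(sireGeno2) &
                 sireGeno1 != sireGeno2)
  if (!length(het)) stop("family uninformative: no heterozygous sire marker")
  aLo <- pmin(sireGeno1, sireGeno2)   # lexicographic labels per marker
  aHi <- pmax(sireGeno1, sireGeno2)
  # transmitted label per offspring per het marker: TRUE = aLo, NA unknown
  o1 <- offspring@a1; o2 <- offspring@a2
  trans <- matrix(NA, nrow(o1), length(het))
  for (k in seq_along(het)) {
    j <- het[k]
    hasLo <- (o1[, j] == aLo[j]) | (o2[, j] == aLo[j])
    hasHi <- (o1[, j] == aHi[j]) | (o2[, j] == aHi[j])
    ok <- !is.na(o1[, j]) & !is.na(o2[, j])
    trans[ok & hasLo & !hasHi, k] <- TRUE
    trans[ok & !hasLo & hasHi, k] <- FALSE
  }
  orient <- logical(length(het))  # TRUE: aLo on hap1
  orient[1] <- TRUE
  conf <- rep(NA_real_, max(0L, length(het) - 1L))
  for (k in seq_along(het)[-1]) {
    votes <- !is.na(trans[, k - 1]) & !is.na(trans[, k])
    same <- sum(trans[votes, k - 1] == trans[votes, k])
    diff_ <- sum(votes) - same
    keep <- same >= diff_
    orient[k] <- if (keep) orient[k - 1] else !orient[k - 1]
    conf[k - 1] <- if (sum(votes)) max(same, diff_) / sum(votes) else NA_real_
  }
  hap1 <- sireGeno1; hap2 <- sireGeno2
  hom <- is.na(sireGeno1) | is.na(sireGeno2) | sireGeno1 == sireGeno2
  hap1[hom] <- sireGeno1[hom]; hap2[hom] <- sireGeno2[hom]
  hap1[het] <- ifelse(orient, aLo[het], aHi[het])
  hap2[het] <- ifelse(orient, aHi[het], aLo[het])
  list(hap1 = hap1, hap2 = hap2, linkConfidence = conf,
       lowConfidence = length(het) == 1L)
}

# residual-projection helpers: F for adding one regressor column to X
fitScanColumns <- function(y, X, P) {
  qrX <- qr(X)
  k <- qrX$rank
  n <- length(y)
  ry <- qr.resid(qrX, y)
  rss0 <- sum(ry^2)
  RP <- qr.resid(qrX, P)              # residualized transmission columns
  spp <- colSums(RP^2)
  spy <- colSums(RP * ry)
  alpha <- ifelse(spp > 1e-12, spy / spp, NA_real_)
  rss1 <- rss0 - ifelse(spp > 1e-12, spy^2 / spp, 0)
  df <- n - k - 1L
  Fst <- ifelse(spp > 1e-12, (rss0 - rss1) / (rss1 / df), 0)
  list(F = pmax(Fst, 0), alpha = alpha, rss0 = rss0, rss1 = rss1, df = df)
}

familyDesign <- function(family) {
  if (ncol(family@covariates) > 0)
    stats::model.matrix(~ ., data = family@covariates)
  else
    matrix(1, nIndividuals(family@offspring), 1L)
}

# transmission probabilities over a cM grid: offspring x positions
transmissionGrid <- function(family, grid) {
  origin <- paternalOrigin(family)
  cm <- markerCm(getMap(family))
  vapply(grid, function(x) transmissionAt(origin, cm, x),
         numeric(nrow(origin)))
}

#' Within-family regression interval mapping
#'
#' At each grid position, fits `y = covariates + alpha * p(x)` by least
#' squares, where `p(x)` is the probability of having inherited sire
#' haplotype 1, and compares against the covariates-only model:
#' `F = (RSS0 - RSS1) / (RSS1 / (n - k - 1))`.  The reported effect is the
#' haplotype-1 minus haplotype-2 contrast `alpha`; percent variance
#' explained at the peak is `100 (RSS0 - RSS1) / RSS0`.  Ties in the
#' maximum F are broken at the leftmost position.
#'
#' @param family a [SireFamily-class] with >= 10 phenotyped offspring.
#' @param gridStepCm scan-grid step in cM (default 1).
#' @return A [QtlScan-class].
#' @export
scanFamily <- function(family, gridStepCm = 1.0) {
  n <- nIndividuals(family@offspring)
  if (sum(!is.na(family@phenotype)) < 10L)
    stop("need at least 10 phenotyped offspring")
  X <- familyDesign(family)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariates")
  map <- getMap(family)
  cm <- markerCm(map)
  grid <- seq(min(cm), max(cm), by = gridStepCm)
  P <- transmissionGrid(family, grid)
  fit <- fitScanColumns(family@phenotype, X, P)
  peak <- which.max(fit$F)            # which.max takes the leftmost tie
  bp <- stats::approx(cm, markerPos(map), xout = grid, rule = 2)$y
  pct <- 100 * (fit$rss0 - fit$rss1[peak]) / fit$rss0
  new("QtlScan",
      profile = data.frame(cm = grid, bp = bp, F = fit$F,
                           effect = fit$alpha),
      peakCm = grid[peak], peakBp = bp[peak], peakF = fit$F[peak],
      effect = fit$alpha[peak], pctVar = pct, residDf = as.numeric(fit$df),
      thresholds = numeric(0), ci = NULL, ciReliable = NA)
}

#' Chromosome-wise permutation thresholds
#'
#' Permutes phenotype rows (keeping each phenotype attached to its
#' covariates) across offspring and records the maximum F over the grid;
#' the threshold at level `a` is the `(1 - a)` quantile.
#'
#' @param family a [SireFamily-class].
#' @param nPerm number of permutations (>= 100).
#' @param alphaLevels significance levels (default 5, 1 and 0.1%).
#' @param seed RNG seed.
#' @param gridStepCm scan-grid step.
#' @return named numeric vector of thresholds, with attribute `maxF`
#'   (the permutation null sample).
#' @export
permutationThreshold <- function(family, nPerm = 1000L,
                                 alphaLevels = c(0.05, 0.01, 0.001),
                                 seed = 1L, gridStepCm = 1.0) {
  if (nPerm < 100L) stop("need at least 100 permutations")
  if (nPerm < 1 / min(alphaLevels))
    stop(sprintf("n_perm = %d cannot resolve alpha = %g", nPerm,
                 min(alphaLevels)))
  X <- familyDesign(family)
  map <- getMap(family)
  cm <- markerCm(map)
  grid <- seq(min(cm), max(cm), by = gridStepCm)
  P <- transmissionGrid(family, grid)
  y <- family@phenotype
  n <- length(y)
  set.seed(seed)
  # permuting (y, covariates) jointly == permuting the rows of P
  maxF <- vapply(seq_len(nPerm), function(b) {
    idx <- sample.int(n)
    max(fitScanColumns(y, X, P[idx, , drop = FALSE])$F)
  }, numeric(1))
  thr <- stats::quantile(maxF, 1 - alphaLevels, names = FALSE)
  names(thr) <- paste0(alphaLevels * 100, "%")
  attr(thr, "maxF") <- maxF
  thr
}

#' Bootstrap confidence interval of the QTL position
#'
#' Offspring are resampled with replacement; the 95% CI is the
#' 2.5-97.5 percentile range of the per-replicate peak positions,
#' converted to bp through the marker map.
#'
#' @param family a [SireFamily-class].
#' @param nBoot bootstrap replicates (>= 200 for use; any positive value
#'   accepted for degenerate checks).
#' @param seed RNG seed.
#' @param gridStepCm scan-grid step.
#' @param threshold5 optional 5% permutation threshold; when given and the
#'   observed peak F falls below it, the CI is flagged unreliable (but
#'   still returned).
#' @return A [GenomicInterval-class] with attributes `reliable` and
#'   `peaksCm`.
#' @export
bootstrapCi <- function(family, nBoot = 1000L, seed = 1L, gridStepCm = 1.0,
                        threshold5 = NULL) {
  X <- familyDesign(family)
  map <- getMap(family)
  cm <- markerCm(map)
  grid <- seq(min(cm), max(cm), by = gridStepCm)
  P <- transmissionGrid(family, grid)
  y <- family@phenotype
  n <- length(y)
  set.seed(seed)
  peaks <- vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(n, replace = TRUE)
    f <- fitScanColumns(y[idx], X[idx, , drop = FALSE],
                        P[idx, , drop = FALSE])$F
    grid[which.max(f)]
  }, numeric(1))
  qs <- stats::quantile(peaks, c(0.025, 0.975), names = FALSE)
  bp <- stats::approx(cm, markerPos(map), xout = qs, rule = 2)$y
  iv <- genomicInterval(unique(map@chrom)[1], bp[1], bp[2])
  reliable <- TRUE
  if (!is.null(threshold5)) {
    obs <- max(fitScanColumns(y, X, P)$F)
    reliable <- obs >= threshold5
  }
  attr(iv, "reliable") <- reliable
  attr(iv, "peaksCm") <- peaks
  iv
}
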