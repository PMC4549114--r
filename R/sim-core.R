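# RNG stream offsets, one per generated table (see simConfig docs).
.STREAM <- c(map = 1L, founders = 2L, gametes = 3L, phenotype = 4L,
             disease = 5L, growth = 6L)

withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed + .STREAM[[stream]])
  expr
}

#' Simulate a marker map
#'
#' Scatters `nMarkers` unique positions uniformly on
#' `[1, chromLengthBp]`; genetic positions follow the constant
#' `cmPerMb` scaling.
#'
#' @param config a [simConfig()] object.
#' @param chrom chromosome id for the simulated map.
#' @return A [MarkerMap-class].
#' @export
simulateMarkerMap <- function(config, chrom = "8") {
  validateSimConfig(config)
  withStream(config$seed, "map", {
    pos <- sort(sample.int(config$chromLengthBp, config$nMarkers))
    markerMap(chrom, pos, cm = pos * config$cmPerMb / 1e6)
  })
}

#' Drop one gamete through meiosis
#'
#' Haldane model, no interference: the crossover count is Poisson in the
#' map length (Morgans), crossover positions are uniform in genetic
#' distance, and the starting parental haplotype is chosen with
#' probability 1/2.
#'
#' @param hap1,hap2 the parent's phased haplotypes (character vectors over
#'   `map`).
#' @param map a [MarkerMap-class].
#' @return character vector: the gamete, with attributes `origin`
#'   (1/2 parental slot per marker) and `crossovers` (positions, cM).
#' @export
dropGamete <- function(hap1, hap2, map) {
  m <- nMarkers(map)
  if (m == 0L) stop("empty marker map")
  stopifnot(length(hap1) == m, length(hap2) == m)
  cm <- markerCm(map)
  g <- gameteOrigin(cm)
  out <- ifelse(g$origin == 1L, hap1, hap2)
  attr(out, "origin") <- g$origin
  attr(out, "crossovers") <- g$crossovers
  out
}

# Crossover machinery shared by dropGamete and the study generator:
# returns per-position origins plus the crossover points so that origin at
# an arbitrary genetic position (e.g. the QTN) can be evaluated.
gameteOrigin <- function(cm) {
  lenM <- (max(cm) - min(cm)) / 100
  nxo <- stats::rpois(1L, lenM)
  xo <- if (nxo > 0) sort(stats::runif(nxo, min(cm), max(cm))) else numeric(0)
  start <- sample(1:2, 1L)
  origin <- originAt(cm, start, xo)
  list(origin = origin, start = start, crossovers = xo)
}

originAt <- function(cmQuery, start, crossovers) {
  k <- findInterval(cmQuery, crossovers)
  ifelse(k %% 2 == 0, start, 3L - start)
}

founderHaplotypes <- function(freqs) {
  # allele "B" with per-marker frequency freqs, else "A"
  ifelse(stats::runif(length(freqs)) < freqs, "B", "A")
}

#' Simulate a full half-sib study
#'
#' Generates a pedigree descending from one founder sire (`"X"`) that
#' carries exactly one QTN haplotype, drops gametes through the pedigree
#' with recombination, and attaches phenotypes and disease labels:
#'
#' * carcass weight = baseline + fixed effects + slaughter-age effect +
#'   `qtnEffectKg` x QTN dose + polygenic value + residual;
#' * withers height gets `qtnHeightEffectCm` per allele, chest width 0;
#' * an animal is labelled affected if it is a QTN homozygote (with
#'   probability `penetranceHom`) or, regardless of genotype, with
#'   probability `misdiagnosisRate`.
#'
#' Dams are unrelated population draws; with probability
#' `damCarrierFreq` a dam carries an identical-by-descent copy of the
#' founder's risk haplotype, which is what makes homozygous (affected)
#' offspring and a shared homozygous risk region possible.
#'
#' @param config a [simConfig()] object.
#' @param includeDams also genotype the dams in the returned panel?
#'   (Default `FALSE`: dams are typically never genotyped.)
#' @return list with components `pedigree` (data.frame: id, sire, dam,
#'   sex), `panel` (a [HaplotypePanel-class]), `phenotypes` (data.frame:
#'   id, carcassWeight, withersHeight, chestWidth, ageDays and any fixed
#'   effect factors), `truth` (data.frame: id, qtnDose, affected) and
#'   `map`.
#' @export
simulateStudy <- function(config, includeDams = FALSE) {
  validateSimConfig(config)
  map <- simulateMarkerMap(config)
  cm <- markerCm(map)
  qtnCm <- config$qtnPositionBp * config$cmPerMb / 1e6
  m <- nMarkers(map)

  sires <- paste0("S", seq_len(config$nSires))
  sireDams <- paste0("DS", seq_len(config$nSires))
  nOff <- config$nSires * config$offspringPerSire
  offIds <- unlist(lapply(seq_len(config$nSires), function(i)
    paste0("S", i, "-", seq_len(config$offspringPerSire))))
  offDams <- paste0("D", seq_len(nOff))

  ped <- rbind(
    data.frame(id = "X", sire = NA_character_, dam = NA_character_,
               sex = "M"),
    data.frame(id = sireDams, sire = NA_character_, dam = NA_character_,
               sex = "F"),
    data.frame(id = offDams, sire = NA_character_, dam = NA_character_,
               sex = "F"),
    data.frame(id = sires, sire = "X", dam = sireDams, sex = "M"),
    data.frame(id = offIds,
               sire = rep(sires, each = config$offspringPerSire),
               dam = offDams, sex = "M"))
  checkPedigree(ped)

  hap <- withStream(config$seed, "founders", {
    freqs <- stats::rbeta(m, config$founderAlleleFreqAlpha,
                          config$founderAlleleFreqBeta)
    founders <- c("X", sireDams, offDams)
    H <- list()
    for (f in founders) {
      H[[f]] <- list(h1 = founderHaplotypes(freqs),
                     h2 = founderHaplotypes(freqs),
                     o1 = rep(paste0(f, ".1"), m),
                     o2 = rep(paste0(f, ".2"), m),
                     q1 = FALSE, q2 = FALSE)
    }
    # Founder sire X carries exactly one QTN haplotype (slot 1).
    H[["X"]]$q1 <- TRUE
    # Carrier dams hold an IBD copy of X's risk haplotype in slot 1.
    dams <- c(sireDams, offDams)
    carrier <- stats::runif(length(dams)) < config$damCarrierFreq
    for (d in dams[carrier]) {
      H[[d]]$h1 <- H[["X"]]$h1
      H[[d]]$o1 <- rep("X.1", m)
      H[[d]]$q1 <- TRUE
    }
    H
  })

  hap <- withStream(config$seed, "gametes", {
    nonFounders <- ped[!is.na(ped$sire), ]
    for (i in seq_len(nrow(nonFounders))) {
      id <- nonFounders$id[i]
      pat <- meiosis(hap[[nonFounders$sire[i]]], cm, qtnCm)
      mat <- meiosis(hap[[nonFounders$dam[i]]], cm, qtnCm)
      hap[[id]] <- list(h1 = pat$h, h2 = mat$h, o1 = pat$o, o2 = mat$o,
                        q1 = pat$q, q2 = mat$q)
    }
    hap
  })

  genotyped <- c("X", sires, offIds)
  if (includeDams) genotyped <- c(genotyped, sireDams, offDams)
  panel <- buildHaplotypePanel(hap, genotyped, map)

  dose <- qtnDosage(panel)[offIds]

  phen <- withStream(config$seed, "phenotype", {
    ageDays <- round(stats::rnorm(nOff, 900, 30))
    fe <- numeric(nOff)
    feCols <- list()
    for (fac in names(config$fixedEffects)) {
      lv <- config$fixedEffects[[fac]]
      assign_ <- sample(names(lv), nOff, replace = TRUE)
      fe <- fe + unname(lv[assign_])
      feCols[[fac]] <- assign_
    }
    # pedigree-propagated polygenic values
    u <- stats::setNames(numeric(nrow(ped)), ped$id)
    sa <- config$polygenicVar
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      u[id] <- if (is.na(ped$sire[i]))
        stats::rnorm(1, 0, sqrt(sa))
      else
        0.5 * (u[ped$sire[i]] + u[ped$dam[i]]) +
          stats::rnorm(1, 0, sqrt(sa / 2))
    }
    cw <- config$baselineKg + fe +
      config$ageSlopeKgPerDay * (ageDays - mean(ageDays)) +
      config$qtnEffectKg * dose + u[offIds] +
      stats::rnorm(nOff, 0, sqrt(config$residualVar))
    wh <- 128 + config$qtnHeightEffectCm * dose + stats::rnorm(nOff, 0, 3)
    chw <- 42 + stats::rnorm(nOff, 0, 2)   # no QTN effect on chest width
    out <- data.frame(id = offIds, carcassWeight = cw, withersHeight = wh,
                      chestWidth = chw, ageDays = ageDays)
    for (fac in names(feCols)) out[[fac]] <- feCols[[fac]]
    out
  })

  truth <- withStream(config$seed, "disease", {
    allDose <- qtnDosage(panel)
    affected <- logical(length(allDose))
    hom <- allDose == 2L
    affected[hom] <- stats::runif(sum(hom)) < config$penetranceHom
    affected[!hom] <- stats::runif(sum(!hom)) < config$misdiagnosisRate
    data.frame(id = names(allDose), qtnDose = as.integer(allDose),
               affected = affected)
  })

  list(pedigree = ped, panel = panel, phenotypes = phen, truth = truth,
       map = map)
}

meiosis <- function(parent, cm, qtnCm) {
  g <- gameteOrigin(cm)
  pick <- function(x1, x2) ifelse(g$origin == 1L, x1, x2)
  qslot <- originAt(qtnCm, g$start, g$crossovers)
  list(h = pick(parent$h1, parent$h2), o = pick(parent$o1, parent$o2),
       q = if (qslot == 1L) parent$q1 else parent$q2)
}

buildHaplotypePanel <- function(hap, ids, map) {
  m <- nMarkers(map)
  a1 <- t(vapply(ids, function(i) hap[[i]]$h1, character(m)))
  a2 <- t(vapply(ids, function(i) hap[[i]]$h2, character(m)))
  o1 <- t(vapply(ids, function(i) hap[[i]]$o1, character(m)))
  o2 <- t(vapply(ids, function(i) hap[[i]]$o2, character(m)))
  rownames(a1) <- rownames(a2) <- rownames(o1) <- rownames(o2) <- ids
  new("HaplotypePanel", map = map, a1 = a1, a2 = a2, phased = TRUE,
      origin1 = o1, origin2 = o2,
      qtn1 = vapply(ids, function(i) hap[[i]]$q1, logical(1)),
      qtn2 = vapply(ids, function(i) hap[[i]]$q2, logical(1)))
}

checkPedigree <- function(ped) {
  known <- character(0)
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$sire[i], ped$dam[i]))
      if (!is.na(p) && !(p %in% known))
        stop("pedigree loop or unknown parent: ", p)
    known <- c(known, ped$id[i])
  }
  invisible(TRUE)
}

#' Simulate longitudinal growth measurements
#'
#' Per animal, measurements at irregular ages equal to the standard mean
#' curve plus a persistent animal effect, an allele-dose effect on height
#' only, a chest-width deficit (`chestDeficitSd` sigma) for QTN
#' homozygotes, and age-dependent noise `sigma(t)`.
#'
#' @param config a [simConfig()] object.
#' @param standards named list of [GrowthStandard-class] objects; names
#'   are measurement names (must include every entry of `measurements`).
#' @param animals data.frame with columns `id` and `qtnDose`.
#' @param measurements measurement names to simulate.
#' @param nObs observations per animal.
#' @param ageRange sampling range of ages (days); must lie inside every
#'   standard's validity range.
#' @param animalSd SD of the persistent per-animal effect (measurement
#'   units).
#' @param noiseScale multiplier on the `sigma(t)` measurement noise
#'   (0 gives noise-free series on the standard curve).
#' @return long data.frame: `id`, `ageDays`, `measurement`, `value`.
#' @export
simulateGrowthSeries <- function(config, standards, animals,
                                 measurements = names(standards),
                                 nObs = 8L, ageRange = NULL,
                                 animalSd = 1.0, noiseScale = 1.0) {
  validateSimConfig(config)
  stopifnot(all(measurements %in% names(standards)))
  if (is.null(ageRange))
    ageRange <- c(max(vapply(standards[measurements],
                             function(s) s@ageRange[1], numeric(1))),
                  min(vapply(standards[measurements],
                             function(s) s@ageRange[2], numeric(1))))
  for (msr in measurements) {
    rg <- standards[[msr]]@ageRange
    if (ageRange[1] < rg[1] || ageRange[2] > rg[2])
      stop("age range outside validity of standard for ", msr)
  }
  withStream(config$seed, "growth", {
    rows <- vector("list", nrow(animals) * length(measurements))
    k <- 0L
    for (i in seq_len(nrow(animals))) {
      ages <- sort(round(stats::runif(nObs, ageRange[1], ageRange[2])))
      for (msr in measurements) {
        std <- standards[[msr]]
        mu <- growthMean(std, ages)
        sg <- growthSigma(std, ages)
        val <- mu + stats::rnorm(1, 0, animalSd) +
          stats::rnorm(nObs, 0, 1) * sg * noiseScale
        if (msr == "withers_height")
          val <- val + config$qtnHeightEffectCm * animals$qtnDose[i]
        if (msr == "chest_width" && animals$qtnDose[i] == 2L)
          val <- val + config$chestDeficitSd * sg
        k <- k + 1L
        rows[[k]] <- data.frame(id = animals$id[i], ageDays = ages,
                                measurement = msr, value = val)
      }
    }
    do.call(rbind, rows[seq_len(k)])
  })
}
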