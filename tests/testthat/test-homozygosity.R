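# quadratic brute-force ROH oracle: all valid [i, j] not contained in a
# larger valid stretch
bruteRoh <- function(a1, a2, minMarkers, maxMissing) {
  m <- length(a1)
  miss <- is.na(a1) | is.na(a2)
  het <- !miss & a1 != a2
  valid <- function(i, j)
    !any(het[i:j]) && sum(miss[i:j]) <= maxMissing
  segs <- list()
  for (i in 1:m) for (j in i:m)
    if (j - i + 1L >= minMarkers && valid(i, j)) segs <- c(segs, list(c(i, j)))
  maximal <- Filter(function(s) {
    !((s[1] > 1 && valid(s[1] - 1L, s[2])) ||
        (s[2] < m && valid(s[1], s[2] + 1L)))
  }, segs)
  do.call(rbind, maximal)
}

test_that("runs of homozygosity match a quadratic brute force", {
  map <- evenMap(30)
  # fully heterozygous: empty; fully homozygous: one full-span segment
  het <- panelFromHaps(map, list(rep("A", 30)), list(rep("B", 30)),
                       ids = "h", phased = FALSE)
  expect_equal(nrow(detectRoh(het, "h", minMarkers = 5)), 0L)
  hom <- panelFromHaps(map, list(rep("A", 30)), list(rep("A", 30)),
                       ids = "h", phased = FALSE)
  r <- detectRoh(hom, "h", minMarkers = 5)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(1L, 30L))

  set.seed(31)
  for (rep in 1:15) {
    a1 <- sample(c("A", "B", NA), 30, TRUE, prob = c(0.45, 0.45, 0.1))
    a2 <- ifelse(runif(30) < 0.7, a1, sample(c("A", "B"), 30, TRUE))
    pm <- genotypePanel(map, matrix(a1, 1, dimnames = list("x", NULL)),
                        matrix(a2, 1))
    got <- detectRoh(pm, "x", minMarkers = 4L, maxMissing = 1L)
    want <- bruteRoh(pm@a1[1, ], pm@a2[1, ], 4L, 1L)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(unname(as.matrix(got[, c("start", "end")])),
                   unname(want))
    }
  }
})

test_that("the shared-homozygosity score follows its definition", {
  # single case, isolated marker run: score is -log10(fhat^2)
  map <- evenMap(3)
  ctrl1 <- c("A", "A", "A"); ctrl2 <- c("A", "B", "B")
  panel <- genotypePanel(
    map,
    rbind(c1 = c("B", "A", "B"), k1 = ctrl1, k2 = ctrl2),
    rbind(c1 = c("A", "A", "B"), k1 = ctrl1, k2 = ctrl2))
  sc <- suppressWarnings(asshomScan(panel, cases = "c1",
                                    controls = c("k1", "k2"),
                                    nPerm = 100, seed = 1))
  # marker 2: case hom A; run limited to marker 2 (het at 1, and at 3 the
  # case is hom B so the run continues there with allele B!  use direct
  # stat on marker 1 instead: case is het there => score 0
  expect_equal(sc$score[1], 0)
  # hand computation for marker 2: control alleles A,A,B,B so
  # f(A) = (2 + .5) / (4 + 1); the run extends to marker 3 where the case
  # is homozygous B with f(B) = (2 + .5) / (4 + 1)
  w2 <- -2 * log10(2.5 / 5)
  w3 <- -2 * log10(2.5 / 5)
  expect_equal(sc$score[2], w2 + w3)

  # score never increases when a case turns heterozygous inside the run
  a1 <- panel@a1; a1["c1", 3] <- "A"   # was hom B -> now het A/B
  panel2 <- genotypePanel(map, a1, panel@a2)
  sc2 <- suppressWarnings(asshomScan(panel2, "c1", c("k1", "k2"),
                                     nPerm = 100, seed = 1))
  expect_lte(sc2$score[2], sc$score[2])
})

test_that("a planted recessive locus is localized with a small genome-wide p", {
  cfg <- simConfig(seed = 3, nMarkers = 120, chromLengthBp = 6e7,
                   qtnPositionBp = 3e7, nSires = 3, offspringPerSire = 40,
                   damCarrierFreq = 0.35, penetranceHom = 1,
                   misdiagnosisRate = 0)
  st <- seedWithCarrierSires(cfg)$study
  off <- st$truth[grep("-", st$truth$id), ]
  cases <- off$id[off$affected]
  controls <- setdiff(off$id, cases)[1:34]
  expect_gte(length(cases), 5L)
  sc <- asshomScan(st$panel, cases, controls, nPerm = 150, seed = 9)
  peakBp <- markerPos(st$map)[sc$peakMarker]
  expect_lt(abs(peakBp - 3e7), 1e7)
  # the autozygous plateau containing the QTN carries the maximal score
  atQtn <- which.min(abs(markerPos(st$map) - 3e7))
  expect_gte(sc$score[atQtn], 0.95 * sc$maxScore)
  expect_lt(sc$pGenome, 0.02)
})

test_that("autozygosity filtering needs sire carriage and equals the
           unfiltered scan when all sires carry", {
  map <- evenMap(5)
  risk <- rep("A", 5)
  mkHom <- function() list(risk, risk)
  panel <- panelFromHaps(
    map,
    list(risk, risk, risk, risk, c("B","B","B","B","B"), c("A","B","A","B","A")),
    list(risk, risk, risk, c("B","A","B","A","B"), c("B","B","B","B","B"),
         c("B","A","B","A","B")),
    ids = c("c1", "c2", "c3", "sireC", "sireN", "k1"), phased = FALSE)
  ped <- data.frame(id = c("c1", "c2", "c3"),
                    sire = c("sireC", "sireC", "sireN"),
                    dam = NA)
  ctrl <- c("sireC", "sireN", "k1")
  amt <- asshomScan(panel, c("c1", "c2", "c3"), ctrl, nPerm = 100, seed = 2)
  ast <- assistScan(panel, c("c1", "c2", "c3"), ctrl, ped,
                    nPerm = 100, seed = 2)
  # c3's sire demonstrably lacks the A haplotype: c3 contributes nothing
  expect_lt(ast$score[3], amt$score[3])
  expect_equal(ast$score[3] / amt$score[3], 2 / 3, tolerance = 1e-9)
  # when every sire carries the haplotype the two scans agree
  ped2 <- data.frame(id = c("c1", "c2", "c3"), sire = "sireC", dam = NA)
  ast2 <- assistScan(panel, c("c1", "c2", "c3"), ctrl, ped2,
                     nPerm = 100, seed = 2)
  expect_equal(ast2$score, amt$score)
  expect_error(assistScan(panel, c("c1", "zz"), ctrl, ped),
               "pedigree missing")
})

# exhaustive oracle over (anchor, allele) pairs with brute-force interval
# checks
bruteSharedRegion <- function(a1, a2, pos) {
  m <- ncol(a1)
  best <- NULL
  compat <- function(i, j, rows) {
    ok <- TRUE
    for (k in i:j) {
      x1 <- a1[rows, k]; x2 <- a2[rows, k]
      het <- !is.na(x1) & !is.na(x2) & x1 != x2
      if (any(het)) return(FALSE)
      obs <- unique(x1[!is.na(x1)])
      if (length(obs) > 1L) return(FALSE)
    }
    TRUE
  }
  for (j in 1:m) {
    hom <- !is.na(a1[, j]) & !is.na(a2[, j]) & a1[, j] == a2[, j]
    for (a in unique(a1[hom, j])) {
      rows <- which(hom & a1[, j] == a)
      if (length(rows) < 2L) next
      # widest interval around j keeping all rows consistent
      lo <- j; while (lo > 1 && compat(lo - 1L, j, rows)) lo <- lo - 1L
      hi <- j; while (hi < m && compat(j, hi + 1L, rows)) hi <- hi + 1L
      cand <- list(n = length(rows), len = pos[hi] - pos[lo], lo = lo)
      if (is.null(best) || cand$n > best$n ||
          (cand$n == best$n && (cand$len > best$len ||
            (cand$len == best$len && cand$lo < best$lo))))
        best <- cand
    }
  }
  best
}

test_that("the maximal shared homozygous region matches exhaustive search", {
  map <- evenMap(25)
  # all cases identical homozygotes: 100%, full chromosome
  hom <- rep("A", 25)
  pid <- paste0("c", 1:4)
  pAll <- panelFromHaps(map, rep(list(hom), 4), rep(list(hom), 4),
                        ids = pid, phased = FALSE)
  res <- sharedHomozygousRegion(pAll, pid)
  expect_equal(res$fraction, 100)
  expect_equal(res$segment@markerIndex, c(1L, 25L))

  # planted 10-marker shared segment in 5 cases vs exhaustive search
  set.seed(61)
  for (rep in 1:8) {
    a1 <- matrix(sample(c("A", "B"), 5 * 25, TRUE), 5, 25)
    a2 <- matrix(sample(c("A", "B"), 5 * 25, TRUE), 5, 25)
    seg <- sample(c("A", "B"), 10, TRUE)
    for (i in 1:4) { a1[i, 8:17] <- seg; a2[i, 8:17] <- seg }
    rownames(a1) <- rownames(a2) <- paste0("c", 1:5)
    panel <- genotypePanel(map, a1, a2)
    got <- sharedHomozygousRegion(panel, rownames(a1))
    want <- bruteSharedRegion(panel@a1, panel@a2, markerPos(map))
    expect_equal(got$nSharing, want$n)
    expect_equal(intervalLength(got$segment@interval), want$len)
  }
  # carrier count shrinks (weakly) as the interval grows
  expect_error(sharedHomozygousRegion(pAll, "c1"), "at least 2")
})
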