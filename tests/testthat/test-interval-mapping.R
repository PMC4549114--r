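test_that("the Haldane map function matches its closed form", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(0.1), 0.5 * (1 - exp(-0.2)))
  expect_lte(haldane(50), 0.5)
  expect_gt(haldane(50), 0.49999)
  expect_error(haldane(-0.01), "negative")
})

# exhaustive-enumeration oracle for the two-flank transmission formula:
# chain L -- x -- R, transition probs r via Haldane, both origins
# equally likely at L.
enumTransmission <- function(oL, oR, dLcm, dRcm) {
  rL <- haldane(dLcm / 100); rR <- haldane(dRcm / 100)
  joint <- function(ox) {
    pTrans1 <- if (ox == oL) 1 - rL else rL
    pTrans2 <- if (oR == ox) 1 - rR else rR
    0.5 * pTrans1 * pTrans2
  }
  joint(1) / (joint(1) + joint(2))
}

test_that("transmission probabilities agree with exhaustive enumeration", {
  # family with two fully informative markers; dam contributes "C"
  mkFam <- function(offA1, spanCm = 20) {
    map <- markerMap("8", c(1e6, 1e6 + spanCm * 1e6),
                     cm = c(0, spanCm))
    a1 <- do.call(rbind, offA1)
    a2 <- matrix("C", nrow(a1), 2)
    rownames(a1) <- rownames(a2) <- paste0("O", seq_len(nrow(a1)))
    sireFamily("s", c("A", "A"), c("B", "B"),
               genotypePanel(map, a1, a2), rep(0, nrow(a1)))
  }
  origins <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  allele <- c("A", "B")
  for (o in origins) {
    fam <- mkFam(list(allele[o]))
    for (x in c(3, 10, 17.5)) {
      got <- transmissionProb(fam, x)
      expect_equal(got, enumTransmission(o[1], o[2], x, 20 - x),
                   tolerance = 1e-12,
                   label = sprintf("o=(%d,%d) x=%g", o[1], o[2], x))
    }
  }
  # at an informative marker the probability is 0/1
  fam <- mkFam(list(c("A", "B"))) # hap1 left, hap2 right
  expect_equal(transmissionProb(fam, 0), 1)
  expect_equal(transmissionProb(fam, 20), 0)
  # disagreeing flanks, equidistant: symmetry gives 1/2
  expect_equal(transmissionProb(fam, 10), 0.5)
})

test_that("ambiguous and missing markers are treated as uninformative", {
  map <- evenMap(3)
  # sire het A/B; offspring het A/B at marker 2 (dam unknown): ambiguous
  a1 <- matrix(c("A", "A", "A"), 1); a2 <- matrix(c("C", "B", "C"), 1)
  rownames(a1) <- rownames(a2) <- "O1"
  fam <- sireFamily("s", rep("A", 3), rep("B", 3),
                    genotypePanel(map, a1, a2), 0)
  org <- paternalOrigin(fam)
  expect_identical(unname(org[1, 2]), NA_integer_)
  expect_identical(unname(org[1, 1]), 1L)
  # no informative flank anywhere: p = 0.5
  a1b <- matrix(rep("A", 3), 1); a2b <- matrix(rep("B", 3), 1)
  rownames(a1b) <- rownames(a2b) <- "O1"
  famb <- sireFamily("s", rep("A", 3), rep("B", 3),
                     genotypePanel(map, a1b, a2b), 0)
  expect_equal(unname(transmissionProb(famb, 2)), 0.5)
})

test_that("sire phase is recovered from offspring co-inheritance", {
  # two tightly linked markers, 10 non-recombinant offspring carrying
  # either A-A or B-B: phase must pair A with A
  map <- evenMap(2, spacingCm = 0.1)
  pat <- lapply(1:10, function(i) if (i %% 2) c("A", "A") else c("B", "B"))
  off <- panelFromHaps(map, pat,
                       replicate(10, c("C", "C"), simplify = FALSE),
                       phased = FALSE)
  ph <- inferSirePhase(c("A", "B"), c("B", "A"), off)
  expect_true(identical(ph$hap1, c("A", "A")) ||
                identical(ph$hap1, c("B", "B")))
  expect_equal(ph$linkConfidence, 1)

  # simulated family with recorded truth: dense map, 30 offspring
  m <- 40
  map2 <- evenMap(m, spacingCm = 1)
  set.seed(13)
  sh1 <- sample(c("A", "B"), m, TRUE)
  sh2 <- sample(c("A", "B"), m, TRUE)
  fam <- informativeFamily(30, map2, sh1, sh2, seed = 14)
  ph2 <- inferSirePhase(pmin(sh1, sh2), pmax(sh1, sh2), fam@offspring)
  het <- sh1 != sh2
  match1 <- identical(ph2$hap1[het], sh1[het])
  match2 <- identical(ph2$hap1[het], sh2[het])
  expect_true(match1 || match2)   # equal up to global haplotype swap
  # single heterozygous marker: deterministic but flagged low-confidence
  off1 <- panelFromHaps(evenMap(1), list("A"), list("C"), phased = FALSE)
  ph3 <- inferSirePhase("A", "B", off1)
  expect_true(ph3$lowConfidence)
  expect_error(inferSirePhase("A", "A", off1),
               "uninformative")
})

test_that("the F profile behaves at the null and at planted QTL", {
  # constant p = 0.5 (sire homozygous): F = 0 everywhere
  map <- evenMap(10)
  off <- panelFromHaps(map,
                       replicate(20, rep("A", 10), simplify = FALSE),
                       replicate(20, rep("B", 10), simplify = FALSE),
                       phased = FALSE)
  set.seed(3)
  fam0 <- sireFamily("s", rep("A", 10), rep("A", 10), off, rnorm(20))
  sc0 <- scanFamily(fam0)
  expect_true(all(sc0@profile$F == 0))

  # null family: median F near the F(1, df) median
  pl <- plantedQtlFamily(200, m = 40, effect = 0, seed = 21)
  scN <- scanFamily(pl$family)
  expect_gt(median(scN@profile$F), 0.1)
  expect_lt(median(scN@profile$F), 1.2)

  # planted QTN, effect 2 SD, 200 offspring: argmax within 5 cM in
  # >= 90% of replicates
  hits <- vapply(1:20, function(r) {
    pl <- plantedQtlFamily(200, m = 40, effect = 2, sd = 1, seed = 100 + r)
    sc <- scanFamily(pl$family)
    abs(sc@peakCm - pl$qtlCm) <= 5
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # single-regressor identity: F equals t^2 of the effect
  pl2 <- plantedQtlFamily(60, m = 20, effect = 1, seed = 5)
  sc2 <- scanFamily(pl2$family)
  x <- transmissionProb(pl2$family, sc2@peakCm)
  fit <- summary(lm(pl2$family@phenotype ~ x))
  expect_equal(sc2@peakF, fit$coefficients["x", "t value"]^2,
               tolerance = 1e-8)
  expect_equal(sc2@effect, fit$coefficients["x", "Estimate"],
               tolerance = 1e-8)
})

test_that("covariates are honored and degenerate designs rejected", {
  pl <- plantedQtlFamily(80, m = 20, effect = 1.5, seed = 33)
  fam <- pl$family
  set.seed(34)
  age <- rnorm(80, 900, 30)
  fam@phenotype <- fam@phenotype + 0.1 * (age - 900)
  fam@covariates <- data.frame(age = age)
  sc <- scanFamily(fam)
  expect_lte(abs(sc@peakCm - pl$qtlCm), 6)
  fam@covariates <- data.frame(age = age, age2 = age)
  expect_error(scanFamily(fam), "rank-deficient")
  fam@covariates <- data.frame(age = age[1:80])
  fam@phenotype[] <- NA
  expect_error(scanFamily(fam), "10 phenotyped")
})

test_that("permutation thresholds are reproducible, ordered and honest", {
  pl <- plantedQtlFamily(60, m = 20, effect = 0, seed = 44)
  thr1 <- permutationThreshold(pl$family, nPerm = 200, seed = 7,
                               alphaLevels = c(0.05, 0.01))
  thr2 <- permutationThreshold(pl$family, nPerm = 200, seed = 7,
                               alphaLevels = c(0.05, 0.01))
  expect_identical(thr1, thr2)
  expect_gte(thr1[["1%"]], thr1[["5%"]])
  thr3 <- permutationThreshold(pl$family, nPerm = 1000, seed = 7)
  expect_gte(thr3[["0.1%"]], thr3[["1%"]])
  expect_gte(thr3[["1%"]], thr3[["5%"]])
  expect_error(permutationThreshold(pl$family, nPerm = 50), "100")
  expect_error(permutationThreshold(pl$family, nPerm = 150,
                                    alphaLevels = 0.001),
               "cannot resolve")
})

test_that("bootstrap CIs are seeded, degenerate at nBoot = 1, and flagged", {
  pl <- plantedQtlFamily(80, m = 20, effect = 2, seed = 55)
  ci1 <- bootstrapCi(pl$family, nBoot = 150, seed = 9)
  ci2 <- bootstrapCi(pl$family, nBoot = 150, seed = 9)
  expect_equal(ci1@start, ci2@start)
  expect_equal(ci1@end, ci2@end)
  ci3 <- bootstrapCi(pl$family, nBoot = 1, seed = 9)
  expect_equal(intervalLength(ci3), 0)
  # null family with a high threshold: flagged unreliable, still returned
  pl0 <- plantedQtlFamily(60, m = 20, effect = 0, seed = 56)
  ci4 <- bootstrapCi(pl0$family, nBoot = 100, seed = 2, threshold5 = 1e6)
  expect_false(attr(ci4, "reliable"))
  expect_s4_class(ci4, "GenomicInterval")
})
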