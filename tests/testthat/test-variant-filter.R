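test_that("the segregation filter implements the three-way pattern", {
  het <- paste0("H", 1:3); homA <- paste0("A", 1:3); homB <- "B1"
  gts <- function(...) {
    g <- matrix(c(...), 1)
    colnames(g) <- c(het, homA, homB)
    g
  }
  # the defining pattern: het x3 = A/G, homA x3 = A/A, homB = G/G
  r <- segregationFilter(gts("A/G","A/G","A/G","A/A","A/A","A/A","G/G"),
                         "A", "G", het, homA, homB)
  expect_true(r$pass)
  # hom groups sharing the same allele fail rule (3)
  r2 <- segregationFilter(gts("A/G","A/G","A/G","A/A","A/A","A/A","A/A"),
                          "A", "G", het, homA, homB)
  expect_false(r2$pass)
  expect_match(r2$reason, "same allele")
  # a missing genotype fails the record
  r3 <- segregationFilter(gts("A/G","A/G",NA,"A/A","A/A","A/A","G/G"),
                          "A", "G", het, homA, homB)
  expect_false(r3$pass)
  expect_identical(r3$reason, "missing genotype")
  # permutation invariance within groups
  r4 <- segregationFilter(gts("A/G","A/G","A/G","A/A","A/A","A/A","G/G"),
                          "A", "G", rev(het), homA[c(2, 3, 1)], homB)
  expect_true(r4$pass)
})

test_that("all 3^7 genotype assignments agree with an independent predicate", {
  het <- paste0("H", 1:3); homA <- paste0("A", 1:3); homB <- "B1"
  gset <- c("A/A", "A/G", "G/G")
  combos <- expand.grid(rep(list(gset), 7), stringsAsFactors = FALSE)
  geno <- as.matrix(combos)
  colnames(geno) <- c(het, homA, homB)
  got <- segregationFilter(geno, rep("A", nrow(geno)),
                           rep("G", nrow(geno)), het, homA, homB)$pass
  # independent predicate written in terms of genotype strings
  want <- apply(geno, 1, function(g) {
    all(g[het] == "A/G") &&
      length(unique(g[homA])) == 1 && g[homA][1] %in% c("A/A", "G/G") &&
      length(unique(g[homB])) == 1 && g[homB][1] %in% c("A/A", "G/G") &&
      g[homA][1] != g[homB][1]
  })
  expect_identical(got, unname(want))
  expect_equal(sum(got), 2L)   # A/A vs G/G and G/G vs A/A
})

test_that("coverage gaps bracket sub-threshold stretches half-open", {
  model <- geneModel("g1", "8", "+",
                     data.frame(start = c(90, 200), end = c(130, 230)))
  depth <- expand.grid(animal = c("x", "y"), pos = c(90:130, 200:230))
  depth$depth <- 10
  gaps <- coverageGaps(depth, model)
  expect_length(gaps$x, 0L)
  # one animal dips to 3 reads over bases 100-110
  depth$depth[depth$animal == "y" & depth$pos %in% 100:110] <- 3
  gaps2 <- coverageGaps(depth, model)
  expect_length(gaps2$y, 1L)
  expect_equal(gaps2$y[[1]]@start, 100)
  expect_equal(gaps2$y[[1]]@end, 111)
  expect_length(gaps2$x, 0L)
  # random tracks against a per-base brute force
  set.seed(9)
  for (r in 1:5) {
    d <- depth
    d$depth <- sample(0:8, nrow(d), TRUE)
    g <- coverageGaps(d, model, minDepth = 4)
    for (an in c("x", "y")) {
      lowPos <- sort(d$pos[d$animal == an & d$depth < 4])
      covered <- sort(unlist(lapply(g[[an]], function(iv)
        iv@start:(iv@end - 1))))
      expect_equal(covered, lowPos)
    }
  }
  # region outside the table errors
  model2 <- geneModel("g2", "8", "+", data.frame(start = 50, end = 60))
  expect_error(coverageGaps(depth, model2), "outside depth table")
})

test_that("coding annotation distinguishes start-loss and codon changes", {
  # synthetic CDS: ATG + 180 codons; codon 171 is CAC (His)
  set.seed(4)
  codons <- c("ATG", replicate(180, paste(sample(c("GCT", "GAA", "TTA",
                                                   "CCA", "TCA"), 1))))
  codons[171] <- "CAC"
  cdsSeq <- paste(codons, collapse = "")
  offset <- 1000L
  genome <- paste0(strrep("N", offset), cdsSeq)
  model <- geneModel("fgd", "8", "+",
                     data.frame(start = offset + 1,
                                end = offset + nchar(cdsSeq)))
  # codon 1 ATG -> ACG: start-loss
  a <- annotateCoding(model, genome, offset + 2, "T", "C")
  expect_identical(a$annotation, "start-loss")
  # CAC -> TGC applied jointly: His-171-Cys
  p171 <- offset + (171 - 1) * 3 + 1
  b <- annotateCoding(model, genome, p171, "C", "T",
                      jointWith = data.frame(pos = p171 + 1, ref = "A",
                                             alt = "G"))
  expect_identical(b$annotation, "non-synonymous")
  expect_identical(b$label, "His-171-Cys")
  # CAC -> CAT: synonymous His
  cc <- annotateCoding(model, genome, p171 + 2, "C", "T")
  expect_identical(cc$annotation, "synonymous")
  expect_match(cc$label, "^His-171-His$")
  # outside the CDS and indels
  expect_identical(annotateCoding(model, genome, 10, "N", "A")$annotation,
                   "none")
  expect_identical(annotateCoding(model, genome, p171, "CA", "C")$annotation,
                   "indel-unclassified")
})

test_that("reverse-strand annotation equals forward annotation of the
           reverse complement", {
  cdsSeq <- "ATGCACGGATTACGT"           # 5 codons on the minus strand
  rcSeq <- paste(rev(strsplit(chartr("ACGT", "TGCA", cdsSeq), "")[[1]]),
                 collapse = "")
  genomeMinus <- paste0(strrep("N", 50), rcSeq, strrep("N", 10))
  modelMinus <- geneModel("m", "8", "-",
                          data.frame(start = 51, end = 50 + nchar(cdsSeq)))
  genomePlus <- paste0(strrep("N", 50), cdsSeq)
  modelPlus <- geneModel("p", "8", "+",
                         data.frame(start = 51, end = 50 + nchar(cdsSeq)))
  # mutate CDS base 5 (A in CAC codon 2) on both representations
  plus <- annotateCoding(modelPlus, genomePlus, 55, "A", "G")
  # on the minus strand CDS base 5 is genomic position end - 4, with
  # complemented alleles
  minusPos <- 50 + nchar(cdsSeq) - 4
  minus <- annotateCoding(modelMinus, genomeMinus, minusPos, "T", "C")
  expect_identical(minus$annotation, plus$annotation)
  expect_identical(minus$label, plus$label)
  expect_identical(minus$refCodon, plus$refCodon)
})

test_that("LD r2 matches closed-form haplotype counts and the EM agrees", {
  # identical loci are in complete LD
  h <- rep(c("A", "B"), each = 10)
  expect_equal(ldR2(h, h), 1)
  # 20 phased haplotypes, hand-computed D
  hapA <- c(rep("A", 12), rep("a", 8))
  hapB <- c(rep("B", 9), rep("b", 3), rep("B", 2), rep("b", 6))
  pA <- 12 / 20; pB <- 11 / 20; pAB <- 9 / 20
  D <- pAB - pA * pB
  expect_equal(ldR2(hapA, hapB),
               D^2 / (pA * (1 - pA) * pB * (1 - pB)), tolerance = 1e-12)
  # EM on phase-unambiguous genotypes equals the phased value
  gA <- paste(hapA[seq(1, 19, 2)], hapA[seq(2, 20, 2)], sep = "/")
  gB <- paste(hapB[seq(1, 19, 2)], hapB[seq(2, 20, 2)], sep = "/")
  dh <- sum(vapply(strsplit(gA, "/"), function(x) x[1] != x[2], TRUE) &
              vapply(strsplit(gB, "/"), function(x) x[1] != x[2], TRUE))
  if (dh == 0)
    expect_equal(ldR2(gA, gB, phased = FALSE), ldR2(hapA, hapB),
                 tolerance = 1e-6)
  # independent loci in a large sample: r2 near 0
  set.seed(22)
  x <- sample(c("A", "a"), 4000, TRUE)
  y <- sample(c("B", "b"), 4000, TRUE)
  expect_lt(ldR2(x, y), 0.01)
  expect_error(ldR2(rep("A", 10), h), "monomorphic")
})
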