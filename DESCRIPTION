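Package: PositionalQTL
Title: Positional Cloning of Livestock QTL from Half-Sib Families to Candidate
    Variant
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the positional-cloning workflow used to fine-map
    quantitative trait loci segregating in paternal half-sib livestock
    pedigrees together with a linked recessive disorder: within-family
    linear-regression interval mapping with permutation thresholds and
    bootstrap confidence intervals, identical-by-descent haplotype
    refinement with recombination-breakpoint localization,
    kinship-adjusted (EMMAX-style) single-marker and sliding-window
    haplotype association, runs-of-homozygosity and autozygosity mapping
    of recessive traits, segregation-based candidate-variant filtering
    with coding-effect annotation, and growth-standard deviation
    classification of skeletal dysproportion. A pedigree gamete simulator
    with a planted pleiotropic quantitative trait nucleotide generates
    fully specified study data so every stage can be exercised and
    calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml,
    minpack.lm,
    seqinr,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
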