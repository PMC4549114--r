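# PositionalQTL

Positional cloning of a livestock QTL, end to end: from paternal half-sib
linkage mapping to a candidate causal variant.

Large-effect QTL segregating in closed livestock populations are mapped in
stages: within-family linear-regression interval mapping detects the locus
in half-sib families; identical-by-descent (IBD) haplotype sharing among
related carrier sires narrows the interval; kinship-adjusted association
on dense (imputed) genotypes and a sliding-window risk-haplotype scan
refine it further; when a linked recessive disorder exists, homozygosity
and autozygosity mapping of affected animals pin the risk haplotype; and a
segregation filter over targeted resequencing calls reduces the candidate
list to sites whose genotypes co-segregate perfectly with the locus.
`PositionalQTL` implements every one of those stages as composable R
functions with S4 data containers, together with a pedigree gamete
simulator that plants a pleiotropic quantitative trait nucleotide (QTN) so
the whole pipeline can be exercised, calibrated and tested without any
external data.

The statistical core:

* **Half-sib interval mapping** — at each grid position `x` the model
  `y = Xβ + α·p(x) + e` is fitted by least squares, where `p(x)` is the
  probability the offspring inherited sire haplotype 1, computed from the
  nearest informative flanking markers under the Haldane map
  `r = ½(1 − e^(−2d))`.  `F = (RSS₀ − RSS₁)/(RSS₁/(n − k − 1))`;
  chromosome-wise thresholds come from phenotype permutations and the 95%
  CI of the QTL position from an offspring bootstrap.
* **Mixed-model association** — `y = Xβ + u + e`, `u ~ N(0, σ_g²K)` with
  an identity-by-state kinship `K`; variance components are estimated
  once by REML on the null model (spectral decomposition of `K`,
  one-dimensional search in log δ, δ = σ_e²/σ_g²) and reused for every
  marker's generalized-least-squares test — the EMMAX approximation.
* **Homozygosity mapping** — a frequency-weighted shared-homozygosity
  score: each case homozygous for the common allele at a marker
  contributes `−log₁₀(f̂²)` summed over its maximal homozygous run, with
  a genome-wide p-value from case/control label permutations.
* **Growth-deviation classification** — Gompertz growth standards
  `A·exp(−b·exp(−kt))` with age-binned σ(t); deviations in σ units feed
  the poor-development (A), narrow-chest (B) and wide-thurl (C) flags.

## Worked example

```r
library(PositionalQTL)

cfg <- simConfig(seed = 17, nMarkers = 180, chromLengthBp = 9e7,
                 qtnPositionBp = 4.5e7, qtnEffectKg = 45,
                 polygenicVar = 100, residualVar = 400,
                 nSires = 3, offspringPerSire = 80,
                 damCarrierFreq = 0.3, penetranceHom = 1)
st  <- simulateStudy(cfg)
fam <- familyFromStudy(st, "S1")
sc  <- scanFamily(fam)
sc
#> QtlScan: peak F = 36.68 at 44.4 cM (44.41 Mb), effect = 40.63, %var = 32.3

seg <- sharedHaplotype(st$panel, c("S1", "S2", "S3"), cfg$qtnPositionBp)
refineInterval(list(bootstrapCi(fam, nBoot = 200, seed = 11)), seg)
#> GenomicInterval 8:[40,414,495, 45,814,495) (5.400 Mb)
```

The scan peaks at 44.4 Mb with an allele-substitution estimate of about
41 kg — the planted QTN sits at 45.0 Mb with a true effect of 45 kg — and
explains ~32% of the within-family variance.  Intersecting the bootstrap
confidence interval with the haplotype the three carrier sires share IBD
narrows the candidate region to 5.4 Mb around the planted site.  The
vignette walks the remaining stages (association, conditioning,
homozygosity mapping, the variant funnel and the skeletal-deviation
classifier) on the same simulated study.

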