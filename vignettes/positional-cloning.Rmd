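---
title: "Positional cloning of a half-sib QTL: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional cloning of a half-sib QTL: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PositionalQTL)
```

This vignette is the package's account of the science it implements: the
models behind each mapping stage, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate,
the numerical choices, and the design decisions taken where the
methodology left the design open.

## The mapping problem

A quantitative trait locus (QTL) with a large additive effect segregates
in paternal half-sib families of a closed cattle population; the same
risk haplotype, when homozygous, expresses a recessive skeletal
disorder.  No single data set resolves the locus: the pipeline chains
within-family linkage, pedigree IBD logic, population-level association,
case homozygosity and finally variant-level segregation.  Every stage is
implemented here against one shared set of S4 containers (`MarkerMap`,
`GenotypePanel`/`HaplotypePanel`, `GenomicInterval`, `SireFamily`), with
all interval logic on a single convention: 1-based bp marker positions,
half-open `[start, end)` intervals.

## Half-sib interval mapping

For a sire heterozygous at the QTL, offspring inheriting haplotype 1
differ in expectation from those inheriting haplotype 2.  At each grid
position (1 cM step by default) the regressor is the transmission
probability `p(x) = P(paternal origin = haplotype 1)`, computed from the
two *nearest informative* flanking markers with Haldane recombination
fractions — full multipoint reconstruction is left out deliberately; at
the simulated marker densities (50k-like and denser) two informative
flanks carry almost all the information.  A marker is uninformative for
an offspring when the sire is homozygous, the call is missing, or sire
and offspring are heterozygous for the same alleles (with ungenotyped
dams the paternal allele is then ambiguous).  Offspring with no
informative flank are retained at `p = 0.5`, where they simply do not
contribute to the contrast.

The test statistic is the 1-df F comparing the covariate-only fit with
the fit including `p(x)`; the effect `α` is the haplotype-1 minus
haplotype-2 contrast, i.e. the allele substitution effect when exactly
one haplotype carries the risk allele.  Per cent variance explained is
reported as `100(RSS₀ − RSS₁)/RSS₀` at the peak — one of several
formulas in circulation, so outputs are labelled with the formula used.

* **Permutation thresholds** shuffle phenotype rows *with their
  covariates attached* (preserving their joint distribution) against the
  genotypes; the chromosome-wise threshold at level `a` is the `1 − a`
  quantile of the max-F null sample.  Ties at the maximum are broken at
  the leftmost grid position.
* **Bootstrap confidence intervals** resample offspring and take the
  2.5–97.5 percentile range of peak positions.  A known limitation,
  reproduced by our own calibration: on short maps with strong effects
  the bootstrap peaks pile up on the observed peak and the percentile
  interval undercovers.  On a 40 cM map with a 0.75 SD effect the
  empirical coverage in the test suite is at nominal level; CIs from
  scans whose peak F falls below the 5% threshold are flagged
  unreliable rather than suppressed.

## IBD refinement

Carrier sires descending from one founder share the risk haplotype
identical by descent.  `sharedHaplotype()` finds the maximal interval
around an anchor where one haplotype per sire agrees with a common
allele sequence — a purely combinatorial extension (no LD model, no
HMM), with missing genotypes as wildcards because sparse microsatellite
panels are the realistic input.  Two bounds are reported: the inner
bound at the outermost agreeing markers and the conservative outer bound
at the flanking markers; downstream logic uses the outer bound.
`locateBreakpoint()` brackets a recombination between the last marker
distinctive for one flanking haplotype and the first distinctive for the
other.  `refineInterval()` is interval algebra: intersect the family
CIs with the shared segment, subtract regions excluded by recombinants
whose phenotype contradicts carriage; if a subtraction splits the
region, the longer piece is kept (the pathological middle-exclusion case
does not arise in practice and is documented rather than guessed at).

## Kinship-adjusted association

Population-level association uses `y = Xβ + u + e` with
`u ~ N(0, σ_g²K)` and the identity-by-state kinship
`K_ij = mean(0, ½, 1 sharing score)`.  IBS matrices are not guaranteed
positive semi-definite, so a ridge of 1e-6 is added before the spectral
decomposition.  Restricted maximum likelihood is maximized in
`log δ ∈ [−10, 10]`, `δ = σ_e²/σ_g²`; hitting the upper boundary is
flagged "no genetic variance", and a scaled-identity `K` (under which
only `σ_g²(1+δ)` is identified) is flagged "unidentifiable".  Variance
components are estimated once on the null model and reused for every
marker — the EMMAX approximation, which trades exactness per marker for
a single decomposition.  Tests are 1-df F with listwise deletion of
missing dosages (the reference implementations do not document their
missing-data rule; listwise deletion is the conservative choice).
Conditional analysis appends a dosage to the fixed effects; with the
causal dosage conditioned, the regional signal should collapse — the
test suite re-enacts exactly that.  P-values are reported raw: the
original analyses applied no multiple-testing correction to these scans
and none is imposed here.

The sliding-window risk-haplotype scan is parameterized in SNP counts
(20-SNP windows, 10-SNP slide on the thinned panel — about 1 Mb and
0.5 Mb at 50-kb spacing) rather than bp, because that is how the
procedure is operationalized in the field.  A haplotype is labelled
"risk" in a window iff it matches the reference at every non-missing
thinned SNP; windows with more than half the reference missing are
dropped with a message.

## Homozygosity and autozygosity mapping

The published analyses delegated the statistic to external programs
without equations, so the score here is this package's own
operationalization, documented as such: at each marker the cases
homozygous for the common (modal) allele each contribute
`−log₁₀(f̂²)` — the rarity of that homozygosity under control allele
frequencies, with a 0.5 pseudocount so `log 0` never occurs — summed
over the case's maximal homozygous run through the marker (missing calls
are wildcards that contribute no weight).  Long autozygous runs shared
by many cases therefore dominate.  An earlier formulation that
multiplied a single group-wide run by the case count rewarded small
case subsets with very long runs and mislocalized on simulated data; the
per-case-run form replaced it before any acceptance quantity was frozen.
The genome-wide p-value is a case/control label permutation test with
the `(1 + count)/(1 + n_perm)` estimator so p is never zero.  The
autozygosity variant additionally requires each case's shared allele to
be carried by its genotyped sire (ungenotyped ancestors leave the case
unconstrained), which suppresses contributions from phenocopies whose
sires demonstrably lack the haplotype.  No claim of numerical
equivalence with any external program is made — the equivalence is at
the level of localization behaviour, which the simulation suite checks.

`sharedHomozygousRegion()` maximizes the number of cases homozygous for
one haplotype over all anchor/allele pairs (ties: longest interval, then
leftmost) and reports the interval between the outermost agreeing
markers half-open at the last marker position, so its length is the bp
distance the field would print.  Runs of homozygosity allow a configured
number of missing calls (default 1 per segment, minimum 20 markers,
roughly 1 Mb at 50k density); with a missing-call budget, maximal valid
segments can overlap, and all are reported.

## The variant funnel

Targeted resequencing of three carrier sires, three non-risk homozygous
sires and one risk-homozygous animal yields candidate variants that are
filtered by the three-way segregation pattern: heterozygous in all
carriers, homozygous in both reference groups, with opposite alleles.
Missing genotypes fail a record (with the reason logged) rather than
passing it vaguely; indel genotypes pass through the same predicate.
Coverage gaps — CDS stretches where any animal has fewer than four
reads — are emitted as half-open intervals for follow-up sequencing.
Coding annotation translates the affected codon before and after
substitution honoring strand; a joint mode applies two substitutions in
the same codon together, which matters when two SNPs in complete LD
change one codon (the His→Cys case the funnel is designed to find).
Loss of ATG at codon 1 is classified start-loss.  LD `r²` comes from
phased haplotype counts, or from the standard two-locus EM
(log-likelihood change < 1e-10) for unphased genotypes.

## Growth standards and the A/B/C classifier

Normal growth curves are Gompertz, `A·exp(−b·exp(−kt))`, fitted by
Levenberg–Marquardt least squares, with `σ(t)` the residual SD in age
bins of at least 20 animals, linearly interpolated.  The Gompertz form
is fixed by convention of the breed registry curves the standards
emulate; the registry's own parameter values are not published, so
standards are always fitted or supplied, never hard-coded.  Deviations
are `(value − mean(age))/σ(age)` with the sex/age selection rule: steers
under 10 months are scored against the sire standard, older steers
against the steer standard, females against the female standard.

Classification flags: **A** (poor development) requires at least two
deviations below −2σ — "below −2σ" reads the deficit convention, since
flagged records are negative — or an external poor-development
diagnosis on record.  The external-diagnosis route is deliberately not
conditioned on a printed sub-−2σ deviation: the documented exceptional
animal qualifies through a measurement outside the four tabulated
columns, so requiring one *within* the table would contradict the
published classification.  **B** (disproportionately narrow chest)
requires chest depth − chest width > 1σ; **C** (wide thurl) requires
thurl width − pin-bone width > 1σ; the directions come from the flag
definitions, and a pair with a missing member is reported unevaluable
instead of silently unflagged.  Animals observed repeatedly are
collapsed by flag union before counting, because cohorts are summarized
per animal, not per observation.  B/C counts are reported among non-A
animals.  Longitudinal series are interpolated by natural cubic spline
on a 4-week grid from 270 days, with no extrapolation; group contrasts
are equal-variance t-tests per timepoint, one-way ANOVA with pairwise
t-tests, or `y ~ age + dosage` regression reporting the dosage
coefficient as the allele-substitution effect and
`100·SS_dosage/SS_total` (sequential, age first) as labelled per cent
variance.

## The synthetic-data generator

`simulateStudy()` is a first-class module, not a test fixture.  It
emulates: a founder sire carrying exactly one QTN haplotype; half-sib
families of his sons; meiosis under Haldane's model (Poisson crossover
count in map length, uniform positions in genetic distance, no
interference) at a constant 1 cM/Mb; dams as unrelated draws from
Beta(2, 2) founder allele frequencies — dams are never genotyped in the
real designs, and no value for their allele spectrum is published, so
this default is asserted, not inferred; carcass weight as baseline +
fixed effects + slaughter-age slope + additive QTN effect × dosage +
pedigree-propagated polygenic value + residual; height responding to
dosage while chest width does not; and recessive disease labels with
configurable penetrance and misdiagnosis rate (the discordant-diagnosis
phenomenon in field data).  `damCarrierFreq` lets dams carry an IBD copy
of the founder risk haplotype, which is what produces affected
homozygotes and a shared homozygous region for the recessive stages.
Default effect sizes mirror the studied trait: +33.9 kg per allele
against a 65.3 kg phenotypic SD.

Reproducibility contract: identical config (including seed) gives
bit-identical outputs, and each generated table draws from its own RNG
stream (`seed` + a fixed per-table offset), so adding one table never
perturbs another.  What the generator does *not* emulate — and what
passing tests therefore do not establish about real data — includes
genotyping error beyond missingness, LD structure in the founder
population (founder alleles are drawn independently per marker),
selection, assortative mating, X-linked loci and imputation error;
phased synthetic panels stand in for imputed data, so only
imputation-concordance *evaluation* is exercised, never imputation
itself.

## Numerical choices and problem sizes

Tolerances and tie-breaks, stated once: Haldane distances in Morgans;
scan ties leftmost; REML search bracket `log δ ∈ [−10, 10]` with
`optimize()` at 1e-6; GLS collinearity cut at residual sum of squares
1e-10 and monomorphism at dosage variance 1e-12; EM for `r²` to
log-likelihood change 1e-10; allele order in unphased genotypes
normalized lexicographically so genotype equality is well defined;
permutation p-values with the +1 correction.  The test suite's
simulation sizes are chosen to make each property measurable with
stable margins while keeping the default run on one core in a few
minutes: 400 null replicates × 200 permutations for type-I error
calibration, 40 replicates × 300 bootstraps for CI coverage, 200
cohorts of 171 steers for effect recovery, and a 3-family × 80-offspring
study with 180 markers on a 90 Mb chromosome for the end-to-end
re-enactment.

## Walking the pipeline

```{r pipeline, eval = FALSE}
cfg <- simConfig(seed = 17, nMarkers = 180, chromLengthBp = 9e7,
                 qtnPositionBp = 4.5e7, qtnEffectKg = 45,
                 polygenicVar = 100, residualVar = 400,
                 nSires = 3, offspringPerSire = 80,
                 damCarrierFreq = 0.3, penetranceHom = 1)
st <- simulateStudy(cfg)

## 1. within-family linkage
fams <- lapply(paste0("S", 1:3), function(s) familyFromStudy(st, s))
scans <- lapply(fams, scanFamily)
cis <- lapply(fams, bootstrapCi, nBoot = 200, seed = 11)

## 2. IBD refinement across the carrier sires
seg <- sharedHaplotype(st$panel, c("S1", "S2", "S3"), cfg$qtnPositionBp)
refined <- refineInterval(cis, seg)

## 3. kinship-adjusted association and conditioning
off <- grep("-", individualIds(st$panel), value = TRUE)
dos <- (alleles1(st$panel)[off, ] == "B") +
       (alleles2(st$panel)[off, ] == "B")
idx <- match(off, st$phenotypes$id)
y <- st$phenotypes$carcassWeight[idx]
X <- cbind(1, age = st$phenotypes$ageDays[idx])
offPanel <- genotypePanel(st$map, alleles1(st$panel)[off, ],
                          alleles2(st$panel)[off, ], phased = TRUE)
K <- ibsKinship(offPanel)
vc <- remlNull(y, X, K)
assoc <- glsScan(dos, y, X, K, vc)
condAssoc <- glsScan(dos, y, X, K, vc,
                     conditionOn = qtnDosage(st$panel)[off])

## 4. risk-haplotype windows
wins <- qHaplotypeWindows(offPanel, alleles1(st$panel)["X", ],
                          seq_len(nMarkers(st$map)))
winAssoc <- glsScan(wins, y, X, K, vc)

## 5. recessive-disease mapping
cases <- st$truth$id[st$truth$affected]
controls <- setdiff(off, cases)[1:34]
hz <- asshomScan(st$panel, cases, controls, nPerm = 1000, seed = 5)
shared <- sharedHomozygousRegion(st$panel, cases)
```

## Known limitations

Single-QTL model only — no composite interval mapping, no multi-locus
variance components.  The transmission regressor uses two flanking
markers, not full multipoint.  Percentile-bootstrap position CIs
undercover when the peak is pinned near a map edge by a strong effect.
The homozygosity score is an operationalization, comparable across
markers within one data set but not across programs.  The growth
standards assume Gompertz means with additive Gaussian noise; traits
with age-dependent skew would need a transformed scale.  All of these
are properties of the methods as defined, not implementation accidents,
and the test suite asserts behaviour within these boundaries.
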