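---
title: "Star-allele calling, Activity Scores and platform error models"
author: "PGxStar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele calling, Activity Scores and platform error models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PGxStar)
```

## The problem

CYP2D6 and CYP2C19 metabolise a large share of commonly prescribed drugs,
and both genes are highly polymorphic. Genotypes are summarised as *star
alleles* — named haplotypes defined by one or more key sequence variants —
and an individual's pair of star alleles (the *diplotype*) predicts their
metaboliser phenotype: poor (PM), intermediate (IM), extensive (EM) or
ultra-rapid (UM). Assigning star alleles from raw variant calls is not a
lookup: the same unphased variant observations can be consistent with
several diplotypes, copy-number events (the `*5` whole-gene deletion,
`xN` duplications, exon-9 gene conversions) are assayed separately from
sequence variants, and genotyping platforms differ in which alleles they
can represent at all.

PGxStar implements this pipeline end to end: an allele catalog, a
diplotype caller that integrates CNV and conversion evidence and flags
novel alleles, Activity-Score phenotype prediction, cohort-level
population-genetics statistics, and a synthetic cohort simulator with
parametrised platform error models so that every stage can be validated
without subject-level data.

## The allele catalog

`builtinCatalog()` holds the star alleles of both genes with gene-local,
1-based coordinates (negative positions are upstream of the ATG; position
0 does not exist), the convention in which pharmacogene variants are
reported (e.g. `2988G>A`, `-1584C>G`). Each allele carries:

* **key variants** — the allele-defining set (e.g. `2988G>A` for
  CYP2D6 `*41`);
* **backbone variants** — non-defining variants the haplotype is known to
  carry (e.g. the `-1584C>G` promoter SNP on the `*2` backbone);
* an **activity class** with a numeric value: increased 2.0, normal 1.0,
  decreased 0.5, absent 0.0; alleles of unknown activity default to 1.0
  so they can participate in scoring;
* a **copy-number multiplier**: 0 for the `*5` deletion, 2 for `xN`
  duplication alleles, 1 otherwise.

Two deliberate catalog choices:

* The hybrid CYP2C19 haplotype carrying both the `19154G>A` splice defect
  and the `-1401G>A` promoter SNP is stored as a distinct allele
  `*2+*27` with the activity of `*2` (0.0), because the splice defect is
  the allele-defining lesion. Its annotations record that at allele level
  it is conventionally reported as `*2`.
* The `*27` promoter SNP is catalogued at `-1401`; the alternative
  printed position `-1041` circulating in parts of the literature is
  noted in the allele's annotations rather than silently adopted.

Alleles whose defining SNPs are taken from the public nomenclature tables
rather than being measured by the analyses this package models are marked
`provenance = "external-nomenclature"`; nothing in the package's tests
depends on those placeholder positions.

## Haplotype matching and diplotype enumeration

`matchHaplotype()` assigns one (phased) variant set to the catalog allele
whose key variants are all present and whose key set is *maximal*: a
haplotype carrying the `*2` core plus `2988G>A` is `*41`, not `*2`. Two
distinct maximal matches of equal size are an ambiguity error. Variants
explained by neither the winner's key nor backbone set produce a
`NovelAlleleCandidate`: backbone = the best partial match, extra variants
recorded, and an assigned activity of 0.0 if the haplotype carries a
known null-defining variant (e.g. the `1846G>A` splice defect) and 1.0
otherwise — the field's default for uncharacterised alleles.

`enumerateDiplotypes()` handles unphased data with standard diploid
semantics: homozygous calls contribute their variant to both haplotypes,
each heterozygous call (or phase-set group) to exactly one. All
assignments of het groups to the two haplotypes are enumerated, each side
matched, and the distinct consistent pairs returned sorted by (fewest
novel candidates, lowest combined allele number). No population-frequency
prior is used in ranking — ambiguity is resolved by stated rules only,
and all consistent explanations are retained. The canonical example is a
CYP2C19 sample heterozygous for both `19154G>A` and `-1401G>A`: it is
`*2/*27` (AS 0.5) or `*2+*27/*1` (AS 1.0), and both are reported, the
first as primary.

CNV evidence then overrides sequence-only explanations
(`integrateCnv()`): one detected deletion replaces the second haplotype
with `*5` and re-interprets the remaining variants as a single copy (so a
sample homozygous for `*17` keys with one deletion is `*17/*5`, not
`*17/*17`); two deletions force `*5/*5`; a positive duplication assay
attaches `xN` to the allele(s) named by sequencing the
duplication-specific product. When the partner haplotype is identical to
the duplicated allele the single- and double-duplication explanations are
observationally equivalent; both are reported (primary first). Finally
`applyExon9Conversion()` relabels `*4` as the non-functional `*4N` and
`*10` as `*36` when the CYP2D7 exon-9 conversion assay is positive.

`callSample()` orchestrates enumerate → CNV → exon-9 → score and is
deterministic; evidence conflicts (e.g. phase sets demanding two
non-reference haplotypes alongside a single-copy deletion result) become
a `no_call` with a diagnostic note rather than an error.

## Activity Scores and phenotype prediction

The Activity Score of a diplotype is the plain sum of its two alleles'
numeric activities; duplications contribute twice their base value. The
phenotype bins are: AS > 2.0 UM; 1.5–2.0 EM; 0.5–1.0 IM; 0.0 PM. Because
per-allele values lie in {0, 0.5, 1, 2}, every attainable score is a
non-negative multiple of 0.5 and no score falls strictly between 0 and
0.5; `classifyActivityScore()` treats anything else as a domain error.

`classifyAmpliChipRules()` implements the categorical scheme used by
array-genotyping software: three or more functional gene copies (each
`xN` copy counting individually) predict UM; two absent-function alleles
PM; reduced-function alleles IM; otherwise EM. The middle rows overlap
for mixed normal/reduced pairs; we resolve those to EM when the AS is at
least 1.5 and IM otherwise, which keeps the two schemes consistent, and
every call records which rule row fired. Unknown-class alleles count as
functional (their default 1.0), and calls containing one are tagged
`contains-unknown` so cohort summaries can surface them; we deliberately
do not create a separate phenotype bucket for them, since scoring treats
them as normal-function.

## Cohort statistics

* `alleleFrequencyTable()` reports percent allele frequencies per stratum
  with "alleles identified" denominators — failed and no-call samples are
  excluded from denominators and tallied separately.
* `reconstructCounts()` inverts printed percentage tables to integer
  counts with half-up rounding (`floor(f/100 * n + 0.5)`); printed
  rounding can leave stratum totals a few alleles short of the
  denominator, which is why `functionalClassBreakdown()` accepts the
  printed denominator explicitly for its percentages.
* `hweExactTest()` is exact for biallelic data (probability-ordered
  enumeration of heterozygote counts conditional on allele counts) and
  seeded Monte Carlo for multi-allelic data (default 100,000 permutations
  of the allele vector; `p = (1 + #\{T_sim \le T_obs\}) /
  (1 + n_permutations)` with the conditional table probability as
  statistic). Monomorphic data return p = 1.
* `fisherExact2x2()` sums hypergeometric probabilities of all tables no
  more probable than the observed one, with a `1 + 1e-7` relative
  tolerance guard against floating-point ties.
* `ldPairwise()` computes D, D′ and r² from phased haplotypes or from
  unphased genotypes via EM (tolerance 1e-8 on the haplotype frequency,
  at most 1000 iterations, started from linkage equilibrium). Note a
  subtlety the tests respect: with double heterozygotes present the EM
  estimate is the maximum-likelihood haplotype frequency, which need not
  equal the realised phase of a particular sample; exact agreement with
  phased direct counts is therefore asserted on data whose phase is
  fully identifiable, and on general data the estimate is checked
  against a direct likelihood search.
* `platformConcordance()` compares two call sets over shared samples:
  per-allele Fisher tests, per-sample diplotype agreement, and a miscall
  matrix built by multiset-differencing each sample's pair and pairing
  the leftovers in allele order. When both alleles of a sample are
  miscalled simultaneously the positional pairing can attribute a miscall
  to the wrong target; pooled over replicates the injected error map
  dominates.
* The significance threshold is 0.05 with no multiple-testing correction
  by default, matching the analysis convention the package models;
  users can apply `p.adjust` to the per-allele column if desired.

## The synthetic cohort simulator

`defaultCohortConfig()` encodes the study conditions the package
emulates: a 100-sample cohort stratified as 70 Black African, 10
Caucasian, 10 Coloured and 10 Indian individuals, with per-stratum allele
frequencies transcribed from the comprehensive-platform columns of the
cohort frequency tables (gene re-sequencing for CYP2D6, PCR-RFLP for
CYP2C19). Within each stratum two alleles per individual are drawn
i.i.d. from the frequency map — Hardy-Weinberg sampling; strata are
independent and no admixture is modelled. Three transcription choices:

* Printed percentages carry rounding (the Black African CYP2D6 column
  sums to 97.8%), so each stratum's map is renormalised to sum to 1.
* The Coloured `*59` entry is kept at the printed 0.5% even though the
  cohort-wide decreased-class tally only reconstructs if it were 5.0%;
  we do not guess the erratum.
* The CYP2C19 hybrid `*2+*27` haplotype is split out of the printed `*2`
  frequency at the carrier counts reported (3 Black African, 1 Indian
  chromosome), so the documented ambiguity class is exercised.

`simulateTruth()` derives each sample's variant calls from the catalog
key + backbone variants, sets deletion flags for `*5` draws and
duplication flags (with the duplicated allele as hint) for `xN` draws,
and is reproducible for a fixed seed (one seeded generator per run,
recorded in output provenance).

`applyPlatformModel()` corrupts a truth cohort with a
`PlatformProfile`: per-haplotype miscalls, heterozygous-deletion dropout
(a `(*X, *5)` sample reported `(*X, *X)`), and whole-sample failures and
no-calls. `amplichipProfile()` encodes the documented array error modes:
alleles the array cannot represent miscalled deterministically
(`*45B`/`*46` → `*41`, `*56B` → `*10`, `*59` → `*2` or `*22` 50/50,
`*33`/`*43` → `*1`, the novel alleles to their nearest covered backbone;
CYP2C19 alleles beyond `*1`/`*2`/`*3` to wild type). The rate-based
modes are estimates derived from reported tallies relative to exposure
counts, not measured rates: `*2` → `*41` at 0.375, `*1` → `*41` at 0.07,
heterozygous `*5` dropout at 12/17, failure 0.224, no-call 0.04. All are
plain slots.

What the simulator does *not* emulate: raw reads or hybridisation
physics, admixture between strata, linkage between the two genes, de
novo variation (novel alleles appear only through the catalogued novel
haplotypes), or per-ethnicity error rates. Passing round-trip tests
therefore show the caller inverts the generator's observation model —
they do not certify performance on real chromatograms or arrays.

## Numerical and design notes

* Diplotype normalisation orders each pair by ascending star number
  (`*2+*27` counts as 2 + 27 = 29; `xN` keeps the base number), then
  name; ties in enumeration order are broken by the pair label, so
  output is fully deterministic.
* Haplotype partitions whose match is ambiguous (two equal maximal keys)
  are skipped during enumeration; if nothing survives, the
  all-on-one-haplotype partition is forced through with novel candidates
  so the result list is never empty.
* Exact-test p-values use log-gamma arithmetic and a `1 + 1e-7` relative
  guard when summing probability-ordered tails.
* Problem sizes in the test-suite calibration checks (e.g. 200
  replicates of a 5,000-sample stratum for the HWE size check, 100-seed
  round-trip batches of the 100-sample default cohort) were chosen as
  the smallest sizes at which the checked properties are stable.
* VCF output is a minimal v4.2 subset: one contig per gene, POS =
  gene-local position + 5000 (offset recorded in the header) so promoter
  positions stay positive, labels in the ID column, `N`-anchored
  insertions/deletions, unphased GT. `VariantAnnotation::readVcf` is
  used both as the reader and as the strictness check in tests.

## Limitations

The caller resolves unphased ambiguity by enumeration and deterministic
ordering, not by population priors — on real cohorts the reported
alternatives should be carried downstream rather than discarded. The
duplication model treats `xN` as exactly one extra copy; arrays that
report higher copy numbers are out of scope. The catalog covers the
alleles relevant to the analyses modelled here, not the full nomenclature
database.
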