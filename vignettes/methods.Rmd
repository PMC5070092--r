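---
title: "Detecting sex-linked variation from pooled sequencing: methods and design"
author: "PoolSexScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-linked variation from pooled sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(PoolSexScan)
  library(GenomicRanges)
  library(S4Vectors)
})
```

## The problem

In a young XY (or WZ) sex-determination system, the X and Y chromosomes are
still largely homologous, so cytogenetics and assembly-based approaches fail
to localise the sex-determining region. Pooled whole-genome sequencing of the
two sexes offers a cheap signature instead. Consider a single family in which
every male is XY and every female XX, sequenced as one male pool and one
female pool. At a site where the Y carries a derived allele:

* the female pool contains only X chromosomes, so it is **fixed (or nearly
  fixed)** for the X allele;
* the male pool contains equal numbers of X and Y chromosomes, so the
  Y allele sits near frequency **0.5** — in practice anywhere in an
  intermediate band once sampling noise is allowed.

A *sex-patterned SNP* is a site showing exactly this profile. PoolSexScan
detects such sites, quantifies per-site differentiation between the pools,
tests genomic regions for enrichment, compares two species that may share an
ancestral sex-determining region, merges conserved copy-number variants
(CNVs), and asks whether candidate SNPs create or destroy transcription
factor binding sites on the Y haplotype.

## Per-site model and statistics

The atomic datum is a biallelic site with ref/alt read counts in each pool
(class `PooledCounts`, a `RangedSummarizedExperiment` with `ref` and `alt`
assays over two columns of role `"het"` and `"hom"`). Which pool is
heterogametic is declared by the user, never inferred, so WZ systems are
handled by swapping roles.

Writing $p_1$, $p_2$ for the alt-allele frequencies in the heterogametic and
homogametic pool and $n_1$, $n_2$ for the read depths, `scanSites()` computes
for every site:

* **Cp** — half the L1 distance between the two allele-frequency vectors,
  $C_p = \sum_i \tfrac12 |x_i - y_i|$, which for a biallelic site reduces to
  $|p_1 - p_2|$; 0 means identical pools, 1 disjoint allele support.
* **FST** — the pi-based per-site estimator: within-pool diversity
  $\pi = \frac{n}{n-1}\,2p(1-p)$ for each pool, $\pi_S$ their mean, $\pi_T$
  computed identically from the summed counts, and
  $F_{ST} = (\pi_T - \pi_S)/\pi_T$. Because the $n/(n-1)$ correction factor
  is smaller for the summed counts than for each pool, identical pools give a
  slightly negative estimate; negative values carry no differentiation
  signal and are truncated at 0. When $\pi_T = 0$ or either depth is
  below 2 the statistic is undefined and reported as `NA`, never 0 — region
  averages over "polymorphic sites" must be able to exclude them.
* **dxy** — the probability that one read drawn from each pool differs,
  $d_{xy} = p_1(1-p_2) + p_2(1-p_1)$, and **da** $= d_{xy} - (\pi_1+\pi_2)/2$
  with the same corrected $\pi$, for internal consistency with FST.
* **Nei's D** — $-\ln I$ with
  $I = \sum_i x_i y_i / \sqrt{\sum_i x_i^2 \sum_i y_i^2}$. At alternatively
  fixed sites $I = 0$ and D diverges; there, and only there, frequencies 0
  and 1 are replaced by $1/\texttt{maxCoverage}$ and
  $1 - 1/\texttt{maxCoverage}$ (default ceiling 100), which bounds D at
  about 3.9 while leaving partially fixed sites untouched. This is the
  narrowest reading of a fix for "numeric difficulties at the upper bound":
  it alters no site whose D is already finite.

## Classification thresholds

`detectorParams()` collects the tunables, all unitless frequencies or read
counts:

| parameter | default | meaning |
|---|---|---|
| `hetLow`, `hetHigh` | 0.3, 0.7 | closed frequency band for the candidate Y allele in the heterogametic pool |
| `homogFixedMax` | 0.1 | maximum minor-allele frequency still "nearly fixed" in the homogametic pool |
| `minDepth` | 10 | per-pool depth below which a site is not evaluated |
| `minAlleleCount` | 2 | minimum reads supporting the candidate Y allele in the heterogametic pool |
| `maxCoverage` | 100 | clamp ceiling for Nei's D at alternatively fixed sites |

Design choices that were genuinely open:

* The intermediate band is **closed** on both ends — "between 0.3 and 0.7"
  read inclusively; boundary sites (frequency exactly 0.3 or 0.7) qualify
  and are covered by tests.
* "Fixed or nearly fixed" has no published cutoff; 0.1 is our default,
  symmetric with the 0.2 gap to the band edge, and it is an explicit
  parameter rather than a constant.
* `minAlleleCount` applies to the candidate sex-linked allele in the
  heterogametic pool, since that is the allele whose reality the filter
  protects against sequencing error.
* Undefined statistics are `NA` in all outputs.

## Windows, enrichment and region tests

`windowCounts()` tiles every chromosome with non-overlapping windows
(default 10 kb) anchored at coordinate 0; a 1-based position $pos$ belongs to
window $\lfloor (pos-1)/10000 \rfloor$, the trailing partial window keeps its
true length, and each window's *effective length* subtracts its overlap with
assembly gaps. A window is *enriched* when it holds at least 10 sex-patterned
SNPs (inclusive). `summarizeRegion()` reports, per region, the mean FST over
sites with defined FST (all polymorphic sites, not only sex-patterned ones),
counts and per-Mb densities of sex-patterned SNPs and enriched windows, and
optional effect-class densities from an external annotation table; report
densities are rounded half-up to 2 decimals.

Region comparisons use the Mann–Whitney U test on per-window counts
(windows assigned to a region by midpoint, which disambiguates windows
straddling a boundary). `mannWhitneyU()` computes U from rank sums with
midranks; the two-sided p-value is exact by full enumeration of all
$\binom{n_a+n_b}{n_a}$ assignments when $n_a+n_b \le 16$ without ties, and
otherwise uses the normal approximation with tie and continuity corrections.
Two-sided is the conservative default since no direction is prescribed. The
family-wise error rate is Bonferroni-controlled; with the default family of
12 comparisons the threshold is $0.05/12 = 0.004167$ (reported rounded
half-up to 6 decimals). The family size $m$ is an explicit parameter because
the set of comparisons is study-specific.

## Shared SNPs between species

When two species are mapped to one reference, positions sex-patterned in
both are candidates for an ancestral sex-determining mutation.
`intersectAndClassify()` labels each shared site from its four inferred
alleles, checked in this order: `CONSERVED` (same X and Y), `SWITCHED`
(X and Y exchanged between species, the signature of alternative lineage
sorting of an ancestral polymorphism), `SAME_X_DIFF_Y` (same X, different Y
— Y-allele replacement), and `OTHER`. `OTHER` is reported even though a
clean data set may leave it empty, so the classes always partition the
total. The null expectation for the shared count in a region of length $L$
is $n_a n_b / L$ (`expectedShared()`), reported both unrounded and at 2
decimals; no significance test is attached — the quantity is an expectation
to compare against, and with the region's published inputs (5,342 and
10,792 sex-patterned SNPs in 8.8 Mb) it evaluates to 6.55.

## Conserved CNVs

Copy-number input is VarScan-2-style segments (mean depths and a log2
ratio); calling those segments is an upstream concern. `thresholdSegments()`
directions them with the inclusive rule AMP $\iff \log_2 \ge 0.2$,
DEL $\iff \log_2 \le -0.2$. A *conserved* CNV (`conservedCnvs()`) is a
maximal interval covered in **all** tracks by same-direction segments — the
per-base rule "every comparison votes the same way", with `minSupport`
exposed for relaxed majorities. The implementation uses interval algebra
(reduce/intersect); the test suite checks it against an independent
per-base brute-force oracle on random 3-track instances. Window densities of
conserved CNVs use midpoint assignment and gap-excluded effective lengths;
fully-gapped windows are excluded (`NA` density).

## Allele-specific binding-site scanning

`pfmToPwm()` converts JASPAR position frequency matrices to log2-odds
weights with a total pseudocount of 0.8 distributed by the background
composition (uniform by default) — a common JASPAR-tool convention; both are
parameters since only the database and the 0.80 relative-score threshold are
fixed by convention. A window's *relative score* is
$(\mathrm{raw} - \min)/(\max - \min)$, invariant under affine rescaling of
the matrix. `scanSequence()` scores every offset on both strands;
`alleleDiff()` substitutes the X and the Y allele at the variant position
and compares **only windows overlapping the variant base**, so a reported
`LOST_ON_Y`/`GAINED_ON_Y` is attributable to the SNP itself rather than to
distal sequence. The default flank radius is 20 bp, comfortably above
vertebrate core-motif lengths. Swapping the X/Y labels exchanges LOST and
GAINED, which the tests assert.

## The synthetic-data generator

`simulatePools()` emulates the study design the package targets: a single
XY family pooled as 21 males and 22 females (one ambiguous individual
excluded from an initially even cross) sequenced to ~35x per pool. These are
the generator defaults. The generative model is deliberately the converse of
the detector:

* Sex-patterned sites (rate `sdSnpRate` per bp inside `sdRegion`): female
  chromosomes all carry X; the male chromosome-level Y frequency is exactly
  $n_\mathrm{males}/(2 n_\mathrm{males}) = 0.5$ — all read-count dispersion
  comes from Poisson depth and binomial sampling, as in a single-family
  cross.
* Background sites: one shared allele frequency per site, uniform on
  $\{0.1, \dots, 0.9\}$ in both pools — the simplest adversarial spectrum
  without sex linkage, which the detector must reject.
* Sequencing error is a per-base flip probability, 0 by default; the
  `minAlleleCount` filter exists to absorb it and tests switch it on
  explicitly.

`simulateSpeciesPair()` models partial lineage sorting: a fraction of one
species' sex-determining sites is shared with the second species and split
by deterministic rounding into conserved, switched and Y-replaced classes;
private sex-patterned sites stay positionally disjoint between species so
the truth intersection is exactly the shared set. `simulateCnvTracks()`
plants CNVs present in all tracks (|log2| ≥ 0.2, consistent sign, optional
boundary jitter) among single-track noise segments.

What the generator does **not** model: read-level artefacts (mapping bias,
duplicates, indels), linkage between neighbouring sites, a realistic allele
frequency spectrum, overlapping CNV calls of opposite sign within one track,
or reference bias toward the X. Passing recovery tests therefore show the
statistical machinery is correct under the stated sampling model, not that
real-data error modes are handled; the depth and allele-count filters are
the only defences exercised against those.

## Verification strategy and problem sizes

The test suite pairs every nontrivial computation with an independent
oracle: hand-evaluated fixtures for Cp/FST/dxy/da/Nei's D;
`stats::wilcox.test`'s exact p-values for the Mann–Whitney implementation;
a per-base voting oracle for conserved CNVs (100 random 3-track instances);
a brute-force scorer for PWM scans, including an exhaustive sweep of all
4,096 6-mers against a length-4 motif. End-to-end recovery runs at two
scales chosen to keep the default suite fast: the study design (≈2,000
planted sex-patterned sites among ≈10,000 background sites at 35x, where
recall ≥ 0.90 and precision ≥ 0.99 are required) and a noiseless regime
(10,000x, ≈100 sites) where recovery and the shared-class allocation must be
exact. Determinism is part of the contract: every simulation takes a seed,
and identical configurations produce byte-identical output files.

## Known limitations

* Biallelic sites only; multiallelic records are excluded at ingest.
* Two pools; designs with replicate pools per sex are out of scope.
* The FST estimator is self-contained and documented here; it follows the
  pi-based "classical" pool-seq form but is not guaranteed to match any
  particular external tool bit for bit.
* No liftover: cross-species comparison assumes both species are mapped to
  the same reference.
* The expected-shared-count null ignores positional clustering of
  sex-patterned SNPs; it is an expectation, not a test.

## A worked micro-example

```{r example}
pc <- PooledCounts(
  chrom = "chr1", pos = c(100L, 200L, 300L),
  ref = c("A", "C", "G"), alt = c("G", "T", "A"),
  hetRef = c(18L, 20L, 5L), hetAlt = c(12L, 0L, 4L),
  homRef = c(30L, 25L, 30L), homAlt = c(0L, 0L, 0L))
st <- scanSites(pc)
as.data.frame(st)[, c("ref", "alt", "p_het", "fst", "cp",
                      "sex_patterned", "evaluated")]
```

Site 1 is the textbook sex-patterned profile (Y allele at 0.4 in the male
pool, absent in the female pool); site 2 is monomorphic (statistics
undefined, `NA`); site 3 fails the depth filter and is not evaluated.
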