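---
title: "Methods: ROH detection, genomic inbreeding, islands and LD decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, genomic inbreeding, islands and LD decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the statistics it computes, the
choices made where conventions diverge, and what the synthetic-data tests
do and do not establish about real data.

## The data model

Genotypes live in a `genotype_matrix`: a samples × SNPs dosage matrix with
entries in {0, 1, 2, NA}, counting copies of a designated allele per SNP.
Every statistic in the package that concerns homozygosity depends only on
the collapsed state {homozygous, heterozygous, missing}, so the allele
that is counted is irrelevant to ROH, F_ROH, F_HOM and incidence; it
matters only for allele frequencies, where it is reported explicitly.
Positions are 1-based physical bp, strictly increasing within a
chromosome, matching the MAP/BIM convention. PED text input codes alleles
by first observation (first seen allele per SNP is `allele_a`); BIM allele
columns are taken as authoritative for binary input and never re-inferred.

Quality control applies, in order: non-autosomal SNP removal (pig
autosomes 1–18 by default), sample call rate, SNP call rate (recomputed on
retained samples), MAF. "Call rate higher than 0.9" is implemented as
≥ 0.9 — retaining the measure-zero boundary case — while "MAF greater
than 0.01" is strict, so a SNP at exactly 0.01 is removed; each phrase is
kept literal where it is unambiguous. The order (samples before SNP call
rate, call rate before MAF) is the dominant convention of array-QC
tooling and is recorded in the QC report so alternative orders are
auditable. Expected heterozygosity uses the uncorrected 2p(1−p); the
small-sample correction is reserved for F_HOM's expected-homozygosity
term, which is where standard implementations apply it.

## ROH detection

The detector is the sliding-window scan of array-based ROH studies. Per
individual and chromosome, a window of `window_snps` (default 50) SNPs
slides one SNP at a time; a window is *homozygous* iff it contains at most
`max_het_per_window` (1) heterozygotes and `max_missing_per_window` (5)
missing calls. Each SNP's *hit fraction* is the proportion of windows
containing it that are homozygous; SNPs with hit fraction ≥
`window_hit_threshold` are flagged as "in ROH". Maximal runs of flagged
SNPs become candidate segments, split wherever the gap between
consecutive SNPs exceeds `max_gap_kb` (1,000 kb — prevents segments
bridging assembly gaps; the scan criteria alone would happily jump them).
A candidate survives iff its inclusive length (`end − start + 1`) is at
least `min_length_bp` (1 Mb), it spans at least `min_snps` (50) SNPs, and
its average spacing is at most `max_density_kb_per_snp` (100 kb/SNP).

Numerical and boundary choices:

- `window_hit_threshold` defaults to 0.05, the established default of the
  sliding-window method; the verbal description of segment calling in the
  literature ("a threshold based on the average value") is not
  operational, so the threshold is exposed as a parameter.
- Windows are never truncated at chromosome ends: end SNPs simply belong
  to fewer windows, which the per-SNP denominator absorbs. The one
  exception is a chromosome with fewer SNPs than `window_snps`, which is
  scanned with a single full-chromosome window rather than skipped.
- The density criterion is applied to the final segment
  (`length_kb / n_snps`), not per window, and no limit is placed on
  heterozygotes inside a final segment beyond what the window criterion
  induces — allowances are stated per window only.
- Length classes are a left-closed partition: [1, 5), [5, 10), [10, ∞)
  Mb. The labels "1–5, 5–10, >10" are ambiguous at exactly 5 and 10 Mb;
  left-closed bounds make the classes a partition, so a 5 Mb segment is
  "5–10".
- Segment length is inclusive (`end − start + 1`), consistent with
  reported island tables in this literature, where printed length equals
  end − start + 1.

`naive_roh_oracle()` restates the same contract as explicit loops — every
window summed afresh, containing windows enumerated per SNP, segments
assembled by walking flagged SNPs — and the test suite requires exact
equality with the fast caller on hundreds of randomized instances with
randomized parameters. The two implementations share the contract but no
code path.

## Inbreeding coefficients

`F_ROH = ΣL_ROH / L_auto`. `L_auto` is computed as the sum over
chromosomes of the inclusive span between the first and last retained
SNP — a literal reading of "genome covered by the SNPs" — rather than a
nominal chip genome size; a fixed override is available for cross-study
comparability. Per-class coefficients use the same denominator, and the
reported total is the *sum of the class coefficients*, so additivity holds
exactly in floating point rather than within rounding.

`F_HOM = (O − E)/(L − E)` per sample, with per-SNP expected homozygosity
`1 − 2p(1−p) · 2N/(2N−1)` (method-of-moments small-sample correction; `p`
and `N` from the post-QC sample itself). By default O, E and L are
restricted to the sample's own non-missing SNPs, keeping the three counts
on one support; a flag switches to the all-SNP panel since published
analyses do not always state which support they used. `L = E`
(e.g. a degenerate monomorphic-only support) yields NA rather than an
arbitrary value; F_HOM is negative for individuals with above-expected
heterozygosity, bounded below by `−E/(L−E)`.

Correlations are plain Pearson on all samples with defined values,
pairwise-complete; constant columns yield NA entries rather than
propagating NaN.

## ROH islands

Incidence of a SNP is the number of individuals with a segment spanning
its position (each individual counted once), divided by the number of
individuals. The island threshold is the incidence at rank
`ceiling(0.01 × nSNPs)` from the top; qualification is inclusive (≥), so
ties at the threshold may push the qualifying set slightly over 1% —
matching the convention that the "top 1%" names a threshold value, not an
exact count. Islands are maximal runs of *consecutive* qualifying SNPs
(adjacency means consecutive in SNP order; an optional bp gap cap is off
by default), with coordinates at the first/last qualifying SNP and
inclusive length. `min_island_snps` defaults to 2 so an isolated noisy
SNP cannot form an island; reported islands in this literature have ≥ 19
SNPs, so any minimum up to that is inconsequential for real panels.
Feature annotation is a 1-bp-overlap interval join against user-supplied
BED/GFF3 via GenomicRanges; gene-function inference is out of scope.

## LD decay

r² is the squared Pearson correlation of the two dosage vectors over
samples non-missing at both SNPs — the composite, genotype-level LD
estimator that genotype-based pipelines compute; an EM haplotype
estimator is deliberately not implemented. Pairs are restricted to one
chromosome, ≤ 99,999 index separation and ≤ 1,000 kb (configurable
upward, since decay beyond 1 Mb is sometimes of interest). Pairs with a
monomorphic SNP on the common support, or fewer than 2 common samples,
are skipped and tallied. Distance bins are half-open `[k·100, (k+1)·100)`
kb from zero; a pair at exactly 100 kb falls in the second bin. The LD
extent at a level r²\* interpolates linearly between the midpoints of the
last bin at or above r²\* and the first below; if even the first bin is
below r²\*, an anchor at distance 0 carrying the consecutive-pair mean r²
is used, and if the level is never crossed the extent is reported as
undefined instead of extrapolated. Because "average r² between adjacent
SNPs within 100 kb" has two readings, both are computed and labelled: all
pairs closer than 100 kb, and strictly consecutive pairs closer than
100 kb. Panel size for a genome `G` at spacing `s` is `ceil(G/s)`.

## The synthetic-data generator

The generator produces exactly the statistical structure the analysis
consumes, and no more:

- **Map**: per chromosome, spacings are exponential (mean 50 kb, min
  1 bp), cumulated to 1-based positions — 2,000 SNPs span ~100 Mb, so the
  default 18 × 2,000 panel emulates a ~50K array on a ~1.8 Gb autosomal
  genome.
- **Background genotypes**: Hardy–Weinberg draws at frequencies uniform
  on [0.05, 0.5]; with `ld_block_snps > 1`, each individual instead draws
  two haplotypes per block from a small founder pool (default 8), which
  creates within-block LD that decays linearly with distance out to the
  block span and a realistic tail of drift-monomorphic SNPs for QC to
  remove.
- **Autozygosity**: IBD tracts are planted directly — per individual a
  Poisson number of tracts with mean `target_f × genome / E[tract]`,
  lengths exponential with mean `tract_mean_bp` (default 4 Mb)
  *conditioned on* ≥ 1 Mb (equivalently 1 Mb + an exponential of the same
  mean; conditioning rather than clamping avoids an artificial atom of
  tracts at exactly the minimum, which real IBD length distributions do
  not have), placed uniformly without overlap. Inside a tract one allele
  is drawn per SNP and doubled; `het_error_rate` then flips tract
  genotypes to heterozygous, deliberately exercising the one-het-per-
  window allowance; missingness is applied genome-wide last. `target_f =
  1` is special-cased to whole-chromosome tracts. An `island_region`
  forces a shared tract into a stated fraction of individuals.
- All randomness flows from one mandatory seed; identical configs give
  byte-identical fixtures.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: pedigree-structured relatedness and
realistic IBD length mixtures from specific demographic histories,
ascertainment-biased allele-frequency spectra, genotyping-error modes
other than symmetric het flips inside tracts, LD that decays smoothly
beyond one block span, and sex chromosomes. Tract planting is the minimal
sufficient model for a tract-based ROH analysis; it validates the
detector and estimators, not any demographic inference.

## Problem sizes and observed behavior

The test and acceptance suites use: oracle equivalence on 500 random
instances of up to ~200 SNPs × 3 chromosomes with randomized scan
parameters; parameter recovery on 200 individuals × 18 chromosomes ×
2,000 SNPs at planted F of 0.05/0.10/0.20 (observed: mean F_ROH within
~0.01 of the target, correlation with per-individual truth ≈ 0.99);
island recovery at 100 individuals with a 3.5 Mb tract carried by 80%;
and LD checks at 500 individuals (null: mean r² ≈ 1/n) and 200
individuals × 5 chromosomes (block model: monotone non-increasing bin
means). These sizes were chosen as the smallest that make the
Monte-Carlo tolerances meaningful.

Two systematic effects are worth knowing. First, recovered F_ROH is
mildly biased downward because tracts spanning fewer than `min_snps`
markers (≲ 2.5 Mb at 50 kb spacing) are invisible to the detector — an
inherent property of array-based ROH calling, not of the implementation;
boundary overshoot of a couple of SNPs per segment end partly offsets it.
Second, with strong LD (small founder pools) chance runs of shared
haplotypes create genuine short ROH that inflate F_ROH relative to
planted truth; this mirrors the real-data caveat that short-ROH classes
partly measure LD structure rather than inbreeding.

## Limitations

No genotype-likelihood or HMM ROH calling (sequencing data), no VCF
input, no imputation or strand handling, no pedigree or GRM-based
inbreeding estimators, no haplotype phasing or D′, and no
effective-population-size inference from LD. Feature annotation is a
coordinate join; assigning biological function to genes in islands is
outside the package.
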