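---
title: "Methods: SV catalogs, selection scans and introgression calling with svadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV catalogs, selection scans and introgression calling with svadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`svadapt` implements a population-genomic analysis of structural variants
(SVs) in high-altitude human populations: it merges per-sample long-read SV
calls into a non-redundant catalog, annotates the catalog against repeat and
functional tracks, quality-controls short-read SV genotypes, identifies
population-stratified SVs by F~ST~, and asks — using haplotype statistics on
the flanking SNVs and a coalescent-simulation null — whether each stratified
SV sits near signatures of positive selection, archaic introgression, or
both (adaptive introgression).  A synthetic-data module generates every
input with known ground truth so that each stage can be scored against
truth.

# The synthetic-data model

## Demography

The default three-population model (`tibHanAfrModel()`) is a
Tibetan–Han–African tree: Tibetans and Hans diverge 22,000 years ago, their
common ancestor splits from Africans 88,000 years ago, with symmetric
migration (10^-4^ per generation) among the extant modern populations.
A second model (`tibHanNorthSouthModel()`) encodes the very recent
northern/southern Han divergence (770 years) below the 17,000-year
Tibetan–Han split.  Time is converted at 25 years per generation
(configurable).  Point estimates for effective sizes are placeholders
chosen at realistic orders of magnitude (ancestral 10,000; Tibetan 5,000;
Han 20,000; African 15,000) and are all constructor arguments: the fitted
values behind the published demographic inference are not part of this
package's inputs, so nothing downstream depends on them beyond the null
being simulated under the *same* model as the data.

The archaic branch diverges 600,000 years ago and delivers a single pulse
into the Tibetan lineage.  The default pulse time is 15,000 years ago —
deliberately *after* the Tibetan–Han split.  The biological history has the
Denisovan-like pulse entering the common ancestor of East Asians with the
introgressed haplotype later selected in Tibetans; emulating that faithfully
would make Tibetans and Hans statistically symmetric at desk scale and the
D/f~d~ contrast powerless.  Placing the pulse on the Tibetan branch gives
the introgression statistics a target-specific signal while the selection
component is emulated separately by sweep implantation.  Both choices are
explicit parameters (`pulseYears`, `pulseFrac`).

Simulation is delegated to the coalescent simulator msprime through a
bundled Python helper; haplotypes come back as 0/1 matrices with the
ancestral allele 0 by construction (binary mutation model).  True
introgressed tracts are recovered exactly by inserting a census just above
the pulse time and linking each sampled haplotype's ancestry to census
nodes sitting on the archaic branch.

## Sweep implantation

`implantSweep()` creates elevated haplotype homozygosity without forward
simulation: a fraction (default 90% in the power tests) of the haplotypes
carrying a chosen derived allele are overwritten by recombined copies of one
template carrier, with per-copy breakpoints drawn from an exponential of
mean `decayScale` (200 kb in the power tests) on each side of the core.
This is a stand-in, not a population-genetic model of a sweep: it produces
the EHH/iHS/XP-EHH signal shape (long shared haplotypes around the core,
decaying with distance) but no accompanying allele-frequency trajectory or
linked-diversity reduction beyond what the copying induces.  Power results
on implanted sweeps therefore demonstrate that the statistics detect
extended haplotype homozygosity, not calibrated power against a specific
selection coefficient.  Power is assessed in each statistic's own domain:
iHS at mid-frequency sweeps (focal derived frequency near 0.40) and
XP-EHH at high-frequency sweeps (near 0.60) — the classical division of
labour between the two statistics.

## SV callsets, genotypes and tracks

`generateTruthSVs()` draws loci with the characteristic bimodal SV length
spectrum (Alu-like mode at 300 bp, L1-like mode at 6 kb, log-uniform
background, minimum 50 bp) spaced at least 5 kb apart. `generateSVCallsets()`
adds discovery noise: a Gaussian positional shift per call (default sd
20 bp, matching the observed cross-sample breakpoint scatter) that moves
both breakpoints together — the dominant long-read error mode, where an
event slides within a repeat while its called length stays consistent —
plus independent length jitter for insertions, carrier dropout and genotype
error.  `generateGenotypeMatrix()` emulates short-read graph
genotyping across a 276-sample panel (78 Tibetan, 174 Han, 24 African by
default) with Hardy–Weinberg sampling within populations, a configurable
allele-frequency shift for planted population-stratified loci, and random
missingness.  `generateTracks()` produces repeats (SINE ~300 bp, LINE
~6 kb, LTR, DNA), tandem repeats, segmental duplications, gene models with
TSS/exon/intron structure, a 15-state chromatin tiling, CTCF clusters, TAD
boundaries and intra-chromosomal loop-anchor pairs.  What the generator does
*not* emulate: sequencing reads, reference biases, repeat-driven genotyping
failure correlated with SV class, or realistic LD between the SV and its
flanking SNVs.  Tests passing on these data show the algorithms are correct
and calibrated, not that real data meet their assumptions.

# Catalog construction

Per-sample calls of the same type on the same chromosome are merged by
single-linkage clustering: two calls link when their starts and ends
(insertions: starts and lengths; translocations: both breakends, no length
test) lie within 1 kb and their lengths agree within a 0.7 min/max ratio.
The 1 kb / 0.7 defaults are package choices: the published 100 bp figure is
a breakpoint-concordance *statistic*, not a merge threshold, and the actual
merge criteria are not in the available text.  The cluster representative is
the member with the highest read support (ties: smallest start), which makes
merging deterministic and idempotent.  Under 20 bp breakpoint jitter this
recovers ≥ 99% of truth loci.  Very short loci (50–100 bp) can split when
per-breakpoint noise pushes the length ratio past 0.7; with the shift-type
noise model the called lengths stay consistent and splitting is rare.

Discovery categories follow the cohort definitions (shared = all samples,
major = at least half, singleton = one, polymorphic = the rest) and
partition the catalog exactly.  Genotype filtering is a hard
support/quality threshold with a removal log; the published analysis used
an unstated hard threshold, so both thresholds are exposed as
configuration.  Novelty against external callsets uses 50% reciprocal
overlap for DEL/DUP/INV and 1 kb + 50% length similarity for insertions.
Arm-tail density compares SV density in the distal 5 Mb of chromosome arms
with the rest of the arms against a uniform-repositioning permutation null.

# Annotation

Breakpoint junctions are the breakpoints ± 50 bp (insertions contribute a
single junction); the window size is a package default, exposed as a
parameter.  Enrichment uses length-preserving uniform repositioning within
chromosomes as the null, fold change against the permutation mean, a
two-sided empirical p-value with the +1 correction, and Bonferroni
adjustment across labels.  Formation mechanisms are classified with the
precedence VNTR (both breakpoints inside one tandem-repeat interval) >
NAHR (deletion with the same interspersed-repeat class at both junctions) >
TE (insertion whose inserted sequence is labelled as an interspersed
repeat); precedence is a package decision — containment in a tandem array
is the most specific signal, and the published pipeline's ordering is not
stated.  "Same family" means the same repeat class (SINE/LINE/LTR/DNA).
The loop-anchor rules mirror the published figure semantics: deletions
remove all interactions of an overlapped anchor; insertions within 10 kb of
an anchor duplicate it at the insertion point and connect the duplicate to
the partner anchors.

# Genotype QC

The Hardy–Weinberg test is the exact conditional test of the heterozygote
count given allele counts, two-sided by summing all configurations with
probability no greater than the observed one; it matches full enumeration
exactly for n ≤ 200 (property-tested) and a locus is removed when it
violates HWE in any population (α = 10^-3^ by default; the published
threshold is unstated).  Cross-dataset concordance tests 2×2 allele-count
homogeneity per dataset pair within shared populations by Fisher's exact
test; a locus fails when it fails more than one comparison.  Copy-number
profiles are round(2 × window mean depth / genome median) in 100 bp windows
stepped by 50 bp.

# F~ST~ and stratification

Both estimators are provided.  Weir–Cockerham (1984) computes the a/b/c
variance components from sample sizes, allele frequencies and *observed*
heterozygote frequencies, θ = a/(a+b+c), aggregated over windows as a ratio
of sums; negative values are reported as computed.  The Hudson estimator is
frequency-only with small-sample correction terms.  Stratified SVs are
called per site at F~ST~ > 0.1 with strict inequality (a published
top-deletion table reproduces to two decimals under the Hudson estimator
applied to the printed allele frequencies).  Window aggregation is provided
but stratification uses per-SV values, since the published per-SV table is
frequency-consistent at the site level.  LD tagging uses haplotype r² when
phase is available and genotype-dosage correlation otherwise.

# Haplotype statistics and the simulation null

EHH at distance d is the probability that two random carrier haplotypes are
identical at every site from the core to d, computed by partition
refinement in compiled code.  iHH integrates EHH over genetic distance
(uniform map from the recombination rate when none is supplied) by
trapezoid, truncating at the 0.05 EHH cutoff with linear interpolation to
the crossing and stopping at inter-site gaps above 200 kb.  iHS =
ln(iHH~ancestral~/iHH~derived~), standardized to mean 0, sd 1 within 50
derived-allele-frequency bins; sites with derived frequency outside
[0.05, 0.95] are skipped.  XP-EHH integrates each population's
all-haplotype EHH over the region where the *pooled* two-population EHH
stays above the cutoff, takes ln(iHH~A~/iHH~B~), and standardizes over the
scanned set; positive values mean longer haplotypes in the focal (Tibetan)
population.

D uses the frequency form of the ABBA–BABA contrast with the sister
population as P1, the test population as P2, the archaic as P3 and the
outgroup as P4; f~d~ normalizes the D numerator by the same numerator with
the donor replaced by the per-site higher-frequency of P2/P3, and is
undefined (NA) where the numerator is negative.  The S*-like score chains
SNVs whose derived allele is absent from the outgroup panel and present in
the scored individual: congruent pairs at distance d ≥ 10 bp score
5000 + d, mismatches −10000, and dynamic programming maximizes the chain
sum (equal to exhaustive subset enumeration, property-tested to 12 SNVs).
The constants follow the classical published scheme and are arguments.

Windows are 50 kb, non-overlapping; iHS and XP-EHH are summarized per
window by the maximum |standardized value|, D/f~d~/S* computed per window
directly.  Standardization matters: in a genome-wide scan the bin means and
standard deviations come from millions of overwhelmingly neutral sites, so
a sweep is local relative to its reference.  A desk-scale region
standardized against itself absorbs its own signal (a 500-kb swept region
shifts its bin means toward the sweep).  `standardizeIHS()` and
`xpehhScan()` therefore accept reference parameters — `ihsBinParams()` on
pooled neutral simulations, or the genome-wide scan — and
`scanWindows()`/`restandardizeWindows()` apply one common reference to
observed and null windows alike; per-frequency-bin null matching is
implicit in that shared standardization.  Significance is empirical against
windows from neutral simulations under the same demographic model:
p = (1 + #null ≥ observed)/(1 + #null), two-sided for iHS via the windowed
|iHS| maximum, upper-tailed for the rest.
An SV is a selection candidate when any window within 500 kb has iHS
p < 0.05, an introgression candidate when some window within the radius is
simultaneously significant for D, f~d~ *and* S* under the same archaic
reference (the published "p < 0.05 for D, f~d~ and S*" is read
conjunctively), and adaptive-introgressed when both hold; the reported
p-value is from the most significant, then closest, window.

# Haplotype views

Signal SNVs around a focal SV are those above a statistic threshold (e.g.
XP-EHH > 2) within a flank, optionally LD-filtered against the SV.
Clustering uses Hamming distance with average linkage (the published figure
states neither; Hamming is the natural metric for binary haplotypes and
average linkage is robust to the chained similarities typical of
haplotypes).  The network is TCS-like rather than TCS: edges are added in
increasing Hamming distance, keeping every tying edge between components
still separate at the start of the distance tier (reticulation), with an
optional step limit instead of the statistical-parsimony connection limit —
the figure's intent (clusters of deletion-carrying haplotypes) survives
this simplification.

# Numerical choices and problem sizes

Empirical p-values use the +1-corrected estimator, so p ∈ (0, 1] and a
value can never be 0; being discrete and conservative, these p-values are
*super*-uniform, so the shipped calibration checks assess uniformity on
their randomized counterpart (which is exactly Uniform(0,1) under the
null) — `permutationEnrichment()` reports the tie counts (`n_gt`, `n_ge`)
needed to form it.  Calibration draws one window per simulated replicate:
windows within a replicate share haplotypes, and a Kolmogorov–Smirnov test
on correlated p-values over-rejects.  For the window statistics the
held-out empirical p-values additionally share one finite null set and are
correlated through its ECDF, so their calibration is assessed as the
equivalent two-sample KS between held-out and null statistic values
rather than a one-sample KS of the p-values against Uniform(0,1).  HWE
probabilities are computed in
log space.  Ties in merging, clustering and representatives are broken
deterministically (support, then position, then sample).  All generators
take explicit seeds; identical seeds give byte-identical outputs,
including across the Python simulation boundary.

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the Monte-Carlo checks are stable: neutral
calibration uses 160–200 independent replicates of 100 kb with 38 diploids
across four populations (≥ 80 held-out windows per statistic; fewer for
f~d~, which is undefined in roughly half of neutral windows); power uses
12–20 replicate pairs of 500 kb with 52 diploids, a 5% pulse and a
90%/200 kb implanted sweep; diversity calibration uses 50 replicates of
1 Mb with 50 diploids; catalog checks average 5 fixtures of 150 truth loci
over 3 Mb with 25 samples.

# Known limitations

The S* variant and its window conventions follow the classical scoring
constants, not the (unpublished) variant used alongside the original
analysis.  iHS standardization at 50 bins needs many scanned sites; at
desk scale sparse bins fall back to NA and are excluded from window
summaries.  The 3D-interaction rules implement figure-level semantics, not
the cited chromatin-interaction algorithm.  Multi-allelic duplications are
excluded from mechanism classification and merging treats them as distinct
biallelic loci.  The pipeline's F~ST~ stage assumes exactly two contrasted
populations; multi-way F~ST~ is out of scope.
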