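---
title: "MNP marker panels for species monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MNP marker panels for species monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnpkit)
library(dplyr)
```

## The problem

Monitoring an aquatic species from environmental DNA (eDNA) is hard for two
reasons: the DNA is fragmented and dilute, and a single water sample pools
material from an unknown number of individuals. Single-locus approaches
(barcoding, qPCR) answer "is the species here?" but little else.
Multiple Nucleotide Polymorphism (MNP) markers — short amplicons (~180 bp)
containing several SNPs whose joint states form multiallelic haplotype
alleles, conceptually equivalent to microhaplotypes — trade locus length for
allelic richness: each marker distinguishes many genotypes, an entire panel
(the working default here is 115 markers) distinguishes individuals,
populations, and closely related species, and the short amplicons remain
amplifiable from degraded template.

`mnpkit` implements the full desk side of such a system: marker screening
from a multi-sample SNP matrix, genotype calling from amplicon read counts,
replicate quality statistics, panel and population summaries with
neighbour-joining clustering, species-diagnostic core-allele screening,
spike-in-calibrated absolute quantification, a binomial detection model,
and an eDNA presence decision rule. A synthetic-data generator produces
every input with known ground truth, so the whole pipeline is validated
without any external dataset.

## Marker screening: the window DP statistic

`scan_windows()` slides a window (default 120 bp, 5 bp step) along each
contig of a multi-sample SNP matrix. A window's discriminative power is

$$\mathrm{DP} = n / N$$

where $n$ counts sample pairs whose genotypes differ at at least
`min_snps_per_pair` (default 3) SNP positions inside the window and $N$
counts pairs with at least one co-called position. Three reading choices
deserve a note, because the statistic is often stated loosely in the field:

* **"At least three SNPs" means three *differing* positions for that
  pair.** DP is a discrimination probability — the chance two random
  samples can be told apart — so a variant both samples share identically
  contributes nothing.
* **Missing data is pairwise.** A position where either sample is missing
  is skipped for that pair only; a pair with no co-called position in the
  window is excluded from both $n$ and $N$ rather than being counted as
  non-discriminated.
* **Genotypes compare as unordered allele pairs.** `0/1` equals `1/0`;
  phasing is not used.

`select_markers()` keeps windows with DP above `dp_min` (default 0.2, a
conventional screening threshold exposed as configuration) and accepts them
greedily in descending DP order, skipping candidates whose ~180 bp amplicon
would come within `min_spacing` of an accepted marker. Greedy
max-DP-with-spacing is our concrete rendering of the informal goal of "high
DP, evenly spread": the default spacing, total contig length divided by the
requested panel size, forces genome-wide dispersal without an explicit
optimisation step. `check_candidate_region()` screens primer regions by
composition only (GC bounds, homopolymer runs, dinucleotide repeats, and a
reverse-complement self-match proxy for hairpins with a 12 bp stem);
thermodynamic primer design is deliberately out of scope and left to
dedicated tools.

## Genotype calling and replicate accuracy

`call_locus()` retains alleles with at least `min_reads` (default 10,
matching the read-support floor used in the eDNA positivity rule below) and
at least `min_allele_fraction` (default 0.05) of the locus total — the
fraction filter guards against index hopping and carry-over, which a pure
count threshold misses at high depth. Tissue mode keeps at most the two
best-supported alleles (an individual is diploid); eDNA mode keeps all
survivors, because a water sample has no individual-level zygosity. Ties at
the tissue-mode cut are broken by count and then lexicographically so calls
are reproducible. No surviving allele means the locus is *missing*, never
an empty genotype.

Replicate agreement between two independently constructed libraries uses

$$r = M_1 / M_2, \qquad a = 1 - (1 - r)/2,$$

with $M_2$ the loci called in both libraries and $M_1$ those with identical
allele sets. The accuracy form halves the disagreement rate because a
discordant locus implies an error in at most one of the two libraries;
$a$ is affine in $r$ with $a(0) = 0.5$, $a(1) = 1$.

## Panel and population statistics

`summarize_markers()` reports per-locus call frequency, heterozygous
proportion, allele count and a per-locus DP (the fraction of co-called
sample pairs whose allele sets differ). For environmental samples
"heterozygous" is read as "two or more alleles detected": zygosity is an
individual-level concept, and a mixture is scored by its observed allelic
complexity.

`pairwise_differentiation()` computes, for every sample pair, the fraction
of co-called loci at which the two allele sets differ. Any symmetric
difference counts: a partial overlap (e.g. {A} vs {A, B}) is a difference,
since the two samples are demonstrably not the same template pool. The
unweighted mean over pairs is reported by `glance()`; stratified means
(tissue–tissue, tissue–eDNA, eDNA–eDNA) can be had by filtering the tidy
pair table.

Trees come from classical neighbour joining (Q-criterion agglomeration) on
the differentiation matrix via `ape`, which is the community-standard
implementation; `mnpkit` adds the policy layer: `NA` entries (pairs with no
shared loci) are a hard error with advice to filter, and negative branch
lengths — an NJ artefact on non-additive distances — are clamped to zero
with the deficit moved to the sibling edge, preserving path lengths through
the parent node.

## Core alleles and the eDNA presence rule

For two labelled groups, `allele_frequencies()` computes *carrier*
frequencies: the fraction of individuals carrying an allele among those
called at the locus. Carrier frequency (not gene-copy frequency) is the
default because cross-species reference panels are often tiny (a handful of
individuals), where "9 of 10 individuals show this allele" is the robust,
directly observable quantity; a `gene_copy` mode is available for diploid
tables. `find_core_alleles()` then applies the diagnostic rule: frequency
at least 0.90 in the focal species *and* strictly below 0.10 in the other.
The boundary semantics are deliberate — 0.90/0.10 exactly fails — and loci
with no cross-species calls are excluded rather than treated as frequency
zero, since absence of data is not absence of the allele. With reference
panels this small the thresholds act on point estimates; no confidence
adjustment is applied, which is a known limitation the user should weigh
when the cross-species panel has fewer than ~10 individuals.

A water sample is scored positive (`decide_presence()`) when at least three
distinct core alleles are detected, each supported by at least 10
quality-filtered reads in at least one of two independent PCR replicates.
Both thresholds are parameters; the rule warns when run on a single
replicate, where it is weaker than designed.

## Absolute quantification

`mass_to_copies()` converts input mass to genome copies,
$\mathrm{copies} = \mathrm{ng} \times 9.12\times 10^{11} / \mathrm{bp}$,
the constant combining Avogadro's number with 660 g/mol/bp for
double-stranded DNA. `estimate_copies()` calibrates against synthetic
spike-ins added at a known input (default $5.55\times 10^4$
copies/reaction):

$$\widehat{\mathrm{copies}} = \frac{C_s}{C_d} \times \mathrm{nominal},$$

with $C_s$ the mean total read count over **all** panel loci and $C_d$ the
mean over all spike-in loci. Averaging over all panel loci — counting
undetected loci as zero — is the choice that keeps $C_s$ proportional to
template down into the dropout regime; averaging over detected loci only
would bias low-concentration estimates upward, exactly where quantification
matters most. The estimator is scale-invariant in sequencing effort
(doubling all reads changes nothing) and undefined on spike-in failure
($C_d = 0$), which is reported as an error rather than an infinite value.

`fit_calibration()` regresses $\log_{10}$ estimated on $\log_{10}$ known
copies. The log–log scale is forced by the span of a dilution series (the
reference six-point design covers 0.912 to 45,600 copies, 4.7 decades),
over which error is multiplicative; an ideal quantifier gives slope 1 and
intercept 0. `detection_probability()` is the binomial upper tail
$P(X \ge k_{\min})$, $X \sim \mathrm{Bin}(\text{panel}, p)$, computed with
the survival form of `pbinom()`; at the degraded-eDNA per-locus detection
ratio of about 0.67, a 115-marker panel detects at least one marker with
probability 1 to any printable precision — panel redundancy, not per-locus
sensitivity, is what buys reliability on fragmented DNA.

`design_spikeins()` draws random constructs under two constraints: GC
fraction within bounds (default 0.40–0.60) and no 21-mer shared with the
target reference on either strand. The default layout is three constructs
carrying 6, 7 and 7 marker-like loci (20 in total), enough redundancy for a
stable $C_d$ without inflating panel cost. Generation is rejection
sampling, deterministic per seed, and fails loudly naming the unsatisfied
constraint rather than silently relaxing it.

## The synthetic-data generator

`sim_config()` centralises every tunable. The defaults are the package's
reference conditions, chosen to emulate the data regime the toolkit
targets:

| parameter | default | what it emulates |
|---|---|---|
| `n_samples`, `n_loci` | 30, 115 | a tissue reference panel on the working marker set |
| `alleles_per_locus` | 14.6 | mean allele richness of a well-chosen MNP panel |
| `hap_len` | 6 | SNPs per marker defining the haplotype alleles |
| `depth_mean`, `depth_dispersion` | 200, 5 | negative-binomial amplicon depth |
| `p_detect_tissue` / `p_detect_edna` | 0.93 / 0.67 | per-locus detection for intact vs degraded template |
| `c0` | 10 copies | template saturation: detection scales by $1-e^{-\mathrm{copies}/c_0}$ |
| `spikein_nominal` | 5.55e4 | spike-in input per reaction |

Read counts are generated as: each (sample, locus) is detected with
probability $p_{\text{detect}} (1 - e^{-\text{copies}/c_0})$; detected loci
draw a negative-binomial depth whose mean scales with template relative to
the spike-in nominal, split symmetrically (multinomially) between the
individual's alleles; spike-in loci are sequenced at the base depth
independent of template, since they are added at fixed input. The $c_0 =
10$ default makes the ~1-copy regime sparse (a handful of detected loci)
while ~$10^2$ copies and up saturate detection — the qualitative shape a
dilution series shows in practice. eDNA samples are weighted unions of
contributor genotypes with degradation acting as a multiplier on detection
probability.

What the generator does *not* emulate: PCR chimeras and polymerase error
(alleles are emitted exactly), primer-binding-site polymorphism, fragment
length distributions (degradation is collapsed to a detection multiplier),
cross-contamination, and any spatial/hydrological structure in eDNA. Tests
passing on synthetic data therefore validate the *estimators and decision
rules under their stated models*, not robustness to these artefacts.

## Numerical and design choices

* Coordinates are 0-based half-open internally; conversion happens only at
  the VCF (1-based) and BED (0-based) boundaries, and round-trip tests pin
  both.
* Allele identity is the haplotype string over a marker's SNP positions,
  not the full amplicon sequence — robust to monomorphic-site errors and
  what the allele-diff statistic (`allele_snp_diff()`, a Hamming distance)
  operates on.
* All randomness flows through explicit seeds; simulators refuse to run
  without one. The RNG state of the caller is never disturbed.
* Degenerate inputs prefer typed emptiness or `NA` over errors where a
  downstream decision is still possible (empty count file → empty table;
  $M_2 = 0$ → `NA` precision), and errors where silence would corrupt an
  analysis (duplicate VCF positions, spike-in failure, `NA` distances fed
  to NJ).
* Validation-suite problem sizes are chosen to exercise each property at
  the smallest scale where it is meaningful: exhaustive oracles cap at 8
  samples and 12-locus binomial panels (where enumeration is exact), and
  stochastic recovery runs use 50 replicates at 30 loci with depth well
  above the calling threshold. The no-dropout regime (`p_detect = 1`) is
  used for quantifier-recovery checks because target-side dropout without
  spike-in-side dropout biases the coverage ratio by the detection
  probability — a real effect users should expect at low template, noted
  here rather than hidden.

## Known limitations

Diploidy is assumed throughout the genotype model. The core-allele rule is
only as good as the cross-species reference panel; with very small panels
the frequency thresholds act on noisy point estimates. Quantification
inherits the spike-in's assumptions (equal amplification efficiency between
target and spike-in loci) — the calibration fit is the place to check that
assumption on a real dilution series. The CLI is a thin wrapper; anything
beyond file-in/file-out composition should use the R functions directly.
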