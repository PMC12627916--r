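# mnpkit

Design, genotype and interpret **Multiple Nucleotide Polymorphism (MNP)
marker panels** — microhaplotype-style amplicons of ~180 bp carrying
several SNPs — for species monitoring from tissue and environmental DNA
(eDNA).

`mnpkit` is aimed at conservation geneticists and eDNA practitioners who
have (or want to build) a targeted multiplex-amplicon panel for one
species and need the full desk-side workflow around it:

* **Marker screening** from a multi-sample SNP matrix (VCF) with a
  sliding-window discriminative-power statistic: DP = *n*/*N*, the
  fraction of sample pairs differing at ≥ 3 SNP positions within a 120 bp
  window, with spaced greedy panel selection, primer-region composition
  checks and synthetic spike-in design.
* **Genotype calling** from per-allele amplicon read counts (≥ 10 reads
  and ≥ 5% of locus depth per retained allele; diploid calls in tissue
  mode, open allele sets in eDNA mode), plus replicate agreement
  statistics *r* = M₁/M₂ and *a* = 1 − (1 − *r*)/2.
* **Panel and population statistics**: per-marker call frequency,
  heterozygosity, allele richness and locus DP; pairwise differentiation
  rates (differing / shared loci per sample pair); neighbour-joining
  clustering with Newick export.
* **Species-diagnostic core alleles**: carrier-frequency screening
  (≥ 90% in the focal species, < 10% in the congener) and the eDNA
  positivity rule (≥ 3 core alleles, each at ≥ 10 reads in ≥ 1 of 2 PCR
  replicates).
* **Absolute quantification**: copies = (Cs/Cd) × 55,500 from the ratio
  of mean panel coverage to mean spike-in coverage, mass→copies
  conversion (× 9.12 × 10¹¹ / genome size), log–log dilution-series
  calibration and the binomial detection-probability model
  P(X ≥ k), X ~ Bin(panel, p).
* A **synthetic-data generator** producing every input above with known
  ground truth — reference contigs, SNP matrices, populations, read
  counts with depth noise and allelic dropout, eDNA mixtures, spike-in
  coverages — so the entire pipeline is testable offline.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` / `plot_*()` for figures, and
a thin `mnpkit` command-line wrapper (`inst/scripts/mnpkit`) over the same
functions.

## Worked example

Simulate a 12-sample population on a 115-marker panel, sequence it with
spike-ins, and run the core statistics:

```r
library(mnpkit)

cfg <- sim_config(seed = 42, n_samples = 12, n_loci = 115, depth_mean = 300)
pop <- simulate_population(cfg)
spk <- design_spikeins(c(ref = paste(rep("ACGGTTCA", 60), collapse = "")),
                       seed = 42)
counts <- simulate_read_counts(pop$gt, cfg, spikeins = spk)

gt <- call_genotypes(counts, mode = "tissue")
summarize_markers(gt, samples = pop$samples)
#> # A tibble: 115 × 5
#>   locus_id call_frequency het_proportion n_alleles dp_locus
#>   <chr>             <dbl>          <dbl>     <int>    <dbl>
#> 1 L001              0.667          0.875         8    0.929
#> 2 L002              0.917          1             7    0.964
#> 3 L003              0.667          1             8    0.964
#> 4 L004              0.833          0.8           6    0.956
#> # ℹ 111 more rows
```

Call frequency is the fraction of samples with a genotype call at the
locus, `dp_locus` the chance two random samples differ there — high values
mean the panel separates individuals well. Pairwise differentiation and
quantification:

```r
glance(pairwise_differentiation(gt))
#> # A tibble: 1 × 4
#>   n_samples n_pairs mean_rate mean_shared
#> 1        12      66     0.964        98.7

estimate_copies(counts, panel_loci = unique(pop$gt$locus_id), spikeins = spk)
#> # A tibble: 12 × 6
#>   sample_id    cs    cd n_target_loci_detected spikein_nominal estimated_copies
#> 1 S001       253.  313.                    104           55500           44882.
#> 2 S002       275.  341.                    108           55500           44800.
#> ...
```

Each of the 66 sample pairs shares ~99 callable loci and differs at ~96%
of them; the spike-in estimator reads back ~45,000 copies/reaction against
the 55,500-copy spike-in for these libraries (the gap reflects simulated
allelic dropout on target loci). Two closed forms used throughout:

```r
mass_to_copies(c(0.001, 50), 1e9)   # ng -> genome copies at a 1 Gb genome
#> [1] 9.12e-01 4.56e+04
detection_probability(0.6697, 115, 1)  # >=1 of 115 markers at p = 0.6697
#> [1] 1
```

See the vignette (`vignettes/mnp-marker-toolkit.Rmd`) for the models,
parameter meanings and design choices, including what the simulator does
and does not emulate.

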