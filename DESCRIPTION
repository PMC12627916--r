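Package: mnpkit
Title: Multiple Nucleotide Polymorphism Marker Panels for eDNA Species
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design, genotype and interpret Multiple Nucleotide Polymorphism
    (MNP, microhaplotype-style) marker panels for species monitoring from
    tissue and environmental DNA. Provides sliding-window marker screening
    from multi-sample SNP matrices using a pairwise discriminative-power
    statistic, MNP genotype calling from amplicon read counts, replicate
    precision and accuracy statistics, panel summaries (call frequency,
    heterozygosity, allele diversity), pairwise differentiation rates with
    neighbour-joining clustering, species-diagnostic core-allele screening,
    spike-in-calibrated absolute DNA quantification with a binomial
    detection-probability model, an eDNA presence decision rule, and a
    synthetic-data generator so the full pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
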