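test_that("config validates rates and demands a seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, p_detect_edna = 1.5), "rates")
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$n_loci, 115)
  expect_equal(cfg$spikein_nominal, 5.55e4)
})

test_that("reference/SNP simulation is deterministic and density-calibrated", {
  cfg <- sim_config(seed = 9, n_contigs = 3, contig_len = 4000,
                    snp_density = 0.02, n_samples = 6)
  a <- simulate_reference_and_snps(cfg)
  b <- simulate_reference_and_snps(cfg)
  expect_identical(a$ref, b$ref)
  expect_identical(a$snps$geno, b$snps$geno)

  # observed SNP count within 3 sigma of the Bernoulli expectation
  n_bp <- 3 * 4000
  expected <- n_bp * 0.02
  sigma <- sqrt(n_bp * 0.02 * 0.98)
  expect_lt(abs(nrow(a$snps$sites) - expected), 3 * sigma)

  # zero density -> zero sites
  cfg0 <- sim_config(seed = 9, snp_density = 0, n_contigs = 2,
                     contig_len = 500)
  expect_equal(nrow(simulate_reference_and_snps(cfg0)$snps$sites), 0L)
})

test_that("simulated VCF round-trips through the reader", {
  cfg <- sim_config(seed = 12, n_contigs = 2, contig_len = 800,
                    n_samples = 4)
  sim <- simulate_reference_and_snps(cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(sim$snps, f)
  back <- read_snp_matrix(f)
  expect_equal(back$sites, sim$snps$sites)
  expect_equal(back$geno, sim$snps$geno)
})

test_that("population simulation honours Hardy-Weinberg at p = 0.5", {
  cfg <- sim_config(seed = 20, n_samples = 500)
  freqs <- tibble::tibble(locus_id = "L001", allele = c("AAAAAA", "CCCCCC"),
                          freq = c(0.5, 0.5))
  pop <- simulate_population(cfg, freqs = freqs)
  het <- mean(pop$gt$zygosity == "HET")
  sigma <- sqrt(0.5 * 0.5 / 500)
  expect_lt(abs(het - 0.5), 3 * sigma)

  # a fixed allele gives all-HOM calls
  pop_fix <- simulate_population(
    cfg, freqs = tibble::tibble(locus_id = "L1", allele = "AAAAAA", freq = 1))
  expect_true(all(pop_fix$gt$zygosity == "HOM"))
})

test_that("allele richness tracks the configured mean", {
  cfg <- sim_config(seed = 33, n_samples = 60, n_loci = 115,
                    alleles_per_locus = 14.6)
  pop <- simulate_population(cfg)
  mean_pool <- pop$truth |>
    dplyr::count(locus_id) |>
    dplyr::pull(n) |>
    mean()
  expect_lt(abs(mean_pool - 14.6) / 14.6, 0.10)
})

test_that("read simulation responds to detection probability and template", {
  cfg <- sim_config(seed = 41, n_samples = 3, n_loci = 30, depth_mean = 300,
                    p_detect_tissue = 1)
  pop <- simulate_population(cfg)
  spk <- design_spikeins(c(r = paste(rep("AACCGGTT", 40), collapse = "")),
                         seed = 2)

  # saturation: p_detect 1 and huge template -> every locus detected
  cnt <- simulate_read_counts(pop$gt, cfg, template_copies = 1e6,
                              spikeins = spk, seed = 77)
  detected <- cnt |>
    dplyr::filter(locus_class == "target") |>
    dplyr::distinct(sample_id, locus_id)
  expect_equal(nrow(detected), 3 * 30)

  # zero template: no target reads, spike-ins still present
  cnt0 <- simulate_read_counts(pop$gt, cfg, template_copies = 0,
                               spikeins = spk, seed = 78)
  expect_equal(sum(cnt0$locus_class == "target"), 0L)
  expect_gt(sum(cnt0$locus_class == "spikein"), 0L)

  # detected-locus counts are monotone along the standard dilution series
  dil <- c(0.912, 9.12, 91.2, 912, 9120, 45600)
  mean_detected <- vapply(seq_along(dil), function(i) {
    hits <- vapply(1:8, function(r) {
      cc <- simulate_read_counts(pop$gt, cfg, template_copies = dil[i],
                                 seed = 100 * i + r)
      nrow(dplyr::distinct(cc, sample_id, locus_id))
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(mean_detected) >= 0))
})

test_that("eDNA mixtures pool contributor alleles and respect degradation", {
  cfg <- sim_config(seed = 50, n_samples = 6, n_loci = 25, depth_mean = 400,
                    p_detect_edna = 1)
  pop <- simulate_population(cfg)

  # single contributor, no degradation: called alleles equal that
  # individual's genotype at every detected locus
  cnt1 <- simulate_edna_mixture(pop$gt, contributors = pop$samples[1], cfg,
                                sample_id = "E1", seed = 7)
  got <- call_genotypes(cnt1, mode = "edna", min_reads = 1,
                        min_allele_fraction = 0)
  truth1 <- pop$gt[pop$gt$sample_id == pop$samples[1], ]
  for (k in seq_len(nrow(got))) {
    want <- truth1$alleles[[match(got$locus_id[k], truth1$locus_id)]]
    expect_equal(got$alleles[[k]], want)
  }

  # contributors with disjoint alleles produce MULTI loci
  gt2 <- make_gt(list(
    i1 = list(L1 = c("AAA", "CCC"), L2 = "GGG"),
    i2 = list(L1 = c("GGG", "TTT"), L2 = "TTT")
  ))
  cnt2 <- simulate_edna_mixture(gt2, c("i1", "i2"),
                                sim_config(seed = 3, p_detect_edna = 1,
                                           depth_mean = 1000),
                                seed = 9)
  gt_called <- call_genotypes(cnt2, mode = "edna", min_reads = 1,
                              min_allele_fraction = 0)
  expect_true(any(gt_called$zygosity == "MULTI"))

  # unnormalised weights warn; unknown contributor errors
  expect_warning(
    simulate_edna_mixture(gt2, c("i1", "i2"), sim_config(seed = 3),
                          weights = c(2, 2), seed = 4),
    "normalising")
  expect_error(
    simulate_edna_mixture(gt2, "ghost", sim_config(seed = 3), seed = 4),
    "absent")

  # degradation strictly lowers expected detections
  det_at <- function(deg) {
    mean(vapply(1:12, function(r) {
      cc <- simulate_edna_mixture(pop$gt, pop$samples[1:3], cfg,
                                  degradation = deg, seed = 300 + r)
      length(unique(cc$locus_id[cc$locus_class == "target"]))
    }, numeric(1)))
  }
  expect_gt(det_at(0), det_at(0.6))
})

test_that("full pipeline closes over one config with no external files", {
  cfg <- sim_config(seed = 70, n_contigs = 2, contig_len = 3000,
                    snp_density = 0.05, n_samples = 8, n_loci = 10,
                    depth_mean = 250)
  sim <- simulate_reference_and_snps(cfg)
  windows <- scan_windows(sim$snps, min_snps_per_pair = 2)
  panel <- select_markers(windows, dp_min = 0.1, min_spacing = 50)
  expect_gt(nrow(panel), 0)

  pop <- simulate_population(cfg, loci = panel$marker_id[seq_len(
    min(10, nrow(panel)))])
  spk <- design_spikeins(sim$ref, seed = cfg$seed)
  counts <- simulate_read_counts(pop$gt, cfg, spikeins = spk)
  gt <- call_genotypes(counts)
  s <- summarize_markers(gt, samples = pop$samples)
  expect_true(all(s$call_frequency >= 0 & s$call_frequency <= 1))
  d <- pairwise_differentiation(gt)
  expect_equal(attr(d, "n_pairs"), choose(8, 2))
  q <- estimate_copies(counts, panel_loci = unique(pop$gt$locus_id),
                       spikeins = spk)
  expect_true(all(q$estimated_copies > 0))
})
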