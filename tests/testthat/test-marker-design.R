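# The 3-sample toy below was scored by hand and by oracle_scan: pairs
# (A,B) and (A,C) differ at 3 of the 4 window positions, (B,C) at only 2,
# so with min_snps_per_pair = 3 the window discriminates 2 of 3 pairs.
toy_snps <- function() {
  geno <- matrix(c(
    # pos 10     20     30     40
    "0/0", "0/0", "0/0", "0/0",   # A
    "1/1", "1/1", "1/1", "0/0",   # B
    "0/1", "0/1", "1/1", "0/0"    # C
  ), nrow = 4, ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  snp_matrix(
    contigs = tibble::tibble(contig = "c1", length = 120L),
    sites = tibble::tibble(contig = "c1", pos = c(10L, 20L, 30L, 40L)),
    geno = geno
  )
}

test_that("window DP counts discriminated pairs over co-called pairs", {
  w <- scan_windows(toy_snps(), window_len = 120, step = 5,
                    min_snps_per_pair = 3)
  expect_equal(nrow(w), 1L)  # floor((120-120)/5)+1
  expect_equal(w$n_pairs_discriminated, 2L)
  expect_equal(w$n_pairs_total, 3L)
  expect_equal(w$dp, 2 / 3)
  # and the independent recount agrees
  o <- oracle_scan(toy_snps(), 120, 5, 3)
  expect_equal(w$dp, o$dp)
})

test_that("window positions follow floor((L - w)/step) + 1", {
  snps <- snp_matrix(
    contigs = tibble::tibble(contig = "c1", length = 200L),
    sites = tibble::tibble(contig = "c1", pos = 50L),
    geno = matrix(c("0/0", "0/1"), 1, 2, dimnames = list(NULL, c("a", "b")))
  )
  w <- scan_windows(snps, window_len = 120, step = 5)
  expect_equal(nrow(w), 17L)
  expect_equal(w$start, seq(0L, 80L, by = 5L))
  expect_equal(w$end - w$start, rep(120L, 17L))
})

test_that("identical samples give zero DP; oversized windows are skipped", {
  geno <- matrix("0/1", 3, 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  snps <- snp_matrix(
    contigs = tibble::tibble(contig = c("c1", "tiny"),
                             length = c(300L, 50L)),
    sites = tibble::tibble(contig = "c1", pos = c(10L, 20L, 30L)),
    geno = geno
  )
  expect_warning(w <- scan_windows(snps, window_len = 120, step = 10),
                 "exceeds contig")
  expect_true(all(w$dp == 0))
  expect_true(all(w$contig == "c1"))
})

test_that("scan_windows matches the brute-force oracle on random matrices", {
  withr::local_seed(42)
  for (rep in 1:5) {
    snps <- random_snps(n_samples = sample(3:8, 1), contig_len = 300,
                        n_sites = sample(5:25, 1), n_alleles = 3)
    for (mins in 1:3) {
      got <- scan_windows(snps, window_len = 100, step = 20,
                          min_snps_per_pair = mins)
      want <- oracle_scan(snps, 100, 20, mins)
      expect_equal(got$dp, want$dp)
      expect_equal(got$n_pairs_discriminated, want$n)
      expect_equal(got$n_pairs_total, want$N)
    }
  }
})

test_that("DP is invariant to sample order, monotone in min_snps_per_pair", {
  withr::local_seed(7)
  snps <- random_snps(n_samples = 6, contig_len = 250, n_sites = 20)
  perm <- sample(ncol(snps$geno))
  snps_p <- snp_matrix(snps$contigs, snps$sites,
                       snps$geno[, perm, drop = FALSE])
  w1 <- scan_windows(snps, 100, 25, 2)
  w2 <- scan_windows(snps_p, 100, 25, 2)
  expect_equal(w1$dp, w2$dp)
  w3 <- scan_windows(snps, 100, 25, 3)
  expect_true(all(w3$dp <= w1$dp))
})

test_that("marker selection thresholds, spaces and caps the panel", {
  mkw <- function(contig, start, dp) {
    tibble::tibble(contig = contig, start = start, end = start + 120L,
                   n_snps = 4L, snp_pos = list(start + c(5L, 20L, 60L, 90L)),
                   n_pairs_discriminated = 1L, n_pairs_total = 1L, dp = dp)
  }
  w <- dplyr::bind_rows(mkw("c1", 0L, 0.1), mkw("c1", 1000L, 0.25),
                        mkw("c1", 2000L, 0.3))
  attr(w, "contigs") <- tibble::tibble(contig = "c1", length = 5000L)
  panel <- select_markers(w, dp_min = 0.2, min_spacing = 0)
  expect_equal(nrow(panel), 2L)
  expect_equal(sort(panel$dp), c(0.25, 0.3))

  # two overlapping windows: the higher-DP one wins
  w2 <- dplyr::bind_rows(mkw("c1", 100L, 0.9), mkw("c1", 130L, 0.8))
  attr(w2, "contigs") <- tibble::tibble(contig = "c1", length = 5000L)
  panel2 <- select_markers(w2, dp_min = 0.2, min_spacing = 0)
  expect_equal(nrow(panel2), 1L)
  expect_equal(panel2$dp, 0.9)

  # capping returns the descending-dp prefix of the spaced set
  w3 <- dplyr::bind_rows(lapply(1:40, function(i) {
    mkw("c1", i * 500L, runif(1, 0.21, 0.99))
  }))
  attr(w3, "contigs") <- tibble::tibble(contig = "c1", length = 25000L)
  full <- select_markers(w3, min_spacing = 0)
  capped <- select_markers(w3, min_spacing = 0, panel_size = 10)
  expect_equal(nrow(capped), 10L)
  expect_equal(capped$dp, sort(full$dp, decreasing = TRUE)[1:10])
  expect_warning(empty <- select_markers(w3, dp_min = 1), "empty panel")
  expect_equal(nrow(empty), 0L)
})

test_that("selected amplicons never overlap nor violate min_spacing", {
  withr::local_seed(3)
  for (rep in 1:5) {
    snps <- random_snps(n_samples = 5, contig_len = 2000, n_sites = 150)
    w <- scan_windows(snps, window_len = 120, step = 10,
                      min_snps_per_pair = 1)
    spacing <- sample(c(0, 30, 100), 1)
    panel <- select_markers(w, dp_min = 0.05, min_spacing = spacing)
    if (nrow(panel) < 2) next
    p <- dplyr::arrange(panel, start)
    gaps <- p$start[-1] - p$end[-nrow(p)]
    expect_true(all(gaps >= spacing))
    # raising dp_min never grows the panel
    stricter <- select_markers(w, dp_min = 0.5, min_spacing = spacing)
    expect_lte(nrow(stricter), nrow(panel))
  }
})

test_that("primer-region checks flag repeats, GC and hairpins", {
  # balanced, repeat-free sequence passes
  clean <- "ACGTCAGTCCAATGGCTAGCTTGACAGTCAAGGTCTACGT"
  f <- check_candidate_region(clean)
  expect_true(f$pass)

  # (AT)x>=6 tandem repeat
  f2 <- check_candidate_region(paste0("ACGGCC", strrep("AT", 8), "GGCCGT"))
  expect_true(f2$flag_dinucleotide)

  # homopolymer run over the cap
  f3 <- check_candidate_region(paste0("ACGTGC", strrep("G", 8), "TTACGC"))
  expect_true(f3$flag_homopolymer)

  # a 12-mer plus its reverse complement triggers the hairpin proxy
  stem <- "ACGTTGCAGTCA"
  f4 <- check_candidate_region(paste0(stem, "CATCATTGG", revcomp_test(stem)))
  expect_true(f4$flag_hairpin)

  expect_true(check_candidate_region(strrep("G", 30))$flag_gc)
  expect_error(check_candidate_region("ACGTN"), "ambiguous")
})

test_that("spike-in design is deterministic and homology-screened", {
  ref <- c(ctg1 = paste(rep("ACGTTGCA", 50), collapse = ""))
  sp1 <- design_spikeins(ref, seed = 5)
  sp2 <- design_spikeins(ref, seed = 5)
  expect_identical(sp1$constructs$sequence, sp2$constructs$sequence)
  expect_equal(nrow(sp1$loci), 20L)                # 6 + 7 + 7
  expect_equal(as.integer(table(sp1$loci$construct_id)[
    sp1$constructs$construct_id]), c(6L, 7L, 7L))
  expect_equal(sp1$nominal_copies, 5.55e4)

  # every construct respects the GC bounds and shares no 21-mer with ref
  for (s in sp1$constructs$sequence) {
    gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
    expect_gte(gc, 0.40); expect_lte(gc, 0.60)
    kms <- substring(s, 1:(nchar(s) - 20), 21:nchar(s))
    ref_k <- substring(ref, 1:(nchar(ref) - 20), 21:nchar(ref))
    expect_length(intersect(kms, ref_k), 0)
  }

  # a reference containing a candidate's every 21-mer forces rejection:
  # make the screen impossible by using a tiny construct fully present in ref
  expect_error(
    design_spikeins(ref, loci_per_construct = 2, construct_len = 25,
                    k = 2, seed = 1, max_attempts = 5),
    "unsatisfiable"
  )
})
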