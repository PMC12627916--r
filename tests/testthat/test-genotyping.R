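test_that("locus calling applies read thresholds and zygosity rules", {
  # two strong alleles + noise -> HET
  het <- call_locus(c(A1 = 100, A2 = 95, A3 = 2), mode = "tissue")
  expect_equal(het$zygosity, "HET")
  expect_equal(het$alleles, c("A1", "A2"))

  hom <- call_locus(c(A1 = 100), mode = "tissue")
  expect_equal(hom$zygosity, "HOM")

  # 9 reads sits below the 10-read floor
  expect_equal(call_locus(c(A1 = 9))$zygosity, "MISSING")
  expect_equal(call_locus(c(A1 = 10))$zygosity, "HOM")

  # fraction filter: 40/1040 < 0.05 is dropped even though >= 10 reads
  frac <- call_locus(c(A1 = 1000, A2 = 40))
  expect_equal(frac$alleles, "A1")

  # eDNA mode keeps all survivors
  multi <- call_locus(c(A1 = 100, A2 = 90, A3 = 80), mode = "edna")
  expect_equal(multi$zygosity, "MULTI")
  expect_length(multi$alleles, 3)
  # tissue mode caps at the two best-supported
  t2 <- call_locus(c(A1 = 100, A2 = 90, A3 = 80), mode = "tissue")
  expect_equal(t2$alleles, c("A1", "A2"))

  expect_equal(call_locus(numeric(0))$zygosity, "MISSING")
})

test_that("locus calling is deterministic and order-invariant", {
  withr::local_seed(99)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    counts <- setNames(sample(0:150, n), paste0("h", sample(100:999, n)))
    perm <- sample(n)
    c1 <- call_locus(counts, mode = "tissue")
    c2 <- call_locus(counts[perm], mode = "tissue")
    expect_identical(c1, c2)
  }
  # exact tie at the #2/#3 slot resolves lexicographically
  tie <- call_locus(c(B = 50, C = 40, A = 40), mode = "tissue")
  expect_equal(tie$alleles, c("A", "B"))
})

test_that("table-level calling excludes spike-ins and drops missing loci", {
  counts <- validate_read_counts(tibble::tibble(
    sample_id = "s1",
    locus_id = c("L1", "L1", "L2", "SPK01"),
    allele = c("AA", "AC", "GG", "spk"),
    count = c(60L, 55L, 4L, 200L)
  ))
  gt <- call_genotypes(counts)
  expect_equal(nrow(gt), 1L)   # L2 below threshold, SPK01 excluded
  expect_equal(gt$locus_id, "L1")
  expect_equal(gt$alleles[[1]], c("AA", "AC"))
  expect_equal(gt$reads[[1]], c(60L, 55L))
})

test_that("replicate comparison implements r = M1/M2 and a = 1-(1-r)/2", {
  lib1 <- make_gt(list(
    s1 = list(L1 = "A", L2 = c("A", "B"), L3 = "C", L4 = "D"),
    s2 = list(L1 = "A", L2 = "B")
  ))
  lib2 <- make_gt(list(
    s1 = list(L1 = "A", L2 = c("A", "B"), L3 = "X"),   # L4 missing in lib2
    s2 = list(L1 = "A", L2 = "B", L9 = "Z")
  ))
  cmp <- compare_replicates(lib1, lib2)
  r1 <- cmp[cmp$sample_id == "s1", ]
  expect_equal(r1$m2, 3L)
  expect_equal(r1$m1, 2L)
  expect_equal(r1$r, 2 / 3)
  expect_equal(r1$a, 1 - (1 - 2 / 3) / 2)
  r2 <- cmp[cmp$sample_id == "s2", ]
  expect_equal(c(r2$r, r2$a), c(1, 1))

  # worked values: M1 = 8, M2 = 10 -> r = 0.8, a = 0.9; r = 0.9 -> a = 0.95
  expect_equal(1 - (1 - 0.8) / 2, 0.9)
  cmp_sub <- compare_replicates(lib1, lib2, sample_id = "s2")
  expect_equal(nrow(cmp_sub), 1L)
  expect_error(compare_replicates(lib1, lib2, sample_id = "nope"),
               "not present")
})

test_that("accuracy is affine in precision with a(0)=0.5 and a(1)=1", {
  # grid check via synthetic M1/M2 pairs
  for (m1 in 0:10) {
    lib1 <- make_gt(list(s = setNames(
      lapply(1:10, function(i) paste0("A", i)), paste0("L", 1:10))))
    calls2 <- lapply(1:10, function(i) {
      if (i <= m1) paste0("A", i) else paste0("B", i)
    })
    lib2 <- make_gt(list(s = setNames(calls2, paste0("L", 1:10))))
    cmp <- compare_replicates(lib1, lib2)
    expect_equal(cmp$r, m1 / 10)
    expect_equal(cmp$a, 0.5 + 0.5 * m1 / 10)
  }
})

test_that("zero-shared-loci replicates report NA, not an error", {
  lib1 <- make_gt(list(s1 = list(L1 = "A")))
  lib2 <- make_gt(list(s1 = list(L2 = "A")))
  cmp <- compare_replicates(lib1, lib2)
  expect_equal(cmp$m2, 0L)
  expect_true(is.na(cmp$r) && is.na(cmp$a))
})

test_that("replicate precision is 1 when simulated libraries never drop out", {
  cfg <- sim_config(seed = 21, n_samples = 4, n_loci = 25,
                    depth_mean = 400, p_detect_tissue = 1)
  pop <- simulate_population(cfg)
  c1 <- simulate_read_counts(pop$gt, cfg, seed = 101)
  c2 <- simulate_read_counts(pop$gt, cfg, seed = 202)
  cmp <- compare_replicates(call_genotypes(c1), call_genotypes(c2))
  expect_true(all(cmp$r == 1))
  expect_true(all(cmp$a == 1))
})

test_that("presence rule needs >= 3 core alleles at >= 10 reads in a replicate", {
  core <- tibble::tibble(locus_id = c("L1", "L2", "L3", "L4"),
                         allele = c("AC", "GG", "TT", "CA"))
  mkcounts <- function(reads1, reads2 = NULL) {
    k <- length(reads1)
    out <- tibble::tibble(
      sample_id = "W1", replicate = 1L,
      locus_id = paste0("L", seq_len(k)),
      allele = core$allele[seq_len(k)], count = as.integer(reads1)
    )
    if (!is.null(reads2)) {
      out <- dplyr::bind_rows(out, dplyr::mutate(
        out, replicate = 2L, count = as.integer(reads2)))
    }
    out
  }
  # three alleles with 12/40/11 reads in replicate 1 -> positive
  pos <- decide_presence(mkcounts(c(12, 40, 11), c(0, 0, 0)), core)
  expect_true(pos$positive)
  expect_equal(pos$n_core_alleles_detected, 3L)

  # two core alleles at high depth -> negative
  expect_false(decide_presence(mkcounts(c(500, 500), c(500, 500)),
                               core)$positive)
  # three core alleles all at 9 reads in every replicate -> negative
  expect_false(decide_presence(mkcounts(c(9, 9, 9), c(9, 9, 9)),
                               core)$positive)
  # support in *either* replicate counts
  either <- decide_presence(mkcounts(c(12, 9, 9), c(2, 30, 15)), core)
  expect_true(either$positive)

  expect_warning(decide_presence(mkcounts(c(12, 40, 11)), core),
                 "single replicate")
  expect_error(decide_presence(mkcounts(c(12, 40, 11), c(0, 0, 0)),
                               core[0, ]), "empty core")
})
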