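# Fixture builders and independent brute-force oracles.
# The oracles re-derive every statistic by direct enumeration, sharing no
# code with the package implementations they check.

# Build a genotype-table row set from a compact list spec:
#   list(s1 = list(L1 = c("A","B"), L2 = "A"), s2 = ...)
# A locus absent from a sample's list is MISSING.
make_gt <- function(spec) {
  rows <- list()
  for (s in names(spec)) {
    for (l in names(spec[[s]])) {
      alleles <- sort(unique(spec[[s]][[l]]))
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = s, locus_id = l,
        zygosity = c("HOM", "HET", "MULTI")[min(length(alleles), 3)],
        alleles = list(alleles)
      )
    }
  }
  validate_genotype_table(dplyr::bind_rows(rows))
}

# Random genotype table: n_samples x n_loci with missingness and a small
# allele pool per locus.
random_gt <- function(n_samples, n_loci, p_missing = 0.2, max_alleles = 4) {
  rows <- list()
  for (s in seq_len(n_samples)) {
    for (l in seq_len(n_loci)) {
      if (runif(1) < p_missing) next
      pool <- paste0("a", seq_len(max_alleles))
      alleles <- sort(unique(sample(pool, sample(1:2, 1), replace = TRUE)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sprintf("s%02d", s), locus_id = sprintf("L%02d", l),
        zygosity = c("HOM", "HET")[length(alleles)],
        alleles = list(alleles)
      )
    }
  }
  validate_genotype_table(dplyr::bind_rows(rows))
}

# Random SNP matrix on one contig.
random_snps <- function(n_samples, contig_len, n_sites, p_missing = 0.15,
                        n_alleles = 2) {
  pos <- sort(sample.int(contig_len, n_sites)) - 1L
  geno <- matrix(NA_character_, n_sites, n_samples,
                 dimnames = list(NULL, sprintf("s%02d", seq_len(n_samples))))
  for (i in seq_len(n_sites)) {
    for (j in seq_len(n_samples)) {
      if (runif(1) < p_missing) next
      a <- sort(sample(0:(n_alleles - 1), 2, replace = TRUE))
      geno[i, j] <- paste(a, collapse = "/")
    }
  }
  snp_matrix(
    contigs = tibble::tibble(contig = "c1", length = as.integer(contig_len)),
    sites = tibble::tibble(contig = "c1", pos = pos),
    geno = geno
  )
}

# Reverse complement, written independently of the package internals.
revcomp_test <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# ---- oracles ---------------------------------------------------------------

# Direct window-by-window, pair-by-pair DP recount.
oracle_scan <- function(snps, window_len, step, min_snps_per_pair) {
  samples <- snps$samples
  out <- list()
  for (ci in seq_len(nrow(snps$contigs))) {
    ctg <- snps$contigs$contig[ci]
    clen <- snps$contigs$length[ci]
    if (window_len > clen) next
    for (s in seq(0, clen - window_len, by = step)) {
      in_w <- snps$sites$contig == ctg &
        snps$sites$pos >= s & snps$sites$pos < s + window_len
      g <- snps$geno[in_w, , drop = FALSE]
      n <- 0L; N <- 0L
      for (i in seq_along(samples)) {
        for (j in seq_along(samples)) {
          if (j <= i) next
          co <- !is.na(g[, i]) & !is.na(g[, j])
          if (sum(co) >= 1) {
            N <- N + 1L
            if (sum(g[co, i] != g[co, j]) >= min_snps_per_pair) n <- n + 1L
          }
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(
        contig = ctg, start = s, n = n, N = N,
        dp = if (N > 0) n / N else 0
      )
    }
  }
  dplyr::bind_rows(out)
}

# Per-locus DP over co-called pairs, by direct enumeration.
oracle_dp_locus <- function(gt, locus) {
  g <- gt[gt$locus_id == locus, ]
  keys <- vapply(g$alleles, function(a) paste(sort(a), collapse = "|"),
                 character(1))
  n <- length(keys)
  if (n < 2) return(NA_real_)
  diff <- 0L; tot <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + 1L
      if (keys[i] != keys[j]) diff <- diff + 1L
    }
  }
  diff / tot
}

# Pairwise differentiation by direct per-pair locus walk.
oracle_pair_rate <- function(gt, s1, s2) {
  g1 <- gt[gt$sample_id == s1, ]
  g2 <- gt[gt$sample_id == s2, ]
  shared_loci <- intersect(g1$locus_id, g2$locus_id)
  if (length(shared_loci) == 0) return(list(shared = 0L, rate = NA_real_))
  differing <- 0L
  for (l in shared_loci) {
    a1 <- sort(g1$alleles[[which(g1$locus_id == l)]])
    a2 <- sort(g2$alleles[[which(g2$locus_id == l)]])
    if (!identical(a1, a2)) differing <- differing + 1L
  }
  list(shared = length(shared_loci), rate = differing / length(shared_loci))
}

# Exhaustive binomial upper tail by enumerating all 2^n detection outcomes.
oracle_binom_tail <- function(p, n, k_min) {
  total <- 0
  for (bits in 0:(2^n - 1)) {
    det <- sum(bitwAnd(bits, 2^(0:(n - 1))) > 0)
    if (det >= k_min) total <- total + p^det * (1 - p)^(n - det)
  }
  total
}
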