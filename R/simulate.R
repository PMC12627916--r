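#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with the defaults
#' used throughout the package's validation suite. The defaults emulate the
#' study conditions the toolkit is built for: ~30 tissue samples genotyped
#' on a ~115-locus MNP panel with a mean of ~14.6 alleles per locus, deep
#' amplicon coverage with negative-binomial noise, per-locus detection
#' probability around 0.93 for tissue DNA and 0.67 (with high variance
#' between samples) for degraded environmental DNA, and a three-construct
#' spike-in set (6 + 7 + 7 loci) at a nominal 5.55e4 copies per reaction.
#'
#' @param seed Mandatory RNG seed; every simulator consumes randomness only
#'   through it.
#' @param n_contigs,contig_len Reference shape (default 5 contigs x 10 kb).
#' @param snp_density Per-bp probability of a SNP site (default 0.02).
#' @param n_samples Individuals to simulate (default 30).
#' @param n_loci Panel size for population simulation (default 115).
#' @param alleles_per_locus Mean number of distinct alleles per locus
#'   (default 14.6).
#' @param hap_len Length of the haplotype strings (SNPs per marker,
#'   default 6).
#' @param dirichlet_conc Dirichlet concentration for per-locus allele
#'   frequencies (default 1 = uniform over the simplex).
#' @param depth_mean,depth_dispersion Negative-binomial total depth per
#'   detected locus (default mean 200, size 5).
#' @param p_detect_tissue,p_detect_edna Per-locus detection probabilities
#'   (defaults 0.93 and 0.67).
#' @param c0 Template-saturation constant in copies: detection probability
#'   scales by `1 - exp(-copies / c0)` (default 10, so the ~1-copy regime
#'   yields sparse detection).
#' @param spikein_nominal Spike-in copies per reaction (default 5.55e4).
#' @param edna_contributors Contributors pooled per eDNA sample (default 3).
#' @param edna_degradation Default degradation factor in `[0, 1)` applied to
#'   eDNA detection (default 0; site-specific values are passed per call).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_contigs = 5, contig_len = 10000,
                       snp_density = 0.02,
                       n_samples = 30, n_loci = 115,
                       alleles_per_locus = 14.6, hap_len = 6,
                       dirichlet_conc = 1,
                       depth_mean = 200, depth_dispersion = 5,
                       p_detect_tissue = 0.93, p_detect_edna = 0.67,
                       c0 = 10,
                       spikein_nominal = 5.55e4,
                       edna_contributors = 3, edna_degradation = 0) {
  if (missing(seed) || is.null(seed)) abort("sim_config requires a seed")
  cfg <- as.list(environment())
  rates <- c(cfg$snp_density, cfg$p_detect_tissue, cfg$p_detect_edna,
             cfg$edna_degradation)
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(cfg, class = "sim_config")
}

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' Simulate a reference and a multi-sample SNP matrix
#'
#' Draws random contigs, places SNP sites by a per-bp Bernoulli density, and
#' assigns each site a biallelic-to-tetraallelic frequency spectrum from
#' which per-sample diploid genotypes are drawn independently
#' (Hardy-Weinberg). Deterministic for a fixed config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `ref` (named character vector of contig sequences) and
#'   `snps` (an [snp_matrix()]).
#' @export
simulate_reference_and_snps <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    contigs <- tibble::tibble(
      contig = sprintf("ctg%02d", seq_len(cfg$n_contigs)),
      length = as.integer(cfg$contig_len)
    )
    ref <- setNames(
      vapply(seq_len(cfg$n_contigs), function(i) random_dna(cfg$contig_len),
             character(1)),
      contigs$contig
    )
    samples <- sprintf("S%03d", seq_len(cfg$n_samples))

    sites <- purrr::map(contigs$contig, function(ctg) {
      hit <- which(runif(cfg$contig_len) < cfg$snp_density)
      if (!length(hit)) return(NULL)
      tibble::tibble(contig = ctg, pos = hit - 1L)
    }) |> purrr::list_rbind()

    if (is.null(sites) || nrow(sites) == 0) {
      sites <- tibble::tibble(contig = character(0), pos = integer(0))
      geno <- matrix(character(0), nrow = 0, ncol = cfg$n_samples,
                     dimnames = list(NULL, samples))
      return(list(ref = ref, snps = snp_matrix(contigs, sites, geno)))
    }

    geno <- t(vapply(seq_len(nrow(sites)), function(i) {
      k <- sample(2:4, 1, prob = c(0.8, 0.15, 0.05))
      p <- rdirichlet1(k, cfg$dirichlet_conc)
      a1 <- sample.int(k, cfg$n_samples, replace = TRUE, prob = p) - 1L
      a2 <- sample.int(k, cfg$n_samples, replace = TRUE, prob = p) - 1L
      paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    }, character(cfg$n_samples)))
    if (cfg$n_samples == 1) geno <- matrix(geno, ncol = 1)
    colnames(geno) <- samples

    list(ref = ref, snps = snp_matrix(contigs, sites, geno))
  })
}

#' Simulate a population genotyped on an MNP panel
#'
#' For each locus, draws an allele pool (haplotype strings of `hap_len`
#' characters) whose size is Poisson-distributed around
#' `alleles_per_locus`, with Dirichlet frequencies; individuals then receive
#' two independent allele draws (Hardy-Weinberg). The generating frequencies
#' are returned as ground truth for recovery tests.
#'
#' @param cfg A [sim_config()]; `n_loci`, `n_samples`, `alleles_per_locus`,
#'   `hap_len`, `dirichlet_conc` and `seed` are used.
#' @param loci Optional locus-id vector overriding `cfg$n_loci`.
#' @param sample_prefix Prefix for generated sample ids (default `"S"`).
#' @param freqs Optional frequency table (`locus_id`, `allele`, `freq`)
#'   fixing the per-locus allele pools instead of drawing them — useful for
#'   simulating under known frequencies (e.g. Hardy-Weinberg checks or
#'   planted species-diagnostic alleles).
#' @return List with `gt` (genotype table), `truth` (tibble: `locus_id`,
#'   `allele`, `freq`) and `samples` (character vector).
#' @export
simulate_population <- function(cfg, loci = NULL, sample_prefix = "S",
                                freqs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  loci <- loci %||% if (!is.null(freqs)) unique(freqs$locus_id) else
    sprintf("L%03d", seq_len(cfg$n_loci))
  with_seed(cfg$seed, {
    samples <- sprintf("%s%03d", sample_prefix, seq_len(cfg$n_samples))

    truth <- if (!is.null(freqs)) {
      tibble::as_tibble(freqs)
    } else purrr::map(loci, function(lc) {
      k <- max(1L, rpois(1, cfg$alleles_per_locus))
      alleles <- unique(vapply(seq_len(k + 5L), function(i) random_dna(cfg$hap_len),
                               character(1)))[seq_len(min(k, 4^cfg$hap_len))]
      k <- length(alleles)
      tibble::tibble(locus_id = lc, allele = alleles,
                     freq = rdirichlet1(k, cfg$dirichlet_conc))
    }) |> purrr::list_rbind()

    gt <- purrr::map(loci, function(lc) {
      pool <- dplyr::filter(truth, .data$locus_id == lc)
      a1 <- sample(pool$allele, cfg$n_samples, replace = TRUE, prob = pool$freq)
      a2 <- sample(pool$allele, cfg$n_samples, replace = TRUE, prob = pool$freq)
      alle <- purrr::map2(a1, a2, function(x, y) sort(unique(c(x, y))))
      tibble::tibble(
        sample_id = samples, locus_id = lc,
        zygosity = ifelse(lengths(alle) == 1, "HOM", "HET"),
        alleles = alle
      )
    }) |> purrr::list_rbind() |>
      dplyr::arrange(.data$sample_id, .data$locus_id)

    list(gt = validate_genotype_table(gt), truth = truth, samples = samples)
  })
}

# Shared read-emission engine: given per-(sample, locus) allele pools with
# weights, a detection probability and a depth model, emit counts.
emit_reads <- function(pools, p_detect, depth_mean, depth_dispersion) {
  purrr::map(seq_len(nrow(pools)), function(i) {
    if (runif(1) > p_detect[i]) return(NULL)
    depth <- rnbinom(1, size = depth_dispersion, mu = depth_mean[i])
    if (depth == 0) return(NULL)
    alleles <- pools$alleles[[i]]
    w <- pools$weights[[i]]
    split <- as.vector(stats::rmultinom(1, depth, prob = w))
    keep <- split > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(
      sample_id = pools$sample_id[i], locus_id = pools$locus_id[i],
      allele = alleles[keep], count = as.integer(split[keep])
    )
  }) |> purrr::list_rbind()
}

spikein_counts <- function(samples, spikeins, depth_mean, depth_dispersion) {
  if (is.null(spikeins)) return(NULL)
  grid <- tidyr::expand_grid(sample_id = samples,
                             locus_id = spikeins$loci$locus_id)
  grid$count <- rnbinom(nrow(grid), size = depth_dispersion, mu = depth_mean)
  grid$count <- pmax(grid$count, 1L)  # spike-ins are added at high, uniform input
  grid$allele <- "spk"
  grid[c("sample_id", "locus_id", "allele", "count")]
}

#' Simulate amplicon read counts for genotyped individuals
#'
#' Emulates MNP-seq of tissue samples: each (sample, locus) is detected with
#' probability `p_detect * (1 - exp(-template_copies / c0))`; a detected
#' locus receives a negative-binomial total depth whose mean scales with
#' template input relative to the spike-in nominal, split symmetrically
#' between the individual's alleles. Spike-in loci, when a spike-in set is
#' given, are sequenced at the configured base depth irrespective of
#' template (they are added at fixed input), so the coverage ratio
#' Cs / Cd tracks template copies.
#'
#' @param gt Genotype table of the individuals.
#' @param cfg A [sim_config()] providing the depth model, `p_detect_tissue`,
#'   `c0` and the seed.
#' @param template_copies Template input per reaction in genome copies
#'   (default: the spike-in nominal, i.e. depth at the base mean).
#' @param p_detect Override for the per-locus detection probability
#'   (default `cfg$p_detect_tissue`).
#' @param spikeins Optional `mnp_spikein_set` whose loci are co-sequenced.
#' @param seed Override seed (default `cfg$seed`).
#' @return A read-count tibble (with `locus_class`), carrying the generating
#'   genotype table in attribute `"truth_gt"`.
#' @export
simulate_read_counts <- function(gt, cfg, template_copies = NULL,
                                 p_detect = NULL, spikeins = NULL,
                                 seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  gt <- validate_genotype_table(gt)
  template_copies <- template_copies %||% cfg$spikein_nominal
  p_detect <- p_detect %||% cfg$p_detect_tissue
  seed <- seed %||% cfg$seed

  p_eff <- p_detect * (1 - exp(-template_copies / cfg$c0))
  mu <- cfg$depth_mean * template_copies / cfg$spikein_nominal

  with_seed(seed, {
    pools <- tibble::tibble(
      sample_id = gt$sample_id, locus_id = gt$locus_id,
      alleles = gt$alleles,
      weights = purrr::map(gt$alleles, function(a) rep(1 / length(a), length(a)))
    )
    reads <- emit_reads(pools,
                        p_detect = rep(p_eff, nrow(pools)),
                        depth_mean = rep(mu, nrow(pools)),
                        depth_dispersion = cfg$depth_dispersion)
    spk <- spikein_counts(unique(gt$sample_id), spikeins,
                          cfg$depth_mean, cfg$depth_dispersion)
    out <- dplyr::bind_rows(reads, spk)
    if (is.null(out) || nrow(out) == 0) {
      out <- tibble::tibble(sample_id = character(0), locus_id = character(0),
                            allele = character(0), count = integer(0))
    }
    out <- validate_read_counts(dplyr::arrange(out, .data$sample_id,
                                               .data$locus_id, .data$allele))
    attr(out, "truth_gt") <- gt
    out
  })
}

#' Simulate an eDNA mixture
#'
#' Pools the genotypes of several contributing individuals into one
#' environmental sample. The per-locus allele pool is the weighted union of
#' the contributors' alleles; detection probability is
#' `p_detect_edna * (1 - degradation)`, so degradation acts as a
#' detection-probability multiplier (fragment-length physics is abstracted
#' away). Replicated PCR libraries can be requested for the presence rule.
#'
#' @param gt Genotype table containing the contributors.
#' @param contributors Character vector of contributing sample ids.
#' @param cfg A [sim_config()].
#' @param sample_id Id given to the pooled water sample (default `"EDNA1"`).
#' @param weights Per-contributor mixing weights; normalised (with a
#'   warning) when they do not sum to 1. Default equal.
#' @param degradation Degradation factor in `[0, 1)`
#'   (default `cfg$edna_degradation`).
#' @param spikeins Optional `mnp_spikein_set`.
#' @param n_replicates Number of independent PCR replicates (default 1).
#' @param seed Override seed (default `cfg$seed`).
#' @return Read-count tibble with a `replicate` column; attribute
#'   `"contributors"` records the ground-truth contributor list.
#' @export
simulate_edna_mixture <- function(gt, contributors, cfg, sample_id = "EDNA1",
                                  weights = NULL, degradation = NULL,
                                  spikeins = NULL, n_replicates = 1,
                                  seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(contributors) >= 1)
  gt <- validate_genotype_table(gt)
  degradation <- degradation %||% cfg$edna_degradation
  seed <- seed %||% cfg$seed
  weights <- weights %||% rep(1 / length(contributors), length(contributors))
  if (abs(sum(weights) - 1) > 1e-8) {
    warn("contributor weights do not sum to 1; normalising")
    weights <- weights / sum(weights)
  }
  missing_c <- setdiff(contributors, gt$sample_id)
  if (length(missing_c)) {
    abort(sprintf("contributor(s) absent from genotype table: %s",
                  paste(missing_c, collapse = ", ")))
  }

  wtab <- tibble::tibble(sample_id = contributors, w = weights)
  pool_tbl <- gt |>
    dplyr::filter(.data$sample_id %in% contributors) |>
    dplyr::left_join(wtab, by = "sample_id") |>
    dplyr::mutate(n_all = lengths(.data$alleles)) |>
    tidyr::unnest_longer("alleles", values_to = "allele") |>
    dplyr::group_by(.data$locus_id, .data$allele) |>
    dplyr::summarise(w = sum(.data$w / .data$n_all), .groups = "drop")
  # rebuild per-locus pools
  pools0 <- pool_tbl |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(alleles = list(.data$allele),
                     weights = list(.data$w / sum(.data$w)),
                     .groups = "drop")

  p_eff <- cfg$p_detect_edna * (1 - degradation)

  with_seed(seed, {
    out <- purrr::map(seq_len(n_replicates), function(rep_i) {
      pools <- dplyr::mutate(pools0, sample_id = sample_id)
      reads <- emit_reads(pools,
                          p_detect = rep(p_eff, nrow(pools)),
                          depth_mean = rep(cfg$depth_mean, nrow(pools)),
                          depth_dispersion = cfg$depth_dispersion)
      spk <- spikein_counts(sample_id, spikeins,
                            cfg$depth_mean, cfg$depth_dispersion)
      res <- dplyr::bind_rows(reads, spk)
      if (is.null(res) || nrow(res) == 0) {
        res <- tibble::tibble(sample_id = character(0),
                              locus_id = character(0),
                              allele = character(0), count = integer(0))
      }
      res$replicate <- rep_i
      res
    }) |> purrr::list_rbind()

    out <- validate_read_counts(out)
    attr(out, "contributors") <- contributors
    out
  })
}
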