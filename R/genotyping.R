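#' Call one locus genotype from per-allele read counts
#'
#' Applies the read-support filters and zygosity rules used throughout the
#' toolkit. Alleles supported by fewer than `min_reads` quality-filtered
#' reads, or by less than `min_allele_fraction` of the locus total, are
#' dropped. In `"tissue"` mode at most the two best-supported surviving
#' alleles are kept (ties broken by count, then lexicographically by allele
#' string, for determinism); in `"edna"` mode all survivors are kept, since
#' an environmental sample can pool templates from many individuals. A locus
#' with no surviving allele is MISSING.
#'
#' @param counts Named numeric vector of non-negative read counts, names are
#'   allele haplotype strings.
#' @param mode `"tissue"` or `"edna"`.
#' @param min_reads Minimum reads supporting a retained allele (default 10).
#' @param min_allele_fraction Minimum within-locus fraction for a retained
#'   allele (default 0.05); guards against index-hopping / carry-over noise.
#' @return A list: `alleles` (sorted character), `reads` (counts aligned with
#'   `alleles`) and `zygosity` (`"HOM"`, `"HET"`, `"MULTI"` or `"MISSING"`).
#' @examples
#' call_locus(c(ACGT = 100, ACGA = 95, ACCA = 2))
#' call_locus(c(ACGT = 9))           # below the 10-read floor: MISSING
#' @export
call_locus <- function(counts, mode = c("tissue", "edna"), min_reads = 10,
                       min_allele_fraction = 0.05) {
  mode <- match.arg(mode)
  if (length(counts) == 0 || sum(counts) == 0) {
    return(list(alleles = character(0), reads = integer(0),
                zygosity = "MISSING"))
  }
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  total <- sum(counts)
  keep <- counts >= min_reads & counts / total >= min_allele_fraction
  surv <- counts[keep]
  if (length(surv) == 0) {
    return(list(alleles = character(0), reads = integer(0),
                zygosity = "MISSING"))
  }
  # deterministic ranking: count desc, then allele string
  ord <- order(-surv, names(surv))
  surv <- surv[ord]
  if (mode == "tissue" && length(surv) > 2) surv <- surv[1:2]
  alleles <- names(surv)
  ord2 <- order(alleles)
  list(
    alleles = alleles[ord2],
    reads = as.integer(unname(surv[ord2])),
    zygosity = switch(as.character(min(length(surv), 3)),
                      "1" = "HOM", "2" = "HET", "3" = "MULTI")
  )
}

#' Call genotypes for a whole read-count table
#'
#' Applies [call_locus()] to every (sample, target-locus) group of a
#' read-count table. Spike-in loci are excluded: they carry no genotype.
#'
#' @param counts Read-count tibble (see [read_read_counts()]); a
#'   `locus_class` column, if absent, is derived from the `SPK` prefix.
#' @inheritParams call_locus
#' @return A genotype table (see [validate_genotype_table()]): one row per
#'   called (sample, locus); loci whose filters left no allele are absent
#'   (MISSING).
#' @export
call_genotypes <- function(counts, mode = c("tissue", "edna"), min_reads = 10,
                           min_allele_fraction = 0.05) {
  mode <- match.arg(mode)
  if (!"locus_class" %in% names(counts)) {
    counts <- validate_read_counts(counts)
  }
  counts <- dplyr::filter(counts, .data$locus_class == "target")
  gt <- counts |>
    dplyr::group_by(.data$sample_id, .data$locus_id) |>
    dplyr::summarise(
      call = list(call_locus(setNames(.data$count, .data$allele),
                             mode = mode, min_reads = min_reads,
                             min_allele_fraction = min_allele_fraction)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      zygosity = purrr::map_chr(.data$call, "zygosity"),
      alleles = purrr::map(.data$call, "alleles"),
      reads = purrr::map(.data$call, "reads")
    ) |>
    dplyr::filter(.data$zygosity != "MISSING") |>
    dplyr::select("sample_id", "locus_id", "zygosity", "alleles", "reads")
  validate_genotype_table(gt)
}

#' Replicate precision and accuracy
#'
#' Compares genotype calls from two independently constructed libraries of
#' the same samples. For each sample, M2 is the number of loci called
#' (non-missing) in both libraries and M1 the number of those with identical
#' allele sets. Precision is r = M1 / M2 and accuracy a = 1 - (1 - r) / 2:
#' when the two libraries disagree at a locus, at most one of them can be
#' wrong, so half of the disagreement rate is charged to each library.
#'
#' @param lib1,lib2 Genotype tables for the two libraries.
#' @param sample_id Samples to compare; default, all samples present in both
#'   tables.
#' @return A tibble with one row per sample: `sample_id`, `m1`, `m2`, `r`,
#'   `a`. When M2 = 0 both `r` and `a` are `NA`.
#' @export
compare_replicates <- function(lib1, lib2, sample_id = NULL) {
  lib1 <- validate_genotype_table(lib1)
  lib2 <- validate_genotype_table(lib2)
  common <- intersect(unique(lib1$sample_id), unique(lib2$sample_id))
  if (is.null(sample_id)) {
    sample_id <- common
  } else if (!all(sample_id %in% common)) {
    abort(sprintf("sample(s) not present in both libraries: %s",
                  paste(setdiff(sample_id, common), collapse = ", ")))
  }
  purrr::map(sample_id, function(s) {
    g1 <- dplyr::filter(lib1, .data$sample_id == s)
    g2 <- dplyr::filter(lib2, .data$sample_id == s)
    shared <- dplyr::inner_join(
      tibble::tibble(locus_id = g1$locus_id,
                     key1 = vapply(g1$alleles, allele_key, character(1))),
      tibble::tibble(locus_id = g2$locus_id,
                     key2 = vapply(g2$alleles, allele_key, character(1))),
      by = "locus_id"
    )
    m2 <- nrow(shared)
    m1 <- sum(shared$key1 == shared$key2)
    r <- if (m2 > 0) m1 / m2 else NA_real_
    tibble::tibble(sample_id = s, m1 = m1, m2 = m2, r = r,
                   a = 1 - (1 - r) / 2)
  }) |> purrr::list_rbind()
}

#' eDNA species-presence decision
#'
#' Scores a water sample positive for the focal species when at least
#' `min_core_alleles` distinct species-diagnostic core alleles are detected,
#' each supported by at least `min_reads` quality-filtered reads in at least
#' one of the PCR replicates. The rule is defined for two independent
#' replicates; running it on a single replicate triggers a warning.
#'
#' @param counts Read-count tibble for one or more water samples, with an
#'   optional `replicate` column (assumed single-replicate when absent).
#' @param core Core-allele set: a tibble with columns `locus_id` and
#'   `allele` (e.g. the `entries` element of [find_core_alleles()] output),
#'   or an `mnp_core_alleles` object.
#' @param min_core_alleles Distinct core alleles required (default 3).
#' @param min_reads Read support required, in at least one replicate
#'   (default 10).
#' @return A tibble with one row per sample: `sample_id`,
#'   `n_core_alleles_detected`, `positive`, plus the species label when
#'   `core` carries one.
#' @examples
#' core <- tibble::tibble(locus_id = c("L1", "L2", "L3"),
#'                        allele = c("AC", "GG", "TT"))
#' counts <- tibble::tibble(
#'   sample_id = "W1", replicate = 1L,
#'   locus_id = c("L1", "L2", "L3"), allele = c("AC", "GG", "TT"),
#'   count = c(12L, 40L, 11L))
#' decide_presence(counts, core)
#' @export
decide_presence <- function(counts, core, min_core_alleles = 3,
                            min_reads = 10) {
  species <- NA_character_
  if (inherits(core, "mnp_core_alleles")) {
    species <- core$species
    core <- core$entries
  }
  core <- tibble::as_tibble(core)
  if (nrow(core) == 0) abort("empty core-allele set")
  counts <- tibble::as_tibble(counts)
  if (!"replicate" %in% names(counts)) {
    warn("single replicate supplied; the decision rule is defined for two independent PCR replicates")
    counts$replicate <- 1L
  } else if (dplyr::n_distinct(counts$replicate) < 2) {
    warn("single replicate supplied; the decision rule is defined for two independent PCR replicates")
  }

  counts |>
    dplyr::semi_join(core, by = c("locus_id", "allele")) |>
    dplyr::group_by(.data$sample_id, .data$locus_id, .data$allele) |>
    dplyr::summarise(max_reads = max(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_core_alleles_detected = sum(.data$max_reads >= min_reads),
      .groups = "drop"
    ) |>
    dplyr::right_join(
      tibble::tibble(sample_id = unique(counts$sample_id)),
      by = "sample_id"
    ) |>
    dplyr::mutate(
      n_core_alleles_detected = dplyr::coalesce(.data$n_core_alleles_detected, 0L),
      species = species,
      positive = .data$n_core_alleles_detected >= min_core_alleles
    ) |>
    dplyr::arrange(.data$sample_id)
}
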