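#' Per-species carrier allele frequencies
#'
#' For each species, locus and allele: the fraction of that species'
#' individuals that carry the allele among individuals with a genotype call
#' at the locus. Carrier frequency (not gene-copy frequency) is the default
#' because diagnostic-allele screening asks "what fraction of individuals
#' would show this allele", and it remains well-defined for multi-allelic
#' environmental samples; gene-copy frequencies are available behind
#' `mode = "gene_copy"` (each individual contributes its allele dosage out
#' of two gene copies; multi-allelic calls are rejected in that mode).
#'
#' @param gt Genotype table.
#' @param labels Data frame mapping `sample_id` to `species`, or a named
#'   character vector (names = sample ids).
#' @param mode `"carrier"` (default) or `"gene_copy"`.
#' @return A tibble: `species`, `locus_id`, `allele`, `n_called` (samples of
#'   the species called at the locus), `n_carriers`, `freq`. Loci with no
#'   called sample in a species yield `freq = NA` rows only through
#'   [find_core_alleles()]'s roster join; here absent combinations are
#'   simply not listed.
#' @export
allele_frequencies <- function(gt, labels, mode = c("carrier", "gene_copy")) {
  mode <- match.arg(mode)
  gt <- validate_genotype_table(gt)
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(sample_id = names(labels),
                             species = unname(labels))
  }
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("sample_id", "species") %in% names(labels)))
  if (dplyr::n_distinct(labels$species) < 2) {
    abort("allele_frequencies needs >= 2 species labels")
  }
  unlabelled <- setdiff(unique(gt$sample_id), labels$sample_id)
  if (length(unlabelled)) {
    abort(sprintf("unlabelled sample(s): %s",
                  paste(unlabelled, collapse = ", ")))
  }
  gt <- dplyr::left_join(gt, labels, by = "sample_id")

  called <- gt |>
    dplyr::group_by(.data$species, .data$locus_id) |>
    dplyr::summarise(n_called = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop")

  if (mode == "carrier") {
    carriers <- gt |>
      tidyr::unnest_longer("alleles", values_to = "allele") |>
      dplyr::distinct(.data$species, .data$locus_id, .data$allele,
                      .data$sample_id) |>
      dplyr::count(.data$species, .data$locus_id, .data$allele,
                   name = "n_carriers")
    out <- dplyr::left_join(carriers, called,
                            by = c("species", "locus_id")) |>
      dplyr::mutate(freq = .data$n_carriers / .data$n_called)
  } else {
    if (any(lengths(gt$alleles) > 2)) {
      abort("gene_copy mode requires diploid calls (<= 2 alleles per locus)")
    }
    dosages <- gt |>
      dplyr::mutate(dose = purrr::map(.data$alleles, function(a) {
        if (length(a) == 1) setNames(2L, a) else setNames(c(1L, 1L), a)
      })) |>
      tidyr::unnest_longer("dose", indices_to = "allele") |>
      dplyr::count(.data$species, .data$locus_id, .data$allele,
                   wt = .data$dose, name = "n_copies")
    out <- dplyr::left_join(dosages, called,
                            by = c("species", "locus_id")) |>
      dplyr::mutate(n_carriers = .data$n_copies,
                    freq = .data$n_copies / (2 * .data$n_called)) |>
      dplyr::select(-"n_copies")
  }
  dplyr::arrange(out, .data$species, .data$locus_id, .data$allele) |>
    dplyr::relocate("species", "locus_id", "allele", "n_called",
                    "n_carriers", "freq")
}

#' Species-diagnostic core alleles
#'
#' A core allele for a focal species is one at >= `hi` frequency in that
#' species and strictly < `lo` frequency in the other: boundary values sit
#' on the inclusive side for `hi` and the exclusive side for `lo`, so a
#' 0.90 / 0.10 pair fails. Alleles never observed in the other species count
#' as frequency 0 there, provided the other species has called samples at
#' the locus; loci with no calls in the other species are excluded (their
#' cross-species frequency is unknowable) and reported via the
#' `n_excluded_na` field.
#'
#' @param freqs Frequency table from [allele_frequencies()] (exactly two
#'   species).
#' @param hi Focal-species frequency floor (default 0.90, inclusive).
#' @param lo Other-species frequency ceiling (default 0.10, exclusive).
#' @return A named list of `mnp_core_alleles` objects, one per species, each
#'   with fields `species`, `entries` (tibble: `locus_id`, `allele`,
#'   `freq_focal`, `freq_other`) and `n_excluded_na`.
#' @export
find_core_alleles <- function(freqs, hi = 0.90, lo = 0.10) {
  species <- sort(unique(freqs$species))
  if (length(species) != 2) {
    abort(sprintf("find_core_alleles expects exactly 2 species, got %d (run pairwise)",
                  length(species)))
  }
  called_by <- freqs |>
    dplyr::distinct(.data$species, .data$locus_id, .data$n_called)

  per_species <- lapply(species, function(sp) {
    other <- setdiff(species, sp)
    focal <- dplyr::filter(freqs, .data$species == sp)
    other_called <- dplyr::filter(called_by, .data$species == other)
    other_freqs <- freqs |>
      dplyr::filter(.data$species == other) |>
      dplyr::select("locus_id", "allele", freq_other = "freq")

    joined <- focal |>
      dplyr::left_join(other_freqs, by = c("locus_id", "allele")) |>
      dplyr::mutate(
        other_has_calls = .data$locus_id %in% other_called$locus_id,
        freq_other = dplyr::if_else(
          is.na(.data$freq_other) & .data$other_has_calls, 0, .data$freq_other)
      )
    n_na <- sum(!joined$other_has_calls & joined$freq >= hi)
    entries <- joined |>
      dplyr::filter(.data$other_has_calls,
                    .data$freq >= hi, .data$freq_other < lo) |>
      dplyr::select("locus_id", "allele", freq_focal = "freq", "freq_other")
    structure(
      list(species = sp, entries = entries, hi = hi, lo = lo,
           n_excluded_na = n_na),
      class = "mnp_core_alleles"
    )
  })
  setNames(per_species, species)
}

#' @method print mnp_core_alleles
#' @export
print.mnp_core_alleles <- function(x, ...) {
  cat(sprintf("<mnp_core_alleles> species '%s': %d core allele(s) (freq >= %g focal, < %g other)\n",
              x$species, nrow(x$entries), x$hi, x$lo))
  if (x$n_excluded_na > 0) {
    cat(sprintf("  %d candidate(s) excluded: no cross-species calls at the locus\n",
                x$n_excluded_na))
  }
  invisible(x)
}

#' SNP differences between two haplotype alleles
#'
#' Hamming distance between two equal-length haplotype strings written over
#' a marker's SNP positions. Species-diagnostic alleles at a good marker
#' typically differ at several positions (3–8 is a useful working range),
#' which is what makes them robust to single sequencing errors.
#'
#' @param a,b Haplotype strings of equal length.
#' @return Integer count of differing positions.
#' @examples
#' allele_snp_diff("AACT", "AAGT")
#' @export
allele_snp_diff <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) {
    abort(sprintf("haplotype lengths differ: %d vs %d", nchar(a), nchar(b)))
  }
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}
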