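#' Read a per-allele read-count table
#'
#' The canonical interchange format for amplicon read counts is a TSV with
#' header columns `sample_id`, `locus_id`, `allele`, `count`. Loci whose id
#' starts with `spikein_prefix` are flagged as spike-in loci; everything else
#' is a target locus.
#'
#' @param path TSV file path.
#' @param spikein_prefix Locus-id prefix identifying spike-in loci
#'   (default `"SPK"`).
#' @return A tibble with columns `sample_id`, `locus_id`, `allele`,
#'   `count` (non-negative integer) and `locus_class`
#'   (`"target"` or `"spikein"`). An empty file with a header yields an
#'   empty, correctly-typed tibble.
#' @export
read_read_counts <- function(path, spikein_prefix = "SPK") {
  counts <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      locus_id = readr::col_character(),
      allele = readr::col_character(),
      count = readr::col_double()
    )
  )
  required <- c("sample_id", "locus_id", "allele", "count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols)) {
    abort(sprintf("read-count TSV '%s' lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  validate_read_counts(counts[required], spikein_prefix = spikein_prefix)
}

#' Validate (and classify) an in-memory read-count table
#'
#' @param counts Data frame with `sample_id`, `locus_id`, `allele`, `count`.
#' @inheritParams read_read_counts
#' @return The validated tibble with a `locus_class` column.
#' @export
validate_read_counts <- function(counts, spikein_prefix = "SPK") {
  counts <- tibble::as_tibble(counts)
  if (nrow(counts)) {
    if (anyNA(counts$count) || any(counts$count < 0) ||
        any(counts$count != floor(counts$count))) {
      bad <- which(is.na(counts$count) | counts$count < 0 |
                     counts$count != floor(counts$count))[1]
      abort(sprintf("invalid read count at row %d: %s", bad,
                    as.character(counts$count[bad])))
    }
    key <- paste(counts$sample_id, counts$locus_id, counts$allele,
                 if ("replicate" %in% names(counts)) counts$replicate else "",
                 sep = "\r")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1]
      abort(sprintf("duplicate (sample, locus, allele) entry: (%s, %s, %s)",
                    counts$sample_id[i], counts$locus_id[i], counts$allele[i]))
    }
  }
  counts$count <- as.integer(counts$count)
  counts$locus_class <- ifelse(startsWith(counts$locus_id, spikein_prefix),
                               "spikein", "target")
  counts
}

#' Write a read-count table as TSV
#' @param counts Read-count tibble (the `locus_class` column, if present, is
#'   dropped: it is derived from the locus-id prefix on read).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_counts <- function(counts, path) {
  readr::write_tsv(counts[c("sample_id", "locus_id", "allele", "count")], path)
  invisible(path)
}

# ---- genotype tables -------------------------------------------------------

#' Validate a genotype table
#'
#' A genotype table is a tibble with one row per called (sample, locus):
#' `sample_id`, `locus_id`, `zygosity` (`"HOM"`, `"HET"` or `"MULTI"`),
#' `alleles` (list-column of sorted haplotype strings) and optionally `reads`
#' (list-column of supporting read counts, aligned with `alleles`). A locus
#' with no row for a sample is MISSING for that sample — an empty allele set
#' never appears.
#'
#' @param gt Data frame to validate.
#' @return The validated tibble.
#' @export
validate_genotype_table <- function(gt) {
  gt <- tibble::as_tibble(gt)
  required <- c("sample_id", "locus_id", "zygosity", "alleles")
  missing_cols <- setdiff(required, names(gt))
  if (length(missing_cols)) {
    abort(sprintf("genotype table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(gt)) {
    key <- paste(gt$sample_id, gt$locus_id, sep = "\r")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1]
      abort(sprintf("duplicate genotype row: (%s, %s)",
                    gt$sample_id[i], gt$locus_id[i]))
    }
    n_all <- lengths(gt$alleles)
    if (any(n_all == 0)) {
      abort("genotype rows must carry >= 1 allele; drop the row to mark MISSING")
    }
    expect_z <- dplyr::case_when(
      n_all == 1 ~ "HOM",
      n_all == 2 ~ "HET",
      TRUE ~ "MULTI"
    )
    if (!all(gt$zygosity == expect_z)) {
      i <- which(gt$zygosity != expect_z)[1]
      abort(sprintf("zygosity '%s' inconsistent with %d allele(s) at (%s, %s)",
                    gt$zygosity[i], n_all[i], gt$sample_id[i], gt$locus_id[i]))
    }
  }
  gt
}

#' Write / read genotype tables as TSV
#'
#' Alleles (and, when present, their supporting read counts) are serialised
#' comma-joined in a single column, giving a diffable flat file that
#' round-trips exactly.
#'
#' @param gt Genotype table (see [validate_genotype_table()]).
#' @param path File path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns the genotype tibble.
#' @export
write_genotypes <- function(gt, path) {
  gt <- validate_genotype_table(gt)
  flat <- tibble::tibble(
    sample_id = gt$sample_id,
    locus_id = gt$locus_id,
    zygosity = gt$zygosity,
    alleles = vapply(gt$alleles, paste, character(1), collapse = ","),
    reads = if ("reads" %in% names(gt)) {
      vapply(gt$reads, paste, character(1), collapse = ",")
    } else NA_character_
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    locus_id = readr::col_character(),
    zygosity = readr::col_character(),
    alleles = readr::col_character(),
    reads = readr::col_character()
  ))
  gt <- tibble::tibble(
    sample_id = flat$sample_id,
    locus_id = flat$locus_id,
    zygosity = flat$zygosity,
    alleles = strsplit(flat$alleles, ",", fixed = TRUE),
    reads = purrr::map(flat$reads, function(r) {
      if (is.na(r)) NULL else as.integer(strsplit(r, ",", fixed = TRUE)[[1]])
    })
  )
  if (all(vapply(gt$reads, is.null, logical(1)))) gt$reads <- NULL
  validate_genotype_table(gt)
}

# ---- marker panels / BED ---------------------------------------------------

#' Write a marker panel as BED
#'
#' Emits one 0-based half-open interval per marker amplicon. The name column
#' is the marker id and the score column is `round(1000 * DP)`, so a marker
#' with discriminative power 0.77 scores 770.
#'
#' @param panel Marker panel tibble from [select_markers()] (columns
#'   `marker_id`, `contig`, `start`, `end`, `dp` at minimum).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  if (is.null(panel) || nrow(panel) == 0) abort("empty marker panel")
  bed <- tibble::tibble(
    chrom = panel$contig,
    start = as.integer(panel$start),
    end = as.integer(panel$end),
    name = panel$marker_id,
    score = as.integer(round(1000 * panel$dp)),
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a marker panel from BED
#' @param path BED file written by [write_panel_bed()].
#' @return Tibble with `marker_id`, `contig`, `start`, `end`, `dp`
#'   (recovered as score / 1000).
#' @export
read_panel_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic"
  )
  tibble::tibble(
    marker_id = bed$name,
    contig = bed$chrom,
    start = bed$start,
    end = bed$end,
    dp = bed$score / 1000
  )
}

# ---- FASTA / Newick --------------------------------------------------------

#' Read / write FASTA as named character vectors
#'
#' Thin wrappers over `ape`'s FASTA support for packages of plain uppercase
#' sequences (reference contigs, spike-in constructs).
#'
#' @param path FASTA path.
#' @return `read_fasta_seqs()`: a named character vector of uppercase
#'   sequences.
#' @export
read_fasta_seqs <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(x) {
    toupper(paste(x, collapse = ""))
  }, character(1))
  setNames(seqs, names(dna))
}

#' @rdname read_fasta_seqs
#' @param seqs Named character vector of sequences.
#' @export
write_fasta_seqs <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  lines <- unlist(purrr::imap(seqs, function(s, nm) c(paste0(">", nm), s)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#' @param tree A `phylo` object (e.g. from [nj_tree()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
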