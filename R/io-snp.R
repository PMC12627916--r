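#' SNP matrix container
#'
#' An `mnp_snp_matrix` holds a multi-sample SNP matrix: the raw material for
#' MNP marker screening. It couples a contig table, a site table and an
#' unphased genotype matrix. All positions are 0-based internally; conversion
#' to and from 1-based coordinates happens only at the VCF boundary.
#'
#' @param contigs Tibble with columns `contig` (character) and `length`
#'   (integer, bp).
#' @param sites Tibble with columns `contig` and `pos` (0-based integer
#'   position), sorted and unique within contig.
#' @param geno Character matrix, one row per site (in `sites` order), one
#'   column per sample. Entries are unphased allele-index pairs such as
#'   `"0/1"` (sorted so `"1/0"` never occurs) or `NA` for a missing call.
#'
#' @return An object of class `mnp_snp_matrix`.
#' @export
snp_matrix <- function(contigs, sites, geno) {
  contigs <- tibble::as_tibble(contigs)
  sites <- tibble::as_tibble(sites)
  stopifnot(
    all(c("contig", "length") %in% names(contigs)),
    all(c("contig", "pos") %in% names(sites)),
    is.matrix(geno), nrow(geno) == nrow(sites)
  )
  if (is.null(colnames(geno))) {
    abort("`geno` must have sample ids as column names.")
  }
  dup <- duplicated(sites[c("contig", "pos")])
  if (any(dup)) {
    abort(sprintf(
      "duplicated site(s): %s",
      paste(sites$contig[dup], sites$pos[dup], sep = ":", collapse = ", ")
    ))
  }
  bad <- !sites$contig %in% contigs$contig
  if (any(bad)) {
    abort(sprintf("site contig(s) not declared: %s",
                  paste(unique(sites$contig[bad]), collapse = ", ")))
  }
  ord <- order(match(sites$contig, contigs$contig), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  structure(
    list(contigs = contigs, sites = sites, geno = geno,
         samples = colnames(geno)),
    class = "mnp_snp_matrix"
  )
}

#' @method print mnp_snp_matrix
#' @export
print.mnp_snp_matrix <- function(x, ...) {
  cat(sprintf("<mnp_snp_matrix> %d sites on %d contig(s), %d sample(s)\n",
              nrow(x$sites), nrow(x$contigs), length(x$samples)))
  cat("samples:", paste(head(x$samples, 8), collapse = ", "),
      if (length(x$samples) > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
dim.mnp_snp_matrix <- function(x) c(nrow(x$sites), length(x$samples))

normalise_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[!grepl("^[0-9]+/[0-9]+$", gt)] <- NA_character_
  ok <- !is.na(gt)
  if (any(ok)) {
    parts <- strsplit(gt[ok], "/", fixed = TRUE)
    gt[ok] <- vapply(parts, function(p) {
      paste(sort(as.integer(p)), collapse = "/")
    }, character(1))
  }
  gt
}

#' Read a multi-sample VCF into an SNP matrix
#'
#' Loads a VCF 4.x file (multiallelic records allowed) and converts it to the
#' internal 0-based representation. Genotypes are unphased: phased `0|1`
#' collapses to `0/1`, and any genotype containing a missing allele (`./.`,
#' `.`) becomes `NA` — missing is never coerced to reference. Contig lengths
#' are taken from `##contig` header lines; a contig that appears in records
#' but not in the header gets length `max(pos) + 1` with a warning.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return An [snp_matrix()] object.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "mnpkit")
#' snps <- read_snp_matrix(vcf)
#' dim(snps)
#' @export
read_snp_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("malformed VCF '%s': %s", path,
                                      conditionMessage(e)))
  )
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) abort(sprintf("VCF '%s' has no records", path))
  chrom <- fix[, "CHROM"]
  pos1 <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos1)) {
    abort(sprintf("malformed VCF '%s': non-integer POS at record %d",
                  path, which(is.na(pos1))[1]))
  }
  key <- paste(chrom, pos1)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    abort(sprintf("duplicated (contig, pos) in '%s': %s", path, d))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) abort(sprintf("VCF '%s' has no samples", path))
  geno <- matrix(normalise_gt(gt), nrow = nrow(gt),
                 dimnames = list(NULL, colnames(gt)))

  meta <- vcf@meta
  clines <- grep("^##contig=", meta, value = TRUE)
  cids <- sub('.*ID=([^,>"]+).*', "\\1", clines)
  clens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", clines)))
  contigs <- tibble::tibble(contig = cids, length = clens)
  seen <- unique(chrom)
  missing_ctg <- setdiff(seen, contigs$contig)
  if (length(missing_ctg)) {
    warn(sprintf("contig length(s) missing from VCF header, using max(pos)+1: %s",
                 paste(missing_ctg, collapse = ", ")))
    extra <- tibble::tibble(
      contig = missing_ctg,
      length = vapply(missing_ctg, function(cc) max(pos1[chrom == cc]), integer(1))
    )
    contigs <- dplyr::bind_rows(contigs, extra)
  }
  contigs <- dplyr::filter(contigs, .data$contig %in% seen | !is.na(.data$length))

  snp_matrix(
    contigs = contigs,
    sites = tibble::tibble(contig = chrom, pos = pos1 - 1L),
    geno = geno
  )
}

#' Write an SNP matrix as VCF
#'
#' Emits a minimal VCF 4.2 file (GT-only FORMAT) from the internal 0-based
#' representation; positions are converted back to 1-based. Alleles are
#' written as generic placeholders (`REF = A`, one `ALT` symbol per extra
#' allele index observed) because the SNP matrix stores allele indices, not
#' nucleotides.
#'
#' @param snps An [snp_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  stopifnot(inherits(snps, "mnp_snp_matrix"))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", snps$contigs$contig, snps$contigs$length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", snps$samples), collapse = "\t")
  )
  nt <- c("A", "C", "G", "T")
  rows <- vapply(seq_len(nrow(snps$sites)), function(i) {
    g <- snps$geno[i, ]
    idx <- suppressWarnings(as.integer(unlist(strsplit(g[!is.na(g)], "/"))))
    amax <- if (length(idx)) max(idx) else 0L
    ref <- nt[1]
    alt <- if (amax >= 1) paste(nt[1 + seq_len(amax)], collapse = ",") else "."
    gcol <- ifelse(is.na(g), "./.", g)
    paste(c(snps$sites$contig[i], snps$sites$pos[i] + 1L, ".", ref, alt, ".",
            "PASS", ".", "GT", gcol), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
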