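# Wide allele-set-key matrix (samples x loci) used by the pairwise
# statistics; NA marks a missing call.
gt_key_matrix <- function(gt, samples = NULL, loci = NULL) {
  gt <- validate_genotype_table(gt)
  samples <- samples %||% unique(gt$sample_id)
  loci <- loci %||% sort(unique(gt$locus_id))
  m <- matrix(NA_character_, length(samples), length(loci),
              dimnames = list(samples, loci))
  if (nrow(gt)) {
    keys <- vapply(gt$alleles, allele_key, character(1))
    m[cbind(match(gt$sample_id, samples), match(gt$locus_id, loci))] <- keys
  }
  m
}

#' Per-marker panel summary statistics
#'
#' For each locus of a genotype table, computes the statistics used to
#' evaluate an MNP panel: call frequency (fraction of samples with a
#' genotype call), heterozygous proportion (fraction of called samples with
#' two or more alleles — for environmental samples "heterozygous" reads as
#' "multi-allelic", since mixed-template samples have no individual-level
#' zygosity), number of distinct alleles observed, and the locus
#' discriminative power: the fraction of co-called sample pairs whose allele
#' sets differ.
#'
#' @param gt Genotype table.
#' @param samples Full sample roster; defaults to the samples present in
#'   `gt`. Supply explicitly when some samples are missing at every locus,
#'   so call frequencies use the true denominator.
#' @param loci Locus roster; defaults to loci present in `gt`. Supply the
#'   full panel to include loci that were never called (call frequency 0).
#' @return A tibble with one row per locus: `locus_id`, `call_frequency`,
#'   `het_proportion`, `n_alleles`, `dp_locus`.
#' @export
summarize_markers <- function(gt, samples = NULL, loci = NULL) {
  gt <- validate_genotype_table(gt)
  samples <- samples %||% unique(gt$sample_id)
  loci <- loci %||% sort(unique(gt$locus_id))
  n_samples <- length(samples)
  if (n_samples < 1) abort("summarize_markers needs >= 1 sample")

  keym <- gt_key_matrix(gt, samples, loci)
  per_locus_alleles <- gt |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      n_alleles = dplyr::n_distinct(unlist(.data$alleles)),
      n_het = sum(lengths(.data$alleles) >= 2),
      .groups = "drop"
    )

  purrr::map(seq_along(loci), function(j) {
    keys <- keym[, j]
    called <- !is.na(keys)
    nc <- sum(called)
    info <- dplyr::filter(per_locus_alleles, .data$locus_id == loci[j])
    # locus DP over co-called pairs
    dp <- NA_real_
    if (nc >= 2) {
      tab <- table(keys[called])
      same <- sum(choose(tab, 2))
      dp <- 1 - same / choose(nc, 2)
    }
    tibble::tibble(
      locus_id = loci[j],
      call_frequency = nc / n_samples,
      het_proportion = if (nc > 0) info$n_het / nc else NA_real_,
      n_alleles = if (nrow(info)) info$n_alleles else 0L,
      dp_locus = dp
    )
  }) |> purrr::list_rbind()
}

#' Pairwise genetic differentiation rates
#'
#' For every pair of samples, the differentiation rate is the proportion of
#' differing MNP loci relative to the loci shared (non-missing in both). Two
#' samples "differ" at a locus when their full allele sets are unequal — any
#' symmetric difference counts, so partial overlap is a difference.
#'
#' @param gt Genotype table with at least two samples.
#' @param samples Optional sample roster (ordering of the output).
#' @return An object of class `mnp_dist`: a tibble with one row per
#'   unordered pair (`sample1`, `sample2`, `shared`, `differing`, `rate`;
#'   `rate` is `NA` when no locus is shared), with the pair count in
#'   attribute `"n_pairs"`. Use [as_dist_matrix()] or `as.dist()` for the
#'   square form.
#' @export
pairwise_differentiation <- function(gt, samples = NULL) {
  keym <- gt_key_matrix(gt, samples)
  samples <- rownames(keym)
  if (length(samples) < 2) abort("pairwise_differentiation needs >= 2 samples")
  pr <- utils::combn(length(samples), 2)
  res <- purrr::map(seq_len(ncol(pr)), function(p) {
    i <- pr[1, p]; j <- pr[2, p]
    co <- !is.na(keym[i, ]) & !is.na(keym[j, ])
    shared <- sum(co)
    differing <- sum(keym[i, co] != keym[j, co])
    tibble::tibble(
      sample1 = samples[i], sample2 = samples[j],
      shared = shared, differing = differing,
      rate = if (shared > 0) differing / shared else NA_real_
    )
  }) |> purrr::list_rbind()
  structure(res, class = c("mnp_dist", class(res)),
            n_pairs = ncol(pr), samples = samples)
}

#' Square matrix / `dist` forms of a pairwise differentiation result
#' @param d An `mnp_dist` from [pairwise_differentiation()].
#' @return `as_dist_matrix()`: a symmetric numeric matrix with zero
#'   diagonal; `NA` where a pair shares no locus.
#' @export
as_dist_matrix <- function(d) {
  stopifnot(inherits(d, "mnp_dist"))
  samples <- attr(d, "samples")
  m <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  diag(m) <- 0
  i <- match(d$sample1, samples)
  j <- match(d$sample2, samples)
  m[cbind(i, j)] <- d$rate
  m[cbind(j, i)] <- d$rate
  m
}

#' @export
as.dist.mnp_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(as_dist_matrix(m), diag = diag, upper = upper)
}

#' Neighbour-joining tree from a differentiation matrix
#'
#' Builds an unrooted tree from pairwise differentiation rates with the
#' standard agglomerative neighbour-joining (Q-criterion) algorithm. NJ can
#' produce negative branch lengths on noisy (non-additive) distances; these
#' are clamped to zero and the deficit moved onto the sibling edge at the
#' same node, preserving the path lengths through the parent.
#'
#' @param d An `mnp_dist` object, a `dist`, or a symmetric numeric matrix.
#' @return An `ape::phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "mnp_dist")) d <- as_dist_matrix(d)
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) < 3) abort("nj_tree needs >= 3 samples")
  if (anyNA(d)) {
    abort(paste("differentiation matrix contains NA (pairs sharing no locus);",
                "filter low-call samples or loci before tree building"))
  }
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

# Clamp negative edges to 0, moving the deficit to the sibling edge attached
# to the same parent node so distances through the parent are preserved.
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
    if (all(tree$edge.length >= 0)) break
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
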