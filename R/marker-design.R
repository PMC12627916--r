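#' Sliding-window discriminative-power scan
#'
#' Screens an SNP matrix for candidate MNP marker regions by sliding a window
#' along each contig and scoring its discriminative power (DP). For each
#' window, a sample pair is *discriminated* when the two samples' unphased
#' genotypes differ at at least `min_snps_per_pair` SNP positions inside the
#' window; positions where either sample is missing are skipped for that
#' pair. DP = n / N where n is the number of discriminated pairs and N the
#' number of pairs with at least one co-called position in the window (pairs
#' sharing no data count toward neither). A window with N = 0 has DP 0.
#'
#' @param snps An [snp_matrix()].
#' @param window_len Window length in bp (default 120).
#' @param step Window increment in bp (default 5).
#' @param min_snps_per_pair Minimum number of differing SNP positions for a
#'   pair to count as discriminated (default 3).
#' @return A tibble with one row per window: `contig`, `start`, `end`
#'   (0-based half-open), `n_snps`, `snp_pos` (list-column of 0-based
#'   positions), `n_pairs_discriminated`, `n_pairs_total` and `dp`. Contig
#'   lengths are attached as the `"contigs"` attribute for downstream
#'   selection.
#' @examples
#' sim <- simulate_reference_and_snps(sim_config(seed = 1, n_contigs = 1,
#'                                               contig_len = 600))
#' windows <- scan_windows(sim$snps)
#' dplyr::arrange(windows, dplyr::desc(dp))
#' @export
scan_windows <- function(snps, window_len = 120, step = 5,
                         min_snps_per_pair = 3) {
  stopifnot(inherits(snps, "mnp_snp_matrix"))
  samples <- snps$samples
  if (length(samples) < 2) abort("scan_windows needs >= 2 samples")

  pair_idx <- utils::combn(length(samples), 2)
  n_pairs <- ncol(pair_idx)

  out <- purrr::map(seq_len(nrow(snps$contigs)), function(ci) {
    ctg <- snps$contigs$contig[ci]
    clen <- snps$contigs$length[ci]
    if (window_len > clen) {
      warn(sprintf("window length %d exceeds contig '%s' length %d; skipped",
                   window_len, ctg, clen))
      return(NULL)
    }
    starts <- seq(0L, clen - window_len, by = step)
    on_ctg <- which(snps$sites$contig == ctg)
    pos <- snps$sites$pos[on_ctg]
    g <- snps$geno[on_ctg, , drop = FALSE]

    m <- length(pos)
    if (m > 0) {
      # pair x site indicators: co-called, and co-called & different
      called <- !is.na(g)
      co <- called[, pair_idx[1, ], drop = FALSE] &
        called[, pair_idx[2, ], drop = FALSE]
      df <- co & (g[, pair_idx[1, ], drop = FALSE] !=
                    g[, pair_idx[2, ], drop = FALSE])
      # cumulative over sites (rows) for O(1) window sums
      cum_co <- apply(co, 2, cumsum)
      cum_df <- apply(df, 2, cumsum)
      cum_co <- rbind(0L, matrix(cum_co, nrow = m))
      cum_df <- rbind(0L, matrix(cum_df, nrow = m))
    }

    purrr::map(starts, function(s) {
      e <- s + window_len
      if (m > 0) {
        lo <- findInterval(s - 1L, pos) + 1L   # first site with pos >= s
        hi <- findInterval(e - 1L, pos)        # last site with pos < e
      } else {
        lo <- 1L; hi <- 0L
      }
      if (hi >= lo) {
        w_co <- cum_co[hi + 1L, ] - cum_co[lo, ]
        w_df <- cum_df[hi + 1L, ] - cum_df[lo, ]
        nn <- sum(w_df >= min_snps_per_pair & w_co > 0)
        NN <- sum(w_co > 0)
        wpos <- pos[lo:hi]
      } else {
        nn <- 0L; NN <- 0L; wpos <- integer(0)
      }
      tibble::tibble(
        contig = ctg, start = s, end = e,
        n_snps = length(wpos), snp_pos = list(wpos),
        n_pairs_discriminated = nn, n_pairs_total = NN,
        dp = if (NN > 0) nn / NN else 0
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  attr(out, "contigs") <- snps$contigs
  out
}

#' Select a spaced marker panel from window statistics
#'
#' Filters windows to those with DP above `dp_min`, then greedily accepts
#' windows in descending DP order (ties broken by contig id then start),
#' skipping any window whose amplicon would overlap or come within
#' `min_spacing` bp of an already accepted marker. Each accepted marker's
#' amplicon is centred on its window and clipped to the contig.
#'
#' @param windows Output of [scan_windows()].
#' @param dp_min DP threshold; windows with `dp <= dp_min` are discarded
#'   (default 0.2).
#' @param amplicon_len Amplicon length in bp (default 180, the nominal MNP
#'   marker length; sensible bounds are roughly 160–200 bp).
#' @param min_spacing Minimum gap in bp between amplicons of accepted
#'   markers. Default: total contig length divided by `panel_size` when a
#'   finite panel size is requested, otherwise 0 (non-overlap only).
#' @param panel_size Maximum number of markers to retain (default `Inf`,
#'   i.e. all that satisfy the constraints).
#' @return A tibble of markers: `marker_id`, `contig`, `start`, `end`
#'   (amplicon, 0-based half-open), `window_start`, `n_snps`, `snp_pos`,
#'   `dp`. Empty (with a warning) when no window passes the DP filter.
#' @export
select_markers <- function(windows, dp_min = 0.2, amplicon_len = 180,
                           min_spacing = NULL, panel_size = Inf) {
  contigs <- attr(windows, "contigs")
  cand <- dplyr::filter(windows, .data$dp > dp_min)
  if (nrow(cand) == 0) {
    warn("no window exceeds dp_min; returning empty panel")
    return(tibble::tibble(
      marker_id = character(0), contig = character(0),
      start = integer(0), end = integer(0), window_start = integer(0),
      n_snps = integer(0), snp_pos = list(), dp = double(0)
    ))
  }
  if (is.null(min_spacing)) {
    min_spacing <- if (is.finite(panel_size) && !is.null(contigs)) {
      floor(sum(contigs$length) / panel_size)
    } else 0
  }
  cand <- dplyr::arrange(cand, dplyr::desc(.data$dp), .data$contig, .data$start)

  clen <- if (!is.null(contigs)) setNames(contigs$length, contigs$contig) else NULL
  acc_contig <- character(0)
  acc_start <- integer(0)
  acc_end <- integer(0)
  keep <- integer(0)
  amp <- matrix(NA_integer_, nrow = nrow(cand), ncol = 2)

  for (i in seq_len(nrow(cand))) {
    if (length(keep) >= panel_size) break
    ctr <- cand$start[i] + (cand$end[i] - cand$start[i]) %/% 2
    a0 <- ctr - amplicon_len %/% 2
    L <- if (!is.null(clen)) unname(clen[cand$contig[i]]) else NA_integer_
    if (!is.na(L)) {
      if (L < amplicon_len) next  # contig shorter than the amplicon
      a0 <- max(0L, min(a0, L - amplicon_len))
    } else {
      a0 <- max(0L, a0)
    }
    a1 <- a0 + amplicon_len
    same <- acc_contig == cand$contig[i]
    clash <- any(same & !(a0 >= acc_end + min_spacing |
                            a1 + min_spacing <= acc_start))
    if (!clash) {
      keep <- c(keep, i)
      acc_contig <- c(acc_contig, cand$contig[i])
      acc_start <- c(acc_start, a0)
      acc_end <- c(acc_end, a1)
      amp[i, ] <- c(a0, a1)
    }
  }

  sel <- cand[keep, , drop = FALSE]
  panel <- tibble::tibble(
    marker_id = sprintf("MNP%03d", seq_along(keep)),
    contig = sel$contig,
    start = amp[keep, 1],
    end = amp[keep, 2],
    window_start = sel$start,
    n_snps = sel$n_snps,
    snp_pos = sel$snp_pos,
    dp = sel$dp
  )
  attr(panel, "contigs") <- contigs
  panel
}

#' Primer-region constraint checks
#'
#' Flags sequence features that make a candidate region hostile to primer
#' design: GC content outside bounds, long homopolymer runs, long
#' dinucleotide repeats, and a hairpin proxy — the presence of a k-mer and
#' its reverse complement in the same sequence (a potential self-annealing
#' stem). This is a composition screen, not thermodynamic primer design.
#'
#' @param sequence A single A/C/G/T string.
#' @param gc_bounds Length-2 numeric, allowed GC fraction range
#'   (default `c(0.40, 0.60)`).
#' @param max_homopolymer Longest tolerated single-base run (default 5).
#' @param max_dinucleotide_repeat Most tolerated tandem repeat units of a
#'   2-mer (default 5; e.g. `(AT)x6` is flagged).
#' @param hairpin_stem Stem length for the reverse-complement self-match
#'   proxy (default 12).
#' @return One-row tibble: `gc`, `flag_gc`, `flag_homopolymer`,
#'   `flag_dinucleotide`, `flag_hairpin`, `pass` (TRUE when no flag set).
#' @export
check_candidate_region <- function(sequence, gc_bounds = c(0.40, 0.60),
                                   max_homopolymer = 5,
                                   max_dinucleotide_repeat = 5,
                                   hairpin_stem = 12) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    abort("sequence contains ambiguous (non-ACGT) bases")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  gc <- mean(chars %in% c("G", "C"))

  runs <- rle(chars)
  max_run <- max(runs$lengths)

  # longest tandem repeat of any dinucleotide unit
  max_units <- 0L
  m <- gregexpr("([ACGT]{2})\\1+", sequence, perl = TRUE)[[1]]
  if (m[1] != -1) {
    max_units <- max(attr(m, "match.length") %/% 2L)
  }

  hair <- FALSE
  kms <- unique(seq_kmers(sequence, hairpin_stem))
  if (length(kms)) hair <- any(revcomp(kms) %in% kms)

  flags <- tibble::tibble(
    gc = gc,
    flag_gc = gc < gc_bounds[1] | gc > gc_bounds[2],
    flag_homopolymer = max_run > max_homopolymer,
    flag_dinucleotide = max_units > max_dinucleotide_repeat,
    flag_hairpin = hair
  )
  flags$pass <- !(flags$flag_gc | flags$flag_homopolymer |
                    flags$flag_dinucleotide | flags$flag_hairpin)
  flags
}

#' Design synthetic spike-in constructs
#'
#' Draws random DNA constructs to serve as external quantification standards,
#' enforcing balanced GC content and no shared k-mer with the target
#' reference (homology screen on both strands). Each construct carries a
#' configured number of marker-like loci laid out end to end; the default
#' layout of 6 + 7 + 7 loci gives a 20-locus spike-in set. Generation is
#' deterministic for a fixed seed.
#'
#' @param reference Named character vector of reference sequences, or a path
#'   to a FASTA file.
#' @param loci_per_construct Integer vector, loci carried by each construct
#'   (default `c(6, 7, 7)`).
#' @param locus_len Length of each spike-in locus in bp (default 180).
#' @param construct_len Construct lengths; default allots `locus_len + 20` bp
#'   per locus.
#' @param gc_bounds Allowed GC fraction per construct (default
#'   `c(0.40, 0.60)`).
#' @param k Homology-screen k-mer size (default 21).
#' @param seed Mandatory RNG seed.
#' @param nominal_copies Copies per reaction the constructs are spiked at
#'   (default `5.55e4`).
#' @param max_attempts Attempts per construct before giving up (default 200).
#' @return An object of class `mnp_spikein_set`: list with `constructs`
#'   (tibble: `construct_id`, `sequence`, `gc`), `loci` (tibble:
#'   `locus_id`, `construct_id`, `start`, `end`) and `nominal_copies`.
#'   Spike-in locus ids take the `SPK` prefix recognised by
#'   [read_read_counts()].
#' @export
design_spikeins <- function(reference, loci_per_construct = c(6, 7, 7),
                            locus_len = 180, construct_len = NULL,
                            gc_bounds = c(0.40, 0.60), k = 21, seed,
                            nominal_copies = 5.55e4, max_attempts = 200) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_fasta_seqs(reference)
  }
  if (!length(reference)) abort("reference is empty")
  if (is.null(construct_len)) {
    construct_len <- loci_per_construct * (locus_len + 20L)
  }
  construct_len <- rep_len(construct_len, length(loci_per_construct))

  ref_kmers <- unique(unlist(lapply(reference, seq_kmers, k = k)))
  ref_kmers <- unique(c(ref_kmers, revcomp(ref_kmers)))

  with_seed(seed, {
    constructs <- purrr::map(seq_along(loci_per_construct), function(i) {
      reason <- "no attempt made"
      for (a in seq_len(max_attempts)) {
        cand <- random_dna(construct_len[i])
        gc <- gc_fraction(cand)
        if (gc < gc_bounds[1] || gc > gc_bounds[2]) {
          reason <- sprintf("GC content out of [%g, %g]", gc_bounds[1], gc_bounds[2])
          next
        }
        if (any(seq_kmers(cand, k) %in% ref_kmers)) {
          reason <- sprintf("shared %d-mer with the reference", k)
          next
        }
        return(tibble::tibble(
          construct_id = sprintf("spikein_%d", i), sequence = cand, gc = gc
        ))
      }
      abort(sprintf("spike-in construct %d: constraint unsatisfiable after %d attempts (%s)",
                    i, max_attempts, reason))
    }) |> purrr::list_rbind()

    loci <- purrr::map(seq_along(loci_per_construct), function(i) {
      nl <- loci_per_construct[i]
      pitch <- construct_len[i] %/% nl
      start <- (seq_len(nl) - 1L) * pitch
      tibble::tibble(
        construct_id = constructs$construct_id[i],
        start = start, end = start + locus_len
      )
    }) |> purrr::list_rbind()
    loci$locus_id <- sprintf("SPK%02d", seq_len(nrow(loci)))
    loci <- loci[c("locus_id", "construct_id", "start", "end")]

    structure(
      list(constructs = constructs, loci = loci,
           nominal_copies = nominal_copies),
      class = "mnp_spikein_set"
    )
  })
}

#' @method print mnp_spikein_set
#' @export
print.mnp_spikein_set <- function(x, ...) {
  cat(sprintf(
    "<mnp_spikein_set> %d construct(s), %d loci, nominal %s copies/reaction\n",
    nrow(x$constructs), nrow(x$loci), format(x$nominal_copies, big.mark = ",")
  ))
  invisible(x)
}
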