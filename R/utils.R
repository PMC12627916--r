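# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) abort("a seed is required (no silent nondeterminism)")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

gc_fraction <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

# All k-mers of a sequence (forward strand), as a character vector.
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Canonical allele-set key used wherever allele sets are compared.
allele_key <- function(alleles) {
  paste(sort(alleles), collapse = "|")
}
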