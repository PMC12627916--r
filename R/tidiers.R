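# broom-style methods for the package's fitted/derived objects.

#' Tidy a calibration fit
#'
#' @param x An `mnp_calibration` from [fit_calibration()].
#' @param ... Unused.
#' @return One row per coefficient of the log10-log10 regression:
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.mnp_calibration <- function(x, ...) {
  # a perfect (zero-residual) fit makes summary.lm warn about unreliable
  # inference; the coefficient table itself is still what we want
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.mnp_calibration
#' @return `glance()`: a one-row tibble with `slope`, `intercept`,
#'   `r.squared`, `sigma`, `n`.
#' @export
glance.mnp_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    sigma = suppressWarnings(summary(x$fit))$sigma,
    n = nrow(x$points)
  )
}

#' Tidy / summarise a pairwise differentiation result
#'
#' @param x An `mnp_dist` from [pairwise_differentiation()].
#' @param ... Unused.
#' @return `tidy()`: the per-pair tibble. `glance()`: one row with
#'   `n_samples`, `n_pairs`, `mean_rate` (unweighted over pairs with shared
#'   loci), `mean_shared`.
#' @export
tidy.mnp_dist <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.mnp_dist
#' @export
glance.mnp_dist <- function(x, ...) {
  tibble::tibble(
    n_samples = length(attr(x, "samples")),
    n_pairs = attr(x, "n_pairs"),
    mean_rate = mean(x$rate, na.rm = TRUE),
    mean_shared = mean(x$shared)
  )
}

#' Tidy a core-allele set
#' @param x An `mnp_core_alleles` object.
#' @param ... Unused.
#' @return The entries tibble with a `species` column prepended.
#' @export
tidy.mnp_core_alleles <- function(x, ...) {
  dplyr::mutate(x$entries, species = x$species, .before = 1)
}
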