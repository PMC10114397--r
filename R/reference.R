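#' Reference statistics of the motivating 46-child training cohort
#'
#' Published summary statistics of the anisometropic-amblyopia cohort (n = 46
#' children treated with dichoptic push-pull training for 6-12 months) whose
#' difference-score structure this package's defaults emulate. All quantities
#' describe post-minus-pre difference scores of the four coupled indicators,
#' ordered `d_va`, `d_brbp`, `d_hpep`, `d_sa`.
#'
#' `reference_cohort()` returns a list with:
#' * `means`, `sds` — per-indicator mean and sample SD of the differences,
#' * `correlation` — the 4x4 Pearson correlation matrix of the differences,
#' * `weights` — the CRITIC weights reported for that cohort,
#' * `n` — the cohort size (46).
#'
#' The reported weights are shipped as a reference constant only: they were
#' derived from the raw per-subject data, which is not public, and are not
#' recoverable from the two-decimal summary statistics via the CRITIC chain
#' (see the package vignette). [run_critic()] therefore never uses them
#' implicitly; pass them explicitly where a fixed weighting is wanted.
#'
#' @return A named list (see Details).
#' @examples
#' reference_cohort()$weights
#' @export
reference_cohort <- function() {
  corr <- matrix(
    c( 1.0000,  0.1004, -0.1891, -0.1906,
       0.1004,  1.0000,  0.0722, -0.1537,
      -0.1891,  0.0722,  1.0000,  0.0408,
      -0.1906, -0.1537,  0.0408,  1.0000),
    nrow = 4, byrow = TRUE,
    dimnames = list(indicator_names, indicator_names)
  )
  list(
    means = stats::setNames(c(-0.38, -1.48, -0.60, 0.85), indicator_names),
    sds = stats::setNames(c(0.26, 2.02, 1.31, 1.26), indicator_names),
    correlation = corr,
    weights = stats::setNames(c(0.2154, 0.2575, 0.1724, 0.3547), indicator_names),
    n = 46L
  )
}
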