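#' Z-score standardize indicator columns
#'
#' Column-wise Z-score transform `(x - mean) / sd` with the sample (n - 1)
#' standard deviation; every output column has mean 0 and sample SD 1.
#'
#' @param x Numeric matrix or data frame of per-subject indicator values
#'   (m >= 3 rows). A `subject_id` column is used as row names.
#' @return A numeric matrix of the same shape.
#' @examples
#' standardize_columns(cbind(a = c(1, 2, 3), b = c(10, 20, 40)))
#' @export
standardize_columns <- function(x) {
  x <- as_indicator_matrix(x)
  check_column_variance(x)
  out <- scale(x)  # base scale() centres and divides by sample SD
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Variation coefficients of indicators
#'
#' The contrast-intensity term of CRITIC. Two conventions are supported:
#'
#' * `"eq"` — the textbook coefficient of variation `v = sd / mean`;
#' * `"table"` — the reciprocal `v = mean / sd` (the convention under which
#'   the reference cohort's published variation-coefficient column is exactly
#'   reproduced from its printed means and SDs, e.g. -0.38 / 0.26 = -1.46).
#'
#' The two are reciprocal wherever both are finite and nonzero. The default
#' is `"table"` for fidelity to the published parameter table; see the
#' vignette for the discrepancy discussion.
#'
#' @param means,sds Numeric vectors of column means and sample SDs.
#' @param convention `"table"` (mean/sd, default) or `"eq"` (sd/mean).
#' @return Numeric vector of variation coefficients.
#' @examples
#' variation_coefficients(-0.38, 0.26, "table")  # -1.4615...
#' variation_coefficients(-0.38, 0.26, "eq")     # -0.6842...
#' @export
variation_coefficients <- function(means, sds, convention = c("table", "eq")) {
  convention <- match.arg(convention)
  if (length(means) != length(sds)) {
    rlang::abort("`means` and `sds` must have equal length.",
                 class = "vc_shape_error")
  }
  den <- if (convention == "table") sds else means
  if (any(den == 0)) {
    rlang::abort(
      sprintf("Zero denominator under the '%s' convention.", convention),
      class = "vc_degenerate_error"
    )
  }
  if (convention == "table") means / sds else sds / means
}

#' Independence (conflict) coefficients from a correlation matrix
#'
#' For each indicator j, `eta_j = sum_k (1 - |r_kj|)` over all indicators k
#' including k = j (whose term is 0). An indicator uncorrelated with all
#' others attains the maximum n - 1; one perfectly correlated with all
#' others scores 0. This is CRITIC's conflict term: it rewards indicators
#' carrying information the others do not.
#'
#' @param r Correlation matrix (symmetric, unit diagonal, entries in
#'   \[-1, 1\]).
#' @return Named numeric vector of independence coefficients in
#'   \[0, n - 1\].
#' @examples
#' independence_coefficients(diag(4))  # all 3
#' @export
independence_coefficients <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r) ||
      any(abs(r) > 1 + 1e-8) || any(abs(diag(r) - 1) > 1e-8) ||
      any(abs(r - t(r)) > 1e-8)) {
    rlang::abort("`r` must be a symmetric correlation matrix with unit diagonal.",
                 class = "vc_domain_error")
  }
  colSums(1 - abs(r))
}

#' Information volume of each indicator
#'
#' Combines contrast intensity and conflict: `D_j = f(v_j) * eta_j`. Under
#' the default `magnitude = "abs"` policy `f` is the absolute value, so that
#' indicators whose variation coefficient is negative (a negative mean
#' difference, as for logMAR acuity improvements) still contribute positive
#' information and yield non-negative weights. `magnitude = "signed"` keeps
#' the literal signed product for sensitivity experiments.
#'
#' @param v Numeric vector of variation coefficients.
#' @param eta Numeric vector of independence coefficients, same length.
#' @param magnitude `"abs"` (default) or `"signed"`.
#' @return Numeric vector of information volumes.
#' @export
information_volume <- function(v, eta, magnitude = c("abs", "signed")) {
  magnitude <- match.arg(magnitude)
  if (length(v) != length(eta)) {
    rlang::abort("`v` and `eta` must have equal length.",
                 class = "vc_shape_error")
  }
  if (magnitude == "abs") abs(v) * eta else v * eta
}

#' Normalize information volumes to CRITIC weights
#'
#' `w_j = D_j / sum(D)`; the weights sum to 1 and are non-negative whenever
#' all information volumes are (guaranteed under the `"abs"` magnitude
#' policy).
#'
#' @param d Numeric vector of information volumes with a positive sum.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' critic_weights(c(1, 1, 2))
#' @export
critic_weights <- function(d) {
  if (all(d == 0)) {
    rlang::abort("All information volumes are zero: no discriminating information.",
                 class = "vc_degenerate_error")
  }
  if (sum(d) <= 0) {
    rlang::abort("Information volumes must have a positive sum.",
                 class = "vc_degenerate_error")
  }
  d / sum(d)
}

#' Fit CRITIC objective weights to a difference-score matrix
#'
#' Runs the full CRITIC (Criteria Importance Through Inter-criteria
#' Correlation) chain on a subjects-by-indicators matrix of difference
#' scores: Z-score standardization, per-column means/SDs and variation
#' coefficients, the Pearson correlation matrix, independence (conflict)
#' coefficients, information volumes, and normalized weights. Every
#' intermediate is retained on the returned object for reporting.
#'
#' @param x Numeric matrix or data frame (m >= 3 subjects, n >= 2
#'   indicators); a `subject_id` column is used for row names.
#' @param convention Variation-coefficient convention, see
#'   [variation_coefficients()].
#' @param magnitude Information-volume magnitude policy, see
#'   [information_volume()].
#' @return An object of class `critic_fit`: a list with `standardized`,
#'   `summaries` (tibble of mean/sd/variation coefficient per indicator),
#'   `correlation`, `independence`, `information`, `weights`, `convention`,
#'   `magnitude`, `m`, `n`. Supports [tidy()], [glance()], `autoplot()` and
#'   `print()`.
#' @examples
#' fit <- run_critic(simulate_differences(cohort_spec(n = 46, seed = 7)))
#' tidy(fit)
#' @export
run_critic <- function(x, convention = c("table", "eq"),
                       magnitude = c("abs", "signed")) {
  convention <- match.arg(convention)
  magnitude <- match.arg(magnitude)
  x <- as_indicator_matrix(x)
  check_column_variance(x)
  std <- standardize_columns(x)
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  v <- variation_coefficients(means, sds, convention)
  # correlation on the standardized matrix; equals raw-data Pearson r
  r <- correlation_matrix(std)
  eta <- independence_coefficients(r)
  d <- information_volume(v, eta, magnitude)
  w <- critic_weights(d)
  structure(
    list(
      standardized = std,
      summaries = tibble::tibble(
        indicator = colnames(x),
        mean = unname(means),
        sd = unname(sds),
        variation_coefficient = unname(v)
      ),
      correlation = r,
      independence = eta,
      information = d,
      weights = w,
      convention = convention,
      magnitude = magnitude,
      m = nrow(x),
      n = ncol(x)
    ),
    class = "critic_fit"
  )
}

#' @export
print.critic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("CRITIC weighting of %d indicators over %d subjects\n",
              x$n, x$m))
  cat(sprintf("(variation-coefficient convention: %s; magnitude policy: %s)\n\n",
              x$convention, x$magnitude))
  print(as.data.frame(tidy(x)), digits = digits, row.names = FALSE)
  invisible(x)
}
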