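#' Paired t-test on a vector of difference scores
#'
#' One-sample t-test of the per-subject differences against zero,
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample (n - 1) standard
#' deviation and a two-sided p-value on n - 1 degrees of freedom. This is the
#' screening test applied to each visual-function difference before it enters
#' the coupling.
#'
#' @param differences Numeric vector of post-minus-pre differences, n >= 2,
#'   no `NA`.
#' @return A one-row tibble: `n`, `mean_diff`, `sd_diff`, `t_stat`, `df`,
#'   `p_value`.
#' @examples
#' paired_t(c(-0.9, -0.5, -0.6, -0.2))
#' @export
paired_t <- function(differences) {
  if (!is.numeric(differences) || anyNA(differences)) {
    rlang::abort("`differences` must be a numeric vector without NA.",
                 class = "vc_domain_error")
  }
  n <- length(differences)
  if (n < 2) {
    rlang::abort("Need at least 2 paired differences.",
                 class = "vc_domain_error")
  }
  s <- stats::sd(differences)
  if (s == 0) {
    rlang::abort("All differences are identical (zero SD); t is undefined.",
                 class = "vc_degenerate_error")
  }
  ht <- stats::t.test(differences, mu = 0)
  tibble::tibble(
    n = n,
    mean_diff = mean(differences),
    sd_diff = s,
    t_stat = unname(ht$statistic),
    df = n - 1L,
    p_value = ht$p.value
  )
}

#' Reconstruct a paired t-statistic from summary statistics
#'
#' `t = mean_diff * sqrt(n) / sd_diff` — algebraically identical to
#' [paired_t()] on any dataset with those summaries. Useful for checking
#' published t-values against published (rounded) means and SDs.
#'
#' @param mean_diff Mean difference (vectorized).
#' @param sd_diff Sample standard deviation of the differences, > 0.
#' @param n Number of paired subjects, >= 2.
#' @return Numeric vector of t-statistics.
#' @examples
#' t_from_summary(-1.48, 2.02, 46)
#' @export
t_from_summary <- function(mean_diff, sd_diff, n) {
  if (any(n < 2)) {
    rlang::abort("Need n >= 2.", class = "vc_domain_error")
  }
  if (any(sd_diff <= 0)) {
    rlang::abort("`sd_diff` must be > 0.", class = "vc_degenerate_error")
  }
  mean_diff * sqrt(n) / sd_diff
}

#' Pearson correlation matrix of indicator columns
#'
#' Pairwise Pearson correlations between the columns of a numeric matrix or
#' data frame of per-subject indicator values. Correlation is invariant under
#' positive affine rescaling of any column, so the result is identical
#' whether computed on raw or Z-score standardized scores.
#'
#' @param x Numeric matrix or data frame, m >= 3 rows; every column must
#'   have nonzero variance and no `NA`.
#' @return A symmetric correlation matrix with unit diagonal, carrying the
#'   column names of `x`.
#' @examples
#' correlation_matrix(cbind(a = c(1, 2, 3), b = c(1, 3, 2)))
#' @export
correlation_matrix <- function(x) {
  x <- as_indicator_matrix(x, min_rows = 3)
  check_column_variance(x)
  r <- stats::cor(x)
  # clamp tiny floating-point excursions outside [-1, 1]
  pmin(pmax(r, -1), 1)
}

# coerce a data frame (numeric columns only; subject_id allowed and used as
# rownames) or matrix into the m x n indicator matrix used by the CRITIC chain
as_indicator_matrix <- function(x, min_rows = 3, call = rlang::caller_env()) {
  if (is.data.frame(x)) {
    ids <- if ("subject_id" %in% names(x)) as.character(x$subject_id) else NULL
    x <- x[setdiff(names(x), "subject_id")]
    num <- vapply(x, is.numeric, logical(1))
    if (!all(num)) {
      rlang::abort(
        sprintf("Non-numeric indicator column(s): %s.",
                paste(names(x)[!num], collapse = ", ")),
        class = "vc_format_error", call = call
      )
    }
    x <- as.matrix(x)
    if (!is.null(ids)) rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    rlang::abort("Expected a numeric matrix or data frame of indicators.",
                 class = "vc_format_error", call = call)
  }
  if (anyNA(x)) {
    rlang::abort("Indicator matrix contains missing values.",
                 class = "vc_format_error", call = call)
  }
  if (nrow(x) < min_rows || ncol(x) < 2) {
    rlang::abort(
      sprintf("Need at least %d subjects (rows) and 2 indicators (columns).",
              min_rows),
      class = "vc_domain_error", call = call
    )
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  x
}

check_column_variance <- function(x, call = rlang::caller_env()) {
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(
      sprintf("Zero-variance column(s): %s.",
              paste(colnames(x)[sds == 0], collapse = ", ")),
      class = "vc_degenerate_error", call = call
    )
  }
  invisible(sds)
}

#' Paired-t screening of every difference-score indicator
#'
#' Runs [paired_t()] on each difference column of a difference-score table
#' (as produced by [difference_scores()] or [simulate_differences()]) and
#' flags significance at the given threshold. This mirrors the pre-coupling
#' screening in which each visual-function difference is tested on its own;
#' a non-significant indicator (classically vertical PEP) is a candidate for
#' exclusion from the coupling.
#'
#' @param diffs Data frame of per-subject differences; any `d_*` numeric
#'   columns are tested, `subject_id` is ignored.
#' @param alpha Two-sided significance threshold (default 0.05).
#' @return A tibble with one row per indicator: `indicator`, `n`,
#'   `mean_diff`, `sd_diff`, `t_stat`, `df`, `p_value`, `significant`.
#' @examples
#' paired_screen(simulate_differences(cohort_spec(n = 46, seed = 1)))
#' @export
paired_screen <- function(diffs, alpha = 0.05) {
  cols <- setdiff(names(diffs)[vapply(diffs, is.numeric, logical(1))],
                  "subject_id")
  if (length(cols) == 0) {
    rlang::abort("No numeric difference columns found.",
                 class = "vc_format_error")
  }
  purrr::map_dfr(cols, function(col) {
    d <- diffs[[col]]
    d <- d[!is.na(d)]
    dplyr::mutate(paired_t(d), indicator = col, .before = 1)
  }) |>
    dplyr::mutate(significant = .data$p_value < alpha)
}
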