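#' Default benefit/cost orientation of the coupled indicators
#'
#' Improvement after treatment appears as a *decrease* in logMAR acuity, the
#' interocular BRBP gap and horizontal PEP deviation (cost-type indicators)
#' but an *increase* in the stereoacuity level (benefit-type). Cost-type
#' difference scores are negated before coupling so that larger always means
#' better.
#'
#' @return Named character vector mapping each indicator to `"benefit"` or
#'   `"cost"`.
#' @export
default_orientation <- function() {
  c(d_va = "cost", d_brbp = "cost", d_hpep = "cost", d_sa = "benefit")
}

#' Orient difference scores so larger is better
#'
#' Negates cost-type difference columns and leaves benefit-type columns
#' unchanged, per the orientation map. Columns not named in `orientation`
#' (e.g. `subject_id`, a carried `d_vpep`) pass through untouched; every
#' oriented column must be present and complete.
#'
#' @param diffs Data frame of per-subject differences.
#' @param orientation Named character vector of `"benefit"`/`"cost"` per
#'   indicator column; defaults to [default_orientation()].
#' @return `diffs` with oriented indicator columns.
#' @examples
#' orient_differences(tibble::tibble(
#'   d_va = -0.9, d_brbp = -3, d_hpep = -0.64, d_sa = 2
#' ))
#' @export
orient_differences <- function(diffs, orientation = default_orientation()) {
  if (!all(orientation %in% c("benefit", "cost"))) {
    rlang::abort("Orientation values must be \"benefit\" or \"cost\".",
                 class = "vc_domain_error")
  }
  missing_cols <- setdiff(names(orientation), names(diffs))
  if (length(missing_cols) > 0) {
    rlang::abort(
      sprintf("Missing oriented indicator column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      class = "vc_completeness_error"
    )
  }
  for (col in names(orientation)) {
    if (anyNA(diffs[[col]])) {
      rlang::abort(
        sprintf("Indicator '%s' has missing values; coupling needs complete vectors.", col),
        class = "vc_completeness_error"
      )
    }
    if (orientation[[col]] == "cost") diffs[[col]] <- -diffs[[col]]
  }
  diffs
}

#' Per-subject coupling index from weighted oriented differences
#'
#' Combines each subject's oriented difference scores into a single
#' treatment-efficacy score. Scores are first normalized per indicator
#' across the cohort — min-max to \[0, 1\] (default, the normalization native
#' to the CRITIC literature) or Z-score — then combined as the weighted sum
#' `ci_i = sum_j w_j * u_ij`. Under min-max normalization the coupling index
#' lies in \[0, 1\]: a subject at the cohort-wide best value of every
#' indicator scores 1, one at every worst value scores 0.
#'
#' @param diffs Data frame of per-subject differences with a `subject_id`
#'   column (as from [difference_scores()]).
#' @param weights Named numeric weights over the coupled indicators, summing
#'   to 1 — typically `run_critic(...)$weights` or
#'   `reference_cohort()$weights`.
#' @param orientation Benefit/cost map; defaults to [default_orientation()].
#'   Only indicators named in `weights` are coupled.
#' @param normalization `"minmax"` (default) or `"zscore"` (cohort
#'   Z-scores).
#' @return A tibble of class `coupling_scores` with one row per subject:
#'   `subject_id`, one contribution column `w_u_<indicator>` per coupled
#'   indicator, and `ci` (their sum), sorted in descending `ci` with
#'   `subject_id` breaking ties; `rank` gives the position. Attributes
#'   record the weights and normalization.
#' @examples
#' diffs <- difference_scores(validation_cohort(fill_missing = TRUE))
#' coupling_index(diffs, reference_cohort()$weights)
#' @export
coupling_index <- function(diffs, weights,
                           orientation = default_orientation(),
                           normalization = c("minmax", "zscore")) {
  normalization <- match.arg(normalization)
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    rlang::abort("`weights` must be a fully named numeric vector.",
                 class = "vc_domain_error")
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    rlang::abort("`weights` must sum to 1.", class = "vc_domain_error")
  }
  orientation <- orientation[intersect(names(orientation), names(weights))]
  if (!setequal(names(orientation), names(weights))) {
    rlang::abort("Every weighted indicator needs a benefit/cost orientation.",
                 class = "vc_completeness_error")
  }
  if (!"subject_id" %in% names(diffs)) {
    rlang::abort("`diffs` needs a subject_id column.",
                 class = "vc_format_error")
  }
  if (nrow(diffs) < 2) {
    rlang::abort("Cohort-relative normalization needs at least 2 subjects.",
                 class = "vc_domain_error")
  }
  oriented <- orient_differences(diffs, orientation)
  u <- purrr::map(names(weights), function(col) {
    xs <- oriented[[col]]
    if (normalization == "minmax") {
      rng <- range(xs)
      if (rng[1] == rng[2]) {
        rlang::abort(
          sprintf("Indicator '%s' is constant across the cohort; min-max normalization is undefined.", col),
          class = "vc_degenerate_error"
        )
      }
      (xs - rng[1]) / (rng[2] - rng[1])
    } else {
      (xs - mean(xs)) / stats::sd(xs)
    }
  })
  contrib <- purrr::map2(u, unname(weights), `*`)
  names(contrib) <- paste0("w_u_", names(weights))
  out <- tibble::tibble(subject_id = as.character(diffs$subject_id), !!!contrib)
  out$ci <- rowSums(out[names(contrib)])
  out <- out[order(-out$ci, out$subject_id), ]
  out$rank <- seq_len(nrow(out))
  structure(out,
            class = c("coupling_scores", class(tibble::tibble())),
            weights = weights, normalization = normalization)
}

#' Rank subjects by coupling index
#'
#' Orders coupling scores by descending index, breaking ties by
#' `subject_id` (lexicographic), and renumbers `rank`.
#'
#' @param scores A `coupling_scores` tibble (or any data frame with
#'   `subject_id` and `ci` columns).
#' @return The reordered tibble with an updated `rank` column.
#' @export
rank_subjects <- function(scores) {
  if (nrow(scores) == 0) {
    rlang::abort("No scores to rank.", class = "vc_domain_error")
  }
  scores <- scores[order(-scores$ci, scores$subject_id), ]
  scores$rank <- seq_len(nrow(scores))
  scores
}
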