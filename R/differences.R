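cohort_columns <- c("subject_id", "phase", "va_logmar", "brbp_right",
                    "brbp_left", "pep_h_deg", "pep_v_deg", "stereo_level")

indicator_names <- c("d_va", "d_brbp", "d_hpep", "d_sa")

# validates the long cohort layout (one row per subject-phase) used throughout
validate_cohort <- function(cohort, call = rlang::caller_env()) {
  if (!is.data.frame(cohort)) {
    rlang::abort("`cohort` must be a data frame.", class = "vc_format_error",
                 call = call)
  }
  missing_cols <- setdiff(setdiff(cohort_columns, "pep_v_deg"), names(cohort))
  if (length(missing_cols) > 0) {
    rlang::abort(
      sprintf("Cohort is missing required column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      class = "vc_format_error", call = call
    )
  }
  if (nrow(cohort) == 0) {
    rlang::abort("Cohort has no rows.", class = "vc_format_error", call = call)
  }
  if (any(is.na(cohort$subject_id) | cohort$subject_id == "")) {
    rlang::abort("Every row needs a non-empty subject_id.",
                 class = "vc_format_error", call = call)
  }
  if (!all(cohort$phase %in% c("pre", "post"))) {
    rlang::abort("`phase` must be \"pre\" or \"post\".",
                 class = "vc_format_error", call = call)
  }
  counts <- table(cohort$subject_id, cohort$phase)
  unpaired <- rownames(counts)[counts[, "pre"] != 1 | counts[, "post"] != 1]
  if (length(unpaired) > 0) {
    rlang::abort(
      sprintf("Each subject needs exactly one pre and one post record; offending subject(s): %s.",
              paste(unpaired, collapse = ", ")),
      class = "vc_pairing_error", call = call
    )
  }
  check_level(cohort$brbp_right, 1L, 8L, "BRBP level (right eye)")
  check_level(cohort$brbp_left, 1L, 8L, "BRBP level (left eye)")
  check_level(cohort$stereo_level, 0L, 4L, "stereo level")
  if (any(!is.na(cohort$pep_h_deg) & cohort$pep_h_deg < 0)) {
    rlang::abort("Horizontal PEP deviations must be non-negative magnitudes.",
                 class = "vc_domain_error", call = call)
  }
  invisible(cohort)
}

#' Per-subject pre/post difference scores
#'
#' Collapses a paired cohort (one `pre` and one `post` examination row per
#' subject) to one difference vector per subject, oriented post minus pre:
#'
#' * `d_va` — change in logMAR acuity of the amblyopic eye; negative values
#'   are improvements (lower logMAR is better).
#' * `d_brbp` — change in the interocular BRBP gap `|left - right|` computed
#'   per phase ([brbp_interocular_gap()]); negative = more balanced rivalry.
#' * `d_hpep` — change in horizontal perceptual-eye-position deviation
#'   (degrees); negative = better cortical eye-position control.
#' * `d_sa` — change in the stereoacuity level code (0-4); positive = finer
#'   stereopsis.
#' * `d_vpep` — change in vertical PEP deviation, carried for reporting when
#'   a `pep_v_deg` column is present but never entered into the coupling
#'   index.
#'
#' @param cohort A data frame with one row per subject-phase and columns
#'   `subject_id`, `phase` (`"pre"`/`"post"`), `va_logmar`, `brbp_right`,
#'   `brbp_left`, `pep_h_deg`, `stereo_level`, optionally `pep_v_deg`.
#' @return A tibble with one row per subject: `subject_id`, `d_va`, `d_brbp`,
#'   `d_hpep`, `d_sa` (and `d_vpep` when vertical PEP was measured). `NA` in
#'   any source field propagates to the affected difference.
#' @examples
#' difference_scores(validation_cohort(fill_missing = TRUE))
#' @export
difference_scores <- function(cohort) {
  validate_cohort(cohort)
  has_vpep <- "pep_v_deg" %in% names(cohort) && any(!is.na(cohort$pep_v_deg))
  scored <- cohort |>
    dplyr::mutate(brbp_gap = brbp_interocular_gap(.data$brbp_left, .data$brbp_right)) |>
    dplyr::select(dplyr::all_of(c("subject_id", "phase", "va_logmar",
                                  "brbp_gap", "pep_h_deg", "stereo_level")),
                  dplyr::any_of("pep_v_deg")) |>
    tidyr::pivot_wider(names_from = "phase",
                       values_from = !dplyr::all_of(c("subject_id", "phase")))
  out <- scored |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      d_va = .data$va_logmar_post - .data$va_logmar_pre,
      d_brbp = .data$brbp_gap_post - .data$brbp_gap_pre,
      d_hpep = .data$pep_h_deg_post - .data$pep_h_deg_pre,
      d_sa = as.numeric(.data$stereo_level_post - .data$stereo_level_pre)
    )
  if (has_vpep) {
    out$d_vpep <- scored$pep_v_deg_post - scored$pep_v_deg_pre
  }
  dplyr::arrange(out, .data$subject_id)
}

#' Difference vector for a single pre/post record pair
#'
#' Convenience wrapper around [difference_scores()] for exactly one subject:
#' both rows must share the same `subject_id`, with phases `pre` and `post`.
#'
#' @param pre,post Single-row data frames in the cohort layout.
#' @return A one-row tibble of difference scores.
#' @export
difference_vector <- function(pre, post) {
  if (nrow(pre) != 1 || nrow(post) != 1) {
    rlang::abort("`pre` and `post` must each be a single record.",
                 class = "vc_pairing_error")
  }
  if (!identical(pre$subject_id, post$subject_id)) {
    rlang::abort(
      sprintf("Subject mismatch: pre is '%s', post is '%s'.",
              pre$subject_id, post$subject_id),
      class = "vc_pairing_error"
    )
  }
  if (!identical(pre$phase, "pre") || !identical(post$phase, "post")) {
    rlang::abort("Records must have phase 'pre' and 'post' respectively.",
                 class = "vc_pairing_error")
  }
  difference_scores(dplyr::bind_rows(pre, post))
}
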