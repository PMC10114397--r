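#' Read a paired examination cohort from CSV
#'
#' Expects one row per subject-phase with a header. Required columns:
#' `subject_id`, `phase` (`pre`/`post`), either `va_logmar` or `va_decimal`
#' (decimal acuity is converted to logMAR on ingest with a notice),
#' `brbp_right`, `brbp_left` (levels 1..8), `pep_h_deg`, and either
#' `stereo_level` (0..4) or `stereo_arcsec` (100/200/300/400 or `"none"`).
#' `pep_v_deg` is optional and carried for reporting only. Empty cells
#' become `NA` and are reported as flagged-missing fields; no imputation is
#' performed.
#'
#' @param path Path to a UTF-8 CSV file with `.` as the decimal separator.
#' @return A validated cohort tibble in the layout of
#'   [difference_scores()].
#' @examples
#' path <- system.file("extdata", "validation_cohort.csv",
#'                     package = "visioncouple")
#' read_cohort(path)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path),
                 class = "vc_format_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    rlang::abort("Cohort file is empty.", class = "vc_format_error")
  }
  need_one <- function(alternatives) {
    hit <- intersect(alternatives, names(raw))
    if (length(hit) == 0) {
      rlang::abort(
        sprintf("Cohort file needs a %s column.",
                paste(alternatives, collapse = " or ")),
        class = "vc_format_error"
      )
    }
    hit[1]
  }
  va_col <- need_one(c("va_logmar", "va_decimal"))
  stereo_col <- need_one(c("stereo_level", "stereo_arcsec"))
  for (col in c("subject_id", "phase", "brbp_right", "brbp_left", "pep_h_deg")) {
    need_one(col)
  }

  num <- function(col, what = col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & nzchar(raw[[col]]) & is.na(x))
    if (length(bad) > 0) {
      rlang::abort(
        sprintf("Unparseable number in column '%s', data row(s) %s.",
                what, paste(bad, collapse = ", ")),
        class = "vc_format_error"
      )
    }
    x
  }
  va <- num(va_col)
  if (va_col == "va_decimal") {
    message("Converting decimal acuity to logMAR (va_logmar = -log10(va_decimal)).")
    va <- decimal_to_logmar(va)
  }
  stereo <- if (stereo_col == "stereo_arcsec") {
    stereo_level(raw[[stereo_col]])
  } else {
    num(stereo_col)
  }
  cohort <- tibble::tibble(
    subject_id = raw$subject_id,
    phase = raw$phase,
    va_logmar = va,
    brbp_right = num("brbp_right"),
    brbp_left = num("brbp_left"),
    pep_h_deg = num("pep_h_deg"),
    pep_v_deg = if ("pep_v_deg" %in% names(raw)) num("pep_v_deg") else NA_real_,
    stereo_level = stereo
  )
  validate_cohort(cohort)
  flag_cols <- setdiff(cohort_columns, "pep_v_deg")
  flagged <- which(rowSums(is.na(cohort[flag_cols])) > 0)
  if (length(flagged) > 0) {
    message(sprintf(
      "Flagged missing examination field(s) in data row(s): %s. No imputation is performed.",
      paste(flagged, collapse = ", ")
    ))
  }
  cohort
}

#' Write a cohort to CSV
#'
#' Writes the long cohort layout back to disk; numbers are serialized at
#' full precision so that `read_cohort(write_cohort(x, f))` round-trips.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort[intersect(cohort_columns, names(cohort))], path,
                   na = "")
  invisible(path)
}

#' The 8-subject validation cohort
#'
#' The packaged validation fixture: eight additional subjects examined
#' before and after treatment, used to demonstrate the coupling index on
#' held-out data. Subject S1's pre-treatment right-eye BRBP level is not
#' legible in the source table and is stored as missing; with
#' `fill_missing = TRUE` it is completed with level 8 — a synthetic,
#' documented reconstruction consistent with the narrative that only S1's
#' *left* eye improved (4 to 7) while the post-treatment right eye sat at
#' level 8 — so that the complete-case coupling pipeline can run.
#'
#' @param fill_missing Replace S1's flagged-missing pre-treatment
#'   `brbp_right` with the documented reconstruction (default `FALSE`).
#' @return A cohort tibble with 16 rows (8 subjects x pre/post).
#' @examples
#' validation_cohort()
#' @export
validation_cohort <- function(fill_missing = FALSE) {
  path <- system.file("extdata", "validation_cohort.csv",
                      package = "visioncouple")
  cohort <- suppressMessages(read_cohort(path))
  if (fill_missing) {
    fix <- cohort$subject_id == "S1" & cohort$phase == "pre"
    cohort$brbp_right[fix] <- 8L
  }
  cohort
}

#' Published coupling-index values of the validation cohort
#'
#' The coupling-index column printed alongside the validation cohort in the
#' source study. The exact formula (and whether normalization used the
#' validation subjects alone or the full training cohort) was never
#' published, so these values are a qualitative reference — the package's
#' default index reproduces their narrated *ordering* (S1 maximal, S5 below
#' S4), not their magnitudes.
#'
#' @return A tibble with `subject_id` and `ci_published`.
#' @export
reference_coupling_index <- function() {
  tibble::tibble(
    subject_id = paste0("S", 1:8),
    ci_published = c(0.5210, 0.3502, 0.3002, 0.3468,
                     0.1897, 0.1784, 0.1389, 0.2066)
  )
}

#' Run the full efficacy-evaluation pipeline on a paired cohort
#'
#' Executes the complete analysis sequence: per-subject difference scores;
#' paired-t screening of every difference indicator (vertical PEP, when
#' measured, is screened but never coupled); CRITIC weighting of the four
#' coupled indicators; per-subject coupling indices; and the pairwise
#' Pearson correlations among all difference indicators (reported as a
#' table — the analysis fits no regression line because single indicators do
#' not track each other well, which is the motivation for coupling).
#'
#' @param cohort A paired cohort tibble with at least 3 subjects and
#'   complete coupled indicators.
#' @param convention,magnitude CRITIC options, see [run_critic()].
#' @param normalization Coupling normalization, see [coupling_index()].
#' @param orientation Benefit/cost map, see [default_orientation()].
#' @param alpha Significance threshold for the screening block.
#' @param weights Optional fixed named weights for the coupling (e.g.
#'   `reference_cohort()$weights`); by default the CRITIC weights fitted to
#'   this cohort are used.
#' @return An object of class `vision_report`: a list with `differences`,
#'   `screening`, `critic` (a `critic_fit`), `scores`
#'   (a `coupling_scores` tibble), `cross_correlation`, `config`, and
#'   `provenance` (package version, input hash, timestamp-free). Supports
#'   `print()` and [report_json()].
#' @examples
#' report <- run_full_report(validation_cohort(fill_missing = TRUE))
#' report$scores
#' @export
run_full_report <- function(cohort,
                            convention = c("table", "eq"),
                            magnitude = c("abs", "signed"),
                            normalization = c("minmax", "zscore"),
                            orientation = default_orientation(),
                            alpha = 0.05,
                            weights = NULL) {
  convention <- match.arg(convention)
  magnitude <- match.arg(magnitude)
  normalization <- match.arg(normalization)
  validate_cohort(cohort)
  if (length(unique(cohort$subject_id)) < 3) {
    rlang::abort("Need at least 3 paired subjects.", class = "vc_domain_error")
  }
  diffs <- difference_scores(cohort)
  screening <- paired_screen(diffs, alpha = alpha)
  coupled <- diffs[c("subject_id", indicator_names)]
  fit <- run_critic(coupled, convention = convention, magnitude = magnitude)
  w <- if (is.null(weights)) fit$weights else weights
  scores <- coupling_index(diffs, w, orientation = orientation,
                           normalization = normalization)
  num_cols <- setdiff(names(diffs), "subject_id")
  cross <- correlation_matrix(diffs[stats::complete.cases(diffs), num_cols])
  config <- list(convention = convention, magnitude = magnitude,
                 normalization = normalization, orientation = orientation,
                 alpha = alpha,
                 weights_source = if (is.null(weights)) "critic_fit" else "supplied")
  structure(
    list(
      differences = diffs,
      screening = screening,
      critic = fit,
      scores = scores,
      cross_correlation = cross,
      config = config,
      provenance = list(
        package = "visioncouple",
        version = as.character(utils::packageVersion("visioncouple")),
        input_hash = rlang::hash(cohort),
        n_subjects = length(unique(cohort$subject_id))
      )
    ),
    class = "vision_report"
  )
}

#' @export
print.vision_report <- function(x, digits = 4, ...) {
  cat(sprintf("Amblyopia treatment-efficacy report: %d paired subjects\n\n",
              x$provenance$n_subjects))
  cat("Paired-t screening of difference scores:\n")
  print(as.data.frame(x$screening), digits = digits, row.names = FALSE)
  cat("\nCRITIC weights:\n")
  print(round(x$critic$weights, digits))
  cat("\nTop coupling indices:\n")
  print(utils::head(as.data.frame(x$scores[c("subject_id", "ci", "rank")]), 5),
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Writes every block of a [run_full_report()] result (screening table,
#' CRITIC intermediates, coupling scores, cross-correlations, configuration,
#' provenance) to JSON at full numeric precision. With `path = NULL` the
#' JSON string is returned instead.
#'
#' @param report A `vision_report`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return `path` (invisibly) or a JSON string.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "vision_report"))
  fit <- report$critic
  payload <- list(
    screening = report$screening,
    critic = list(
      summaries = fit$summaries,
      correlation = mat_to_list(fit$correlation),
      independence = as.list(fit$independence),
      information = as.list(stats::setNames(fit$information,
                                            fit$summaries$indicator)),
      weights = as.list(fit$weights),
      convention = fit$convention,
      magnitude = fit$magnitude
    ),
    scores = as.data.frame(report$scores),
    cross_correlation = mat_to_list(report$cross_correlation),
    config = report$config,
    provenance = report$provenance
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

mat_to_list <- function(m) {
  list(labels = colnames(m), entries = unname(apply(m, 1, as.list)))
}
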