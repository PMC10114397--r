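#' Specification of a synthetic difference-score cohort
#'
#' Bundles the generative parameters of the synthetic-cohort module. The
#' defaults reproduce the published difference-score structure of the
#' motivating 46-child training cohort ([reference_cohort()]): per-indicator
#' means and SDs, and the 4x4 inter-indicator Pearson correlation.
#'
#' @param n Number of subjects (>= 3).
#' @param seed Integer seed; every draw from the spec is deterministic given
#'   it. Mandatory — there is no hidden global randomness.
#' @param means,sds Length-4 target means and SDs of
#'   (`d_va`, `d_brbp`, `d_hpep`, `d_sa`); SDs must be positive.
#' @param correlation 4x4 target correlation matrix: symmetric, unit
#'   diagonal, positive definite.
#' @param mode `"continuous"` (Gaussian scores) or `"discretized"`
#'   (additionally snaps `d_va` to the 0.1 logMAR grid, rounds `d_brbp` and
#'   `d_sa` to integers, and clips them to their legal spans \[-7, 7\] and
#'   \[-4, 4\]).
#' @return A list of class `cohort_spec`.
#' @examples
#' cohort_spec(n = 46, seed = 1)
#' @export
cohort_spec <- function(n = 46, seed,
                        means = reference_cohort()$means,
                        sds = reference_cohort()$sds,
                        correlation = reference_cohort()$correlation,
                        mode = c("continuous", "discretized")) {
  mode <- match.arg(mode)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    rlang::abort("`seed` is required and must be a single integer.",
                 class = "vc_spec_error")
  }
  if (n < 3) {
    rlang::abort("Need n >= 3 subjects for a defined correlation.",
                 class = "vc_spec_error")
  }
  if (length(means) != 4 || length(sds) != 4) {
    rlang::abort("`means` and `sds` must have length 4.",
                 class = "vc_spec_error")
  }
  if (any(sds <= 0)) {
    rlang::abort("Target SDs must be strictly positive.",
                 class = "vc_spec_error")
  }
  if (!is.matrix(correlation) || !all(dim(correlation) == 4) ||
      any(abs(correlation - t(correlation)) > 1e-10) ||
      any(abs(diag(correlation) - 1) > 1e-10)) {
    rlang::abort("`correlation` must be a symmetric 4x4 matrix with unit diagonal.",
                 class = "vc_spec_error")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    rlang::abort(
      paste("`correlation` is not positive definite; repair it first,",
            "e.g. with a nearest-positive-definite projection",
            "(Matrix::nearPD), and rerun."),
      class = "vc_spec_error"
    )
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         means = stats::setNames(as.numeric(means), indicator_names),
         sds = stats::setNames(as.numeric(sds), indicator_names),
         correlation = correlation, mode = mode),
    class = "cohort_spec"
  )
}

# snap to a grid of the given step (0.1 logMAR lines, integer levels)
snap <- function(x, step) round(x / step) * step

#' Draw a synthetic difference-score cohort
#'
#' Samples `n` subjects from a multivariate normal with the spec's target
#' correlation (via the Cholesky factor of the target covariance), rescaled
#' to the target SDs and shifted to the target means. In `"discretized"`
#' mode the draws are then snapped to each scale's legal grid: `d_va` to 0.1
#' logMAR steps, `d_brbp` to integers in \[-7, 7\], `d_sa` to integers in
#' \[-4, 4\]. Identical spec and seed give identical output.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `d_va`, `d_brbp`, `d_hpep`,
#'   `d_sa`.
#' @examples
#' simulate_differences(cohort_spec(n = 10, seed = 42))
#' @export
simulate_differences <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sigma <- diag(spec$sds) %*% spec$correlation %*% diag(spec$sds)
  z <- matrix(stats::rnorm(spec$n * 4), nrow = spec$n)
  x <- z %*% chol(sigma)
  x <- sweep(x, 2, spec$means, `+`)
  colnames(x) <- indicator_names
  out <- tibble::as_tibble(x)
  out <- tibble::add_column(out,
                            subject_id = sprintf("P%04d", seq_len(spec$n)),
                            .before = 1)
  if (spec$mode == "discretized") {
    out$d_va <- snap(out$d_va, 0.1)
    out$d_brbp <- pmin(pmax(round(out$d_brbp), -7), 7)
    out$d_sa <- pmin(pmax(round(out$d_sa), -4), 4)
  }
  out
}

#' Generate a full synthetic paired cohort of examination records
#'
#' Builds pre-treatment examination records on clinically legal grids —
#' logMAR acuity 0.1 to 1.0 in 0.1 steps, per-eye BRBP levels 1..8,
#' horizontal PEP deviation 0 to 3 degrees, stereo levels 0..4 — and sets
#' each post-treatment record to pre plus the subject's (discretized)
#' difference score. Differences whose magnitude no pre value can
#' accommodate are first clipped to the achievable span, so
#' [difference_scores()] on the generated cohort returns exactly the clipped
#' difference matrix. The interocular BRBP gap is realized as a random legal
#' eye pair with that gap in each phase.
#'
#' @param spec A [cohort_spec()] with `mode = "discretized"`.
#' @return A cohort tibble, one row per subject-phase, in the layout
#'   accepted by [difference_scores()].
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 8, seed = 3, mode = "discretized"))
#' difference_scores(cohort)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$mode != "discretized") {
    rlang::abort("Examination records live on discrete grids; use mode = \"discretized\".",
                 class = "vc_spec_error")
  }
  diffs <- simulate_differences(spec)  # seeds the stream; draws below continue it
  n <- spec$n

  # acuity: work in integer tenths of logMAR; pre on 1..10, post on -3..10
  d_tenths <- pmin(pmax(as.integer(round(diffs$d_va * 10)), -13L), 9L)
  pre_va <- vapply(d_tenths, function(d) {
    lo <- max(1L, -3L - d)
    hi <- min(10L, 10L - d)
    sample_int(lo, hi)
  }, integer(1))
  post_va <- pre_va + d_tenths

  # BRBP: choose a feasible pre gap, then random legal eye pairs per phase
  d_gap <- as.integer(diffs$d_brbp)
  pre_gap <- vapply(d_gap, function(d) sample_int(max(0L, -d), min(7L, 7L - d)),
                    integer(1))
  post_gap <- pre_gap + d_gap
  pre_eyes <- t(vapply(pre_gap, eye_pair_with_gap, integer(2)))
  post_eyes <- t(vapply(post_gap, eye_pair_with_gap, integer(2)))

  # horizontal PEP: continuous on [0, 3] pre; post must stay non-negative
  d_hpep <- pmax(diffs$d_hpep, -3)
  pre_h <- stats::runif(n, min = pmax(0, -d_hpep), max = 3)
  post_h <- pre_h + d_hpep

  # stereo level: integer 0..4 both phases
  d_sa <- as.integer(diffs$d_sa)
  pre_sa <- vapply(d_sa, function(d) sample_int(max(0L, -d), min(4L, 4L - d)),
                   integer(1))
  post_sa <- pre_sa + d_sa

  record <- function(phase, va, h, eyes, sa) {
    tibble::tibble(
      subject_id = diffs$subject_id,
      phase = phase,
      va_logmar = va / 10,
      pep_h_deg = h,
      pep_v_deg = NA_real_,
      brbp_right = eyes[, 1],
      brbp_left = eyes[, 2],
      stereo_level = sa
    )
  }
  dplyr::bind_rows(
    record("pre", pre_va, pre_h, pre_eyes, pre_sa),
    record("post", post_va, post_h, post_eyes, post_sa)
  ) |>
    dplyr::arrange(.data$subject_id, dplyr::desc(.data$phase))
}

# uniform integer draw on lo..hi (inclusive); degenerate range allowed
sample_int <- function(lo, hi) {
  if (lo > hi) {
    rlang::abort("Infeasible difference: no legal pre-treatment value exists.",
                 class = "vc_spec_error")
  }
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# random (right, left) BRBP levels in 1..8 with the requested gap
eye_pair_with_gap <- function(gap) {
  lower <- sample_int(1L, 8L - gap)
  pair <- c(lower, lower + gap)
  if (stats::runif(1) < 0.5) pair <- rev(pair)
  pair
}
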