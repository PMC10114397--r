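#' Convert decimal visual acuity to logMAR
#'
#' Standard logarithmic acuity charts record decimal acuity from 0.1 to 2.0 in
#' 14 steps, corresponding to logMAR 1.0 down to -0.3 in 0.1 steps. The
#' conversion is `logMAR = -log10(decimal)`; values are stored at full
#' precision and rounded only for display.
#'
#' @param decimal Numeric vector of decimal acuities; all values must be
#'   strictly positive.
#' @return Numeric vector of logMAR values.
#' @examples
#' decimal_to_logmar(c(0.1, 1.0, 2.0))
#' @seealso [logmar_to_decimal()]
#' @export
decimal_to_logmar <- function(decimal) {
  if (!is.numeric(decimal)) {
    rlang::abort("`decimal` must be numeric.", class = "vc_domain_error")
  }
  bad <- !is.na(decimal) & decimal <= 0
  if (any(bad)) {
    rlang::abort(
      sprintf("Decimal acuity must be > 0 (got %s).",
              paste(decimal[bad], collapse = ", ")),
      class = "vc_domain_error"
    )
  }
  -log10(decimal)
}

#' Convert logMAR visual acuity to decimal
#'
#' Inverse of [decimal_to_logmar()]: `decimal = 10^(-logMAR)`. Chart-sourced
#' values lie in logMAR -0.3 to 1.0; arbitrary reals are accepted.
#'
#' @param logmar Numeric vector of logMAR acuities.
#' @return Numeric vector of decimal acuities (strictly positive).
#' @export
logmar_to_decimal <- function(logmar) {
  if (!is.numeric(logmar)) {
    rlang::abort("`logmar` must be numeric.", class = "vc_domain_error")
  }
  10^(-logmar)
}

# signal/noise ladder for the 8 BRBP levels; levels 4-7 follow the stated
# 10-points-per-level progression between level 3 (70/30) and level 8 (20/80)
.brbp_ladder <- c(100, 85, 70, 60, 50, 40, 30, 20)

#' Signal/noise proportions of a binocular-rivalry balance-point level
#'
#' The binocular rivalry balance point (BRBP) is measured per eye on an
#' 8-level ladder of signal/noise dot proportions under dichoptic viewing:
#' level 1 is 100% signal / 0% noise, level 2 is 85/15, level 3 is 70/30, and
#' each further level trades 10 percentage points from signal to noise until
#' level 8 at 20/80. Proportions always sum to 100.
#'
#' @param level Integer vector of BRBP levels in 1..8.
#' @return A tibble with columns `level`, `signal_pct`, `noise_pct`.
#' @examples
#' brbp_proportions(1:8)
#' @export
brbp_proportions <- function(level) {
  level <- check_level(level, 1L, 8L, "BRBP level")
  tibble::tibble(
    level = level,
    signal_pct = .brbp_ladder[level],
    noise_pct = 100 - .brbp_ladder[level]
  )
}

#' Interocular BRBP gap
#'
#' Absolute difference between the BRBP levels of the two eyes,
#' `|left - right|`. The absolute value makes the index invariant to which eye
#' is labelled amblyopic; a gap of 0 means perfectly balanced rivalry, 7 is
#' the maximal imbalance the ladder can express.
#'
#' @param left,right Integer vectors of per-eye BRBP levels (1..8). `NA`
#'   propagates.
#' @return Numeric vector of gaps in 0..7.
#' @examples
#' brbp_interocular_gap(4, 8)
#' @export
brbp_interocular_gap <- function(left, right) {
  left <- check_level(left, 1L, 8L, "BRBP level (left eye)")
  right <- check_level(right, 1L, 8L, "BRBP level (right eye)")
  abs(left - right)
}

# arcsec thresholds for stereo levels 4,3,2,1 (level 0 = no stereopsis)
.stereo_arcsec <- c(`4` = 100, `3` = 200, `2` = 300, `1` = 400)

#' Encode a stereoacuity threshold as a 0-4 level
#'
#' The random-dot stereo test has four plates at 100, 200, 300 and 400
#' seconds of arc; results are coded on a five-point scale where level 4 is
#' the finest threshold (100") and level 0 means no measurable stereopsis.
#'
#' @param arcsec Threshold in seconds of arc: one of 100, 200, 300, 400, or
#'   the string `"none"` (alternatively `NA` or `Inf`) for absent stereopsis.
#'   Vectorized; may mix numbers and `"none"` in a character vector.
#' @return Integer vector of levels in 0..4.
#' @examples
#' stereo_level(c(100, 400))
#' stereo_level("none")
#' @seealso [stereo_arcsec()] for the inverse.
#' @export
stereo_level <- function(arcsec) {
  if (is.character(arcsec)) {
    is_none <- !is.na(arcsec) & tolower(trimws(arcsec)) == "none"
    num <- suppressWarnings(as.numeric(arcsec))
    if (any(!is_none & is.na(num) & !is.na(arcsec))) {
      rlang::abort(
        "Stereoacuity must be 100/200/300/400 arcsec or \"none\".",
        class = "vc_domain_error"
      )
    }
    num[is_none] <- Inf
    arcsec <- num
  }
  out <- rep(NA_integer_, length(arcsec))
  none <- is.infinite(arcsec)
  out[none] <- 0L
  idx <- match(arcsec[!none & !is.na(arcsec)], .stereo_arcsec)
  if (anyNA(idx)) {
    rlang::abort(
      "Stereoacuity threshold must be one of 100, 200, 300, 400 arcsec (the test has exactly four plates).",
      class = "vc_domain_error"
    )
  }
  out[!none & !is.na(arcsec)] <- as.integer(names(.stereo_arcsec))[idx]
  out
}

#' Decode a stereoacuity level to its threshold in arcseconds
#'
#' Inverse of [stereo_level()]: levels 4..1 map back to 100/200/300/400
#' arcsec; level 0 returns `Inf` (no measurable stereopsis).
#'
#' @param level Integer vector of stereo levels in 0..4.
#' @return Numeric vector of thresholds in seconds of arc (`Inf` for level 0).
#' @export
stereo_arcsec <- function(level) {
  level <- check_level(level, 0L, 4L, "stereo level")
  out <- unname(.stereo_arcsec[as.character(level)])
  out[!is.na(level) & level == 0L] <- Inf
  out
}

# shared integer-grid validator: NA passes through, non-integers and
# out-of-range values are domain errors naming the offending scale
check_level <- function(x, lo, hi, what) {
  if (is.logical(x) && all(is.na(x))) x <- as.numeric(x)
  if (!is.numeric(x)) {
    rlang::abort(sprintf("%s must be numeric.", what), class = "vc_domain_error")
  }
  ok <- is.na(x) | (x >= lo & x <= hi & x == round(x))
  if (!all(ok)) {
    rlang::abort(
      sprintf("%s must be an integer in %d..%d (got %s).", what, lo, hi,
              paste(unique(x[!ok]), collapse = ", ")),
      class = "vc_domain_error"
    )
  }
  as.integer(round(x))
}
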