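#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CRITIC fit
#'
#' One row per indicator with every stage of the weighting chain: mean,
#' sample SD, variation coefficient, independence (conflict) coefficient,
#' information volume, and the final weight.
#'
#' @param x A `critic_fit` from [run_critic()].
#' @param ... Unused.
#' @return A tibble with columns `indicator`, `mean`, `sd`,
#'   `variation_coefficient`, `independence`, `information`, `weight`.
#' @method tidy critic_fit
#' @export
tidy.critic_fit <- function(x, ...) {
  dplyr::mutate(x$summaries,
                independence = unname(x$independence),
                information = unname(x$information),
                weight = unname(x$weights))
}

#' Glance at a CRITIC fit
#'
#' @param x A `critic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_subjects`, `n_indicators`, `convention`,
#'   `magnitude`, `max_weight_indicator`, `mean_abs_correlation`.
#' @method glance critic_fit
#' @export
glance.critic_fit <- function(x, ...) {
  off <- x$correlation[upper.tri(x$correlation)]
  tibble::tibble(
    n_subjects = x$m,
    n_indicators = x$n,
    convention = x$convention,
    magnitude = x$magnitude,
    max_weight_indicator = names(x$weights)[which.max(x$weights)],
    mean_abs_correlation = mean(abs(off))
  )
}

#' Plot CRITIC weights
#'
#' Bar chart of the fitted indicator weights, annotated with each
#' indicator's independence coefficient.
#'
#' @param object A `critic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot critic_fit
#' @export
autoplot.critic_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$indicator, -.data$weight),
    y = .data$weight
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("η = %.2f", .data$independence)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "CRITIC weight",
                  title = "Objective indicator weights",
                  subtitle = sprintf("%d subjects; convention = %s, magnitude = %s",
                                     object$m, object$convention, object$magnitude)) +
    ggplot2::theme_minimal()
}

#' Plot coupling indices
#'
#' Stacked per-indicator contributions to each subject's coupling index,
#' ordered by rank.
#'
#' @param object A `coupling_scores` tibble from [coupling_index()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coupling_scores
#' @export
autoplot.coupling_scores <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with("w_u_"),
    names_to = "indicator", values_to = "contribution",
    names_prefix = "w_u_"
  )
  long$subject_id <- stats::reorder(long$subject_id, -long$ci)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subject_id,
                                     y = .data$contribution,
                                     fill = .data$indicator)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "subject", y = "coupling index",
                  fill = "indicator",
                  title = "Coupling index and per-indicator contributions") +
    ggplot2::theme_minimal()
}

#' Plot paired-screening results
#'
#' Mean difference with a 95% confidence band per indicator; solid points
#' are indicators significant at the screening threshold.
#'
#' @param screening The tibble returned by [paired_screen()].
#' @return A ggplot object.
#' @export
plot_screening <- function(screening) {
  half <- stats::qt(0.975, df = screening$df) * screening$sd_diff /
    sqrt(screening$n)
  df <- dplyr::mutate(screening, lo = .data$mean_diff - half,
                      hi = .data$mean_diff + half)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$indicator, y = .data$mean_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                          shape = .data$significant)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = NULL, y = "mean post - pre difference",
                  shape = "significant",
                  title = "Paired-t screening of difference scores") +
    ggplot2::theme_minimal()
}
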