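#' Plot intraclass twin correlations by zygosity
#'
#' Point-and-errorbar display of MZ versus DZ intraclass correlations per
#' trait, the standard first look at a twin dataset: MZ points well above DZ
#' points indicate genetic influence; DZ above half the MZ value indicates
#' shared environment.
#'
#' @param icc A tibble as returned by [twin_correlations()] (columns `trait`,
#'   `zygosity`, `icc`, optionally `lower`/`upper`).
#' @return A ggplot object.
#' @export
plot_twin_correlations <- function(icc) {
  p <- ggplot2::ggplot(icc, ggplot2::aes(x = .data$trait, y = .data$icc,
                                         colour = .data$zygosity)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        size = 2.5)
  if (all(c("lower", "upper") %in% names(icc)) && !all(is.na(icc$lower))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      position = ggplot2::position_dodge(width = 0.4), width = 0.15)
  }
  p + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "intraclass twin correlation",
                  colour = "zygosity") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_twin_correlations Stacked-bar display of the standardized
#'   A/C/E shares of a structured fit.
#' @param object A `twin_fit` (structured) or `twin_decomposition`.
#' @param ... Unused.
#' @method autoplot twin_fit
#' @export
autoplot.twin_fit <- function(object, ...) {
  assert_that(!is.null(object$vc), "autoplot requires a structured fit")
  sh <- standardize_components(object$vc)
  long <- tidyr::pivot_longer(sh, -"trait", names_to = "component",
                              values_to = "share")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$share,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of variance (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_twin_correlations Stacked-bar display of the percent
#'   contributions of A, C and E to each phenotypic correlation.
#' @method autoplot twin_decomposition
#' @export
autoplot.twin_decomposition <- function(object, ...) {
  assert_that(!is.null(object$pairs),
              "decomposition has no trait pairs to plot")
  d <- dplyr::mutate(object$pairs,
                     pair = paste(.data$trait_i, "&", .data$trait_j))
  long <- tidyr::pivot_longer(d[, c("pair", "pct_A", "pct_C", "pct_E")],
                              -"pair", names_to = "component",
                              values_to = "pct")
  long$component <- sub("pct_", "", long$component)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$pct,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contribution to phenotypic correlation (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_twin_correlations Per-rung p-values of an assumption
#'   ladder against its significance level.
#' @method autoplot twin_ladder
#' @export
autoplot.twin_ladder <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$p), ]
  d$constraint <- factor(d$constraint, levels = d$constraint)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$constraint, y = .data$p)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "likelihood-ratio p-value") +
    ggplot2::theme_minimal()
}
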