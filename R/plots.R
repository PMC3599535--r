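#' Plot dN/dS distributions by age class
#'
#' Box plot of omega by (merged) age class, mirroring the usual presentation
#' of age-stratified rate distributions.
#'
#' @param rates Data frame with `age_class_merged` and `omega` (e.g. the
#'   `rates` component of a [run_analysis()] report); rows failing filters or
#'   with undefined omega are dropped.
#' @return A ggplot object.
#' @export
plot_omega_by_age <- function(rates) {
  d <- rates[!is.na(rates$omega), ]
  if ("pass_filter" %in% names(d)) d <- d[d$pass_filter, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_class_merged,
                                  y = .data$omega)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Domain age class", y = "dN/dS") +
    ggplot2::theme_minimal()
}

#' Plot positions of young domains within proteins
#'
#' Bar chart of N-terminal / internal / C-terminal counts per stratum
#' (2-domain vs >2-domain proteins).
#'
#' @param positions Tibble from [young_positions()].
#' @return A ggplot object.
#' @export
plot_positions <- function(positions) {
  d <- dplyr::mutate(positions, position = factor(
    .data$position, levels = c("N_terminal", "internal", "C_terminal")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~stratum, labeller = ggplot2::as_labeller(
      c("2" = "2 domains", ">2" = "> 2 domains"))) +
    ggplot2::labs(x = "Position of young domain", y = "Occurrences") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of within-protein relative dN/dS differences
#'
#' Histogram of (omega_young - omega_old) / max(omega_young, omega_old) over
#' within-protein comparisons; positive values mean the young domain evolves
#' faster.
#'
#' @param pairs The `pairs` component of a [run_analysis()] report.
#' @param binwidth Histogram bin width (default 0.1).
#' @return A ggplot object.
#' @export
plot_relative_difference <- function(pairs, binwidth = 0.1) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$relative_difference)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Relative dN/dS difference (young vs old)",
                  y = "Protein pairs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for analysis reports
#'
#' @param object A `domage_report`.
#' @param which One of `"omega"`, `"positions"`, `"pairs"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.domage_report <- function(object, which = c("omega", "positions",
                                                     "pairs"), ...) {
  which <- match.arg(which)
  switch(which,
         omega = plot_omega_by_age(object$rates),
         positions = plot_positions(object$positions),
         pairs = plot_relative_difference(object$pairs))
}
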