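# ggplot2 displays for the main result types.

#' Plot a siRNA size profile
#'
#' Side-by-side bars of read abundance by length and strand, the standard
#' display for hairpin-derived siRNA populations (dominant 21- and 24-nt
#' classes).
#'
#' @param profile A `size_profile` tibble from [size_profile()].
#' @param normalized Plot RPM (`TRUE`, default) or raw counts.
#' @return A ggplot object.
#' @export
plot_size_profile <- function(profile, normalized = TRUE) {
  y <- if (normalized) "rpm" else "count"
  ggplot2::ggplot(profile, ggplot2::aes(
    x = factor(.data$length), y = .data[[y]], fill = .data$strand
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "Read length (nt)",
      y = if (normalized) "Reads per million" else "Read count",
      fill = "Strand"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.size_profile <- function(object, ...) plot_size_profile(object, ...)

#' Plot a per-cytosine methylation profile
#'
#' Lollipop-style display of the methylated fraction at each cytosine,
#' colored by CG/CHG/CHH context. Positions suppressed by the noise floor
#' are omitted.
#'
#' @param profile A `methylation_profile` from [call_methylation()].
#' @return A ggplot object.
#' @export
plot_methylation_profile <- function(profile) {
  shown <- dplyr::filter(profile, !is.na(.data$fraction_methylated))
  ggplot2::ggplot(shown, ggplot2::aes(
    x = .data$position, y = .data$fraction_methylated,
    color = .data$context
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Position (nt)", y = "Methylated fraction",
                  color = "Context") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.methylation_profile <- function(object, ...) {
  plot_methylation_profile(object)
}

#' Plot ranked design stabilities
#'
#' Bar chart of predicted stem free energy per design, most stable first.
#'
#' @param ranked A ranked tibble from [rank_designs()] or [score_schemes()].
#' @return A ggplot object.
#' @export
plot_design_ranking <- function(ranked) {
  ggplot2::ggplot(ranked, ggplot2::aes(
    x = stats::reorder(.data$design_id, .data$rank), y = .data$delta_g
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = expression(Delta * G ~ "(kcal/mol)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
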