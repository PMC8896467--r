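#' Plot a mutational spectrum
#'
#' Bar chart of counts (or opportunity-normalised frequencies when
#' present) per substitution class, coloured by class; 96-context
#' spectra are faceted by class.
#'
#' @param spectrum A `spectrum_matrix`.
#' @param y `"count"` or `"frequency"` (the latter requires
#'   [normalized_frequency_spectrum()] output).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, y = c("count", "frequency")) {
  y <- match.arg(y)
  if (y == "frequency" && !"frequency" %in% names(spectrum)) {
    stop("spectrum has no frequency column; ",
         "run normalized_frequency_spectrum() first")
  }
  df <- tibble::as_tibble(spectrum)
  if (attr(spectrum, "context") == 96L) {
    df$class <- substr(df$category, 3L, 5L)
    df$context <- paste0(substr(df$category, 1L, 1L),
                         substr(df$category, 3L, 3L),
                         substr(df$category, 7L, 7L))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$context,
                                     y = .data[[y]],
                                     fill = .data$class)) +
      ggplot2::geom_col() +
      ggplot2::facet_grid(. ~ class, scales = "free_x") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(
        angle = 90, vjust = 0.5, size = 5),
        legend.position = "none") +
      ggplot2::labs(x = "trinucleotide context", y = y)
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                     y = .data[[y]],
                                     fill = .data$category)) +
      ggplot2::geom_col() +
      ggplot2::theme_minimal() +
      ggplot2::theme(legend.position = "none") +
      ggplot2::labs(x = "substitution class", y = y)
  }
}

#' Plot stratified mutation frequencies with Poisson intervals
#'
#' @param stratified Output of [stratified_frequency()].
#' @return A ggplot object.
#' @export
plot_mutation_frequency <- function(stratified) {
  ggplot2::ggplot(stratified,
                  ggplot2::aes(x = .data$stratum, y = .data$frequency)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "mutation frequency (subst./bp)")
}

#' Plot spike-in recovery: expected versus measured VAF
#'
#' Log-log scatter of nominal spiked fraction against measured duplex
#' VAF with the identity line; undetected variants are dropped.
#'
#' @param x A `spikein_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spikein_eval <- function(x, ...) {
  det <- x$table[x$table$detected & x$table$vaf > 0, , drop = FALSE]
  ggplot2::ggplot(det, ggplot2::aes(x = .data$fraction, y = .data$vaf)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "expected VAF (spiked fraction)",
                  y = "measured VAF (DCS)")
}

#' Plot a dN/dS randomization null with the observed ratio
#'
#' @param x A `dnds_null` object.
#' @param observed Optional observed dN/dS drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnds_null <- function(x, observed = NULL, ...) {
  p <- ggplot2::ggplot(tidy.dnds_null(x),
                       ggplot2::aes(x = .data$dnds)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70",
                            colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = x$null_median, linetype = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "dN/dS under the randomization null", y = "draws")
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red3")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
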