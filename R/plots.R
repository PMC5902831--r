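#' Plot allele-frequency spectra by functional class
#'
#' @param afs Output of [afs_by_class()] (or a single [afs_histogram()]).
#' @return A ggplot object.
#' @export
plot_afs <- function(afs) {
  ggplot2::ggplot(afs, ggplot2::aes(x = .data$lower + 0.025,
                                    y = .data$proportion,
                                    fill = .data$class_label)) +
    ggplot2::geom_col(position = "dodge", width = 0.045) +
    ggplot2::labs(x = "Alternate allele frequency",
                  y = "Proportion of variants", fill = "Class") +
    ggplot2::theme_minimal()
}

#' Plot genome-wide zHp with the sweep threshold
#'
#' @param sweeps Output of [zhp_scan()] (one or more lines row-bound).
#' @param z_threshold Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_zhp <- function(sweeps, z_threshold = .ls_defaults$zhp_threshold) {
  ggplot2::ggplot(sweeps, ggplot2::aes(x = .data$start / 1e6, y = .data$zHp,
                                       colour = .data$line)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = z_threshold, linetype = 2) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "zHp", colour = "Line") +
    ggplot2::theme_minimal()
}

#' Plot the recombination-rate vs deleterious/tolerated-ratio relationship
#'
#' @param x A `purging_cor` object.
#' @return A ggplot object.
#' @export
plot_purging <- function(x) {
  b <- x$bins[!is.na(x$bins$del_tol_ratio), ]
  ggplot2::ggplot(b, ggplot2::aes(x = .data$rate, y = .data$del_tol_ratio)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Recombination rate (cM/Mb)",
      y = "Deleterious / tolerated ratio",
      subtitle = paste0("Pearson r = ", signif(x$estimate, 3),
                        ", p = ", format(x$p_value, digits = 3))
    ) +
    ggplot2::theme_minimal()
}

#' Plot protein-position profiles
#'
#' @param profiles The `profiles` tibble of [position_profiles()].
#' @return A ggplot object.
#' @export
plot_position_profiles <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$bin, y = .data$proportion,
                                         fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "Protein decile (N- to C-terminus)",
                  y = "Proportion of variants", fill = "Class") +
    ggplot2::theme_minimal()
}

#' Plot coding vs non-coding indel-length spectra
#'
#' @param spectrum The `spectrum` tibble of [indel_length_spectrum()].
#' @return A ggplot object.
#' @export
plot_indel_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$length, y = .data$count,
                                         fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = 1:15) +
    ggplot2::labs(x = "Indel length (bp)", y = "Count", fill = "Region") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a deficit scan
#'
#' @param object A `dh_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dh_scan <- function(object, ...) {
  r <- object$results
  ggplot2::ggplot(r, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = 2) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Window midpoint (Mb)",
                  y = expression(-log[10](p)),
                  colour = paste0("p < ", object$params$alpha)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
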