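# ggplot2 display methods for the package's result types.

#' @rdname length_spectrum
#' @param object A `length_spectrum` tibble.
#' @param ... Unused.
#' @method autoplot length_spectrum
#' @export
autoplot.length_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Read length (nt)", y = "Reads",
                  title = "Small-RNA length distribution") +
    ggplot2::theme_minimal()
}

#' @rdname overlap_distribution
#' @param object An `overlap_distribution` tibble.
#' @param ... Unused.
#' @method autoplot overlap_distribution
#' @export
autoplot.overlap_distribution <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap, y = .data$fraction)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$overlap == 10), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "5'-5' overlap (nt)", y = "Fraction of pairs",
                  title = "Ping-pong overlap signature") +
    ggplot2::theme_minimal()
}

#' @rdname pingpong_signature
#' @param object A `pingpong_signature` object.
#' @method autoplot pingpong_signature
#' @export
autoplot.pingpong_signature <- function(object, ...) {
  p <- autoplot(object$distribution)
  if (is.finite(object$z)) {
    p <- p + ggplot2::annotate(
      "text", x = object$focal,
      y = max(object$distribution$fraction, na.rm = TRUE),
      label = sprintf("Z = %.1f", object$z), vjust = -0.4
    )
  }
  p
}

#' Plot per-superfamily divergence landscapes
#'
#' Faceted 1-percent-bin histograms of read-to-consensus divergence, the
#' standard visual for TE amplification history (a mass near 0 percent
#' indicates ongoing activity).
#'
#' @param hist Tibble from [divergence_histogram()].
#' @return A ggplot object.
#' @export
plot_divergence_landscape <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(width = 0.9, fill = "darkolivegreen4") +
    ggplot2::facet_wrap(~superfamily, scales = "free_y") +
    ggplot2::labs(x = "Divergence from consensus (%)", y = "Reads",
                  title = "TE amplification landscapes") +
    ggplot2::theme_minimal()
}

#' Plot pathway ratios against genome size
#'
#' @param ratios Tibble from [pathway_ratios()] with `genome_size_gb`.
#' @param ratio Unquoted ratio column to display.
#' @return A ggplot object.
#' @export
plot_ratio_vs_genome_size <- function(ratios, ratio = ratio_pirna) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$genome_size_gb, y = {{ ratio }},
                                       colour = .data$sex)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Genome size (Gb, log scale)",
                  y = "Pathway / miRNA-pathway expression ratio") +
    ggplot2::theme_minimal()
}
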