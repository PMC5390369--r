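#' Plot a gene-element methylation metaprofile
#'
#' One line per context across the 20 bins, faceted by element class.
#'
#' @param object A `meth_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_profile
#' @export
autoplot.meth_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin, y = .data$mean_ml,
                               colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$element)) +
    ggplot2::labs(x = "bin (5' → 3')", y = "mean corrected ML",
                  colour = "context") +
    ggplot2::theme_minimal()
}

#' Sequence-logo-style plot of a position frequency matrix
#'
#' Bar heights are base frequencies scaled by the column's information
#' content (bits), the usual logo representation of base preference
#' around a methylcytosine.
#'
#' @param object A `meth_pfm` from [build_pfm()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_pfm
#' @export
autoplot.meth_pfm <- function(object, ...) {
  d <- tidy(object) |>
    mutate(height = .data$freq * .data$ic)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$height,
                                  fill = .data$base)) +
    ggplot2::geom_col(position = "stack", width = 0.85) +
    ggplot2::labs(x = "offset from methylcytosine",
                  y = "information content (bits)", fill = "base") +
    ggplot2::theme_minimal()
}

#' Plot detected DMRs along the genome
#'
#' Signed methylation-level difference of each DMR at its midpoint,
#' coloured by direction and faceted by chromosome.
#'
#' @param object A `dmr_result` from [detect_dmrs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dmr_result
#' @export
autoplot.dmr_result <- function(object, ...) {
  d <- tidy(object) |>
    mutate(mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$delta_ml,
                                  colour = .data$direction,
                                  shape = .data$scope)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(Delta ~ "ML (B - A)"),
                  colour = "direction") +
    ggplot2::theme_minimal()
}
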