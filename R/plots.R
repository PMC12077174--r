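# ggplot2 displays for the result types.

#' Plot a consensus-stability curve
#'
#' Hamming distance to the all-reads consensus against the prefix subset
#' size; points where the subset consensus is identical to the expected one
#' are marked. The flattening of this curve is what the minimum-read rule
#' operationalizes.
#'
#' @param object A `stability_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subset_size, y = .data$hd)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$identical), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f0e"),
      name = "identical to\nexpected") +
    ggplot2::labs(x = "reads in prefix subset",
                  y = "Hamming distance to all-reads consensus") +
    ggplot2::theme_minimal()
}

#' Plot an identification-level cross-tabulation
#'
#' @param object An `id_crosstab`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.id_crosstab <- function(object, ...) {
  df <- tidy.id_crosstab(object)
  df$level_a <- factor(df$level_a, levels = id_levels())
  df$level_b <- factor(df$level_b, levels = id_levels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level_a, y = .data$level_b,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
                       colour = "black") +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "short-read arm (A)", y = "long-read arm (B)") +
    ggplot2::theme_minimal()
}

#' Plot per-column read depth of a frequency matrix
#'
#' @param object A `freq_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.freq_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::labs(x = "profile column", y = "reads covering column") +
    ggplot2::theme_minimal()
}
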