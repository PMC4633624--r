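#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a mutational spectrum
#'
#' @param object A `mutation_spectrum`.
#' @param collapse Plot the 6 collapsed base-pair classes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mutation_spectrum
#' @export
autoplot.mutation_spectrum <- function(object, collapse = FALSE, ...) {
  dat <- tidy(object, collapse = collapse)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$fraction,
                                    fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of substitutions", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-position corrected mutation fractions
#'
#' Corrected fractions along the amplicon with called positions
#' highlighted and the treatment-mean threshold drawn.
#'
#' @param object A `position_call_table` (called with [call_mutations()]
#'   first if needed).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot position_call_table
#' @export
autoplot.position_call_table <- function(object, ...) {
  if (!"called" %in% names(object)) object <- call_mutations(object)
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$corrected_frac)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$called), size = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "mean_corrected"),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "reference position", y = "corrected fraction mutated",
                  colour = "called") +
    ggplot2::theme_minimal()
}

#' Stacked plaque-phenotype bar chart
#'
#' @param object A `plaque_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plaque_result
#' @export
autoplot.plaque_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$.row), y = .data$n,
                                    fill = .data$phenotype)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(values = c(blue = "#3366cc",
                                          light_blue = "#99ccee",
                                          white = "grey90")) +
    ggplot2::labs(x = "assay", y = "fraction of plaques", fill = NULL) +
    ggplot2::theme_minimal()
}
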