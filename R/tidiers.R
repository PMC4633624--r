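#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mutational spectrum
#'
#' @param x A `mutation_spectrum`.
#' @param collapse Return the 6 collapsed classes instead of the 12
#'   strand-specific ones.
#' @param ... Unused.
#' @return A plain tibble of classes, counts and fractions.
#' @method tidy mutation_spectrum
#' @export
tidy.mutation_spectrum <- function(x, collapse = FALSE, ...) {
  if (collapse) x <- collapse_spectrum(x)
  tibble::as_tibble(x)
}

#' @rdname tidy.mutation_spectrum
#' @return `glance()`: one row with `total`, `n_transition`,
#'   `n_transversion`, `ts_tv_ratio`.
#' @method glance mutation_spectrum
#' @export
glance.mutation_spectrum <- function(x, ...) {
  ts <- sum(x$count[x$type == "transition"])
  tv <- sum(x$count[x$type == "transversion"])
  tibble::tibble(
    total = spectrum_total(x),
    n_transition = ts,
    n_transversion = tv,
    ts_tv_ratio = ifelse(tv > 0, ts / tv, NA_real_)
  )
}

#' Tidy a position-call table
#'
#' @param x A `position_call_table`.
#' @param ... Unused.
#' @return The per-position tibble.
#' @method tidy position_call_table
#' @export
tidy.position_call_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.position_call_table
#' @return `glance()`: one row with `n_positions`, `n_called`,
#'   `mean_corrected`, `sd_control`.
#' @method glance position_call_table
#' @export
glance.position_call_table <- function(x, ...) {
  tibble::tibble(
    n_positions = nrow(x),
    n_called = if ("called" %in% names(x)) sum(x$called) else NA_integer_,
    mean_corrected = attr(x, "mean_corrected"),
    sd_control = attr(x, "sd_control")
  )
}

#' Tidy a plaque-assay result
#'
#' @param x A `plaque_result`.
#' @param ... Unused.
#' @return Counts in long form (`phenotype`, `n`).
#' @method tidy plaque_result
#' @export
tidy.plaque_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("n_blue", "n_light_blue", "n_white")] |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::pivot_longer(-".row", names_to = "phenotype", values_to = "n",
                        names_prefix = "n_")
}

#' @rdname tidy.plaque_result
#' @return `glance()`: one row per assay with totals and the lacZ-minus
#'   fraction.
#' @method glance plaque_result
#' @export
glance.plaque_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("n_total", "lacz_minus_fraction")]
}
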