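#' A Poisson model of reporter-gene inactivation
#'
#' Links a per-bp substitution rate to the fraction of lacZ-inactive
#' (white or light-blue) plaques. Substitutions hit the `L_target`-bp
#' cassette as a Poisson process over `generations` rounds of copying, and
#' each substitution independently inactivates the gene with probability
#' `p_inactivating`; a plaque is lacZ-minus when at least one inactivating
#' hit occurred.
#'
#' `p_inactivating` is explicitly a user assumption (default 0.33: roughly,
#' nonsense plus frameshift-free missense knockouts among random
#' substitutions) and is surfaced in every report. `L_target` defaults to
#' 3,075 bp, the length of a standard lacZ open reading frame - a package
#' default, not a measured value.
#'
#' @param L_target Length of the reporter cassette in bp.
#' @param generations Rounds of genome copying per propagation.
#' @param p_inactivating Probability a substitution in the target
#'   inactivates it, in `(0, 1]`.
#' @return An `inactivation_model` list.
#' @export
inactivation_model <- function(L_target = 3075, generations = 1, p_inactivating = 0.33) {
  stopifnot(L_target >= 1, generations >= 0,
            p_inactivating > 0, p_inactivating <= 1)
  structure(list(L_target = L_target, generations = generations,
                 p_inactivating = p_inactivating),
            class = "inactivation_model")
}

#' @export
print.inactivation_model <- function(x, ...) {
  cat(sprintf("<inactivation_model: L = %g bp, g = %g, p_inactivating = %g (assumed)>\n",
              x$L_target, x$generations, x$p_inactivating))
  invisible(x)
}

#' Expected lacZ-minus plaque fraction at a given mutation rate
#'
#' `1 - exp(-mu_bp * L * g * p)` under the Poisson hit model.
#'
#' @param mu_bp Substitutions per bp per generation (>= 0, vectorised).
#' @param model An [inactivation_model()].
#' @return Expected fraction of white-or-light-blue plaques, in `[0, 1)`.
#' @examples
#' expected_lacz_minus(7.2e-5, inactivation_model()) # ~0.07
#' @export
expected_lacz_minus <- function(mu_bp, model = inactivation_model()) {
  stopifnot(inherits(model, "inactivation_model"))
  if (any(mu_bp < 0)) stop("mu_bp must be non-negative", call. = FALSE)
  1 - exp(-mu_bp * model$L_target * model$generations * model$p_inactivating)
}

#' Mutation rate from an observed lacZ-minus fraction
#'
#' Inverse of [expected_lacz_minus()]: `-ln(1 - fraction) / (L * g * p)`.
#' A fraction of 1 saturates the assay and leaves the rate unidentifiable.
#'
#' @param result A `plaque_result` from [summarize_plaques()], or a bare
#'   lacZ-minus fraction in `[0, 1)`.
#' @param model An [inactivation_model()].
#' @return Substitutions per bp per generation.
#' @export
rate_from_plaques <- function(result, model = inactivation_model()) {
  fraction <- if (inherits(result, "plaque_result")) result$lacz_minus_fraction
              else result
  if (any(fraction < 0 | fraction > 1)) {
    stop("lacZ-minus fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(fraction >= 1)) {
    stop("assay saturated (lacZ-minus fraction = 1): rate unidentifiable", call. = FALSE)
  }
  -log(1 - fraction) / (model$L_target * model$generations * model$p_inactivating)
}

#' Summarise blue/light-blue/white plaque counts
#'
#' Light-blue plaques are counted as lacZ-minus together with white ones;
#' the lacZ-minus fraction is their share of all plaques.
#'
#' @param n_blue,n_light_blue,n_white Plaque counts (>= 0, total > 0), or
#'   a data frame with those columns as the first argument.
#' @return A `plaque_result` tibble with the counts, `n_total` and
#'   `lacz_minus_fraction`.
#' @examples
#' summarize_plaques(73, 0, 27) # lacZ-minus fraction 0.27
#' @export
summarize_plaques <- function(n_blue, n_light_blue = NULL, n_white = NULL) {
  if (is.data.frame(n_blue)) {
    df <- n_blue
    need <- c("n_blue", "n_light_blue", "n_white")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0) {
      stop(sprintf("plaque table lacks column(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    n_blue <- df$n_blue; n_light_blue <- df$n_light_blue; n_white <- df$n_white
  }
  if (any(c(n_blue, n_light_blue, n_white) < 0)) {
    stop("plaque counts must be non-negative", call. = FALSE)
  }
  total <- n_blue + n_light_blue + n_white
  if (any(total == 0)) stop("no plaques counted: fraction undefined", call. = FALSE)
  out <- tibble::tibble(
    n_blue = n_blue, n_light_blue = n_light_blue, n_white = n_white,
    n_total = total,
    lacz_minus_fraction = (n_white + n_light_blue) / total
  )
  structure(out, class = c("plaque_result", class(out)))
}
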