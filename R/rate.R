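#' Default assay constants
#'
#' Constants used throughout the rate-estimation functions unless
#' overridden: the number of distinct rpoB sites conferring rifampin
#' resistance (`R = 77`), the population size at which resistance first
#' becomes observable (`N0 = 1.5e7`), and the E. coli MG1655 genome length
#' (`4.64e6` bp). All are arguments everywhere they are used.
#'
#' @return A named list with elements `R`, `N0`, `genome_len`.
#' @export
assay_defaults <- function() {
  list(R = 77, N0 = 1.5e7, genome_len = 4.64e6)
}

#' Per-base-pair mutation rate from a reporter fluctuation assay
#'
#' The frequency-based estimator
#' \deqn{\mu_{bp} = f / (R \, \ln(N/N_0))}
#' where `f` is the frequency of resistant mutants relative to the
#' non-selective control, `R` the number of distinct nucleotide sites that
#' confer resistance, `N` the final population size and `N0` the population
#' size at which resistance first becomes observable. Closed form, no
#' iteration.
#'
#' @param f Resistant-mutant frequency in `[0, 1]` (vectorised).
#' @param R Number of resistance sites (>= 1).
#' @param N Final population size.
#' @param N0 Population size at first observable resistance; must satisfy
#'   `N > N0 > 0`.
#' @return Substitutions per bp per generation.
#' @examples
#' estimate_mu_bp(2.005e-3, R = 77, N = 1e9, N0 = 1.5e7) # ~6.2e-6
#' @export
estimate_mu_bp <- function(f, R = assay_defaults()$R, N, N0 = assay_defaults()$N0) {
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  if (any(R < 1)) stop("R must be >= 1", call. = FALSE)
  if (any(N0 <= 0)) stop("N0 must be positive", call. = FALSE)
  if (any(N <= N0)) {
    stop("growth undefined: final population N must exceed N0", call. = FALSE)
  }
  f / (R * log(N / N0))
}

#' Per-genome mutation rate
#'
#' @param mu_bp Substitutions per bp per generation (>= 0).
#' @param genome_len Genome length in bp (> 0).
#' @return Substitutions per genome per generation.
#' @examples
#' genome_rate(6.2e-6, 4.64e6) # ~28.8, i.e. ~29 per genome per generation
#' @export
genome_rate <- function(mu_bp, genome_len = assay_defaults()$genome_len) {
  if (any(mu_bp < 0)) stop("mu_bp must be non-negative", call. = FALSE)
  if (any(genome_len <= 0)) stop("genome_len must be positive", call. = FALSE)
  mu_bp * genome_len
}

#' Fold change between two rates
#'
#' @param numerator,denominator Rates; `denominator` must be positive.
#' @return `numerator / denominator`.
#' @export
fold_change <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("fold change undefined: denominator must be positive", call. = FALSE)
  }
  numerator / denominator
}

#' Dynamic range of an inducible mutator
#'
#' Fold change of the induced over the uninduced rate.
#'
#' @param induced,uninduced Rates.
#' @return `induced / uninduced`.
#' @export
dynamic_range <- function(induced, uninduced) {
  fold_change(induced, uninduced)
}

#' Expected mutations per generation falling in essential genes
#'
#' @param mu_g Substitutions per genome per generation.
#' @param essential_fraction Fraction of the genome that is essential, in
#'   `[0, 1]` (for E. coli, estimates span roughly 0.10-0.30).
#' @return Mutations in essential genes per generation.
#' @examples
#' essential_load(1.9, 0.30) # ~0.57
#' @export
essential_load <- function(mu_g, essential_fraction) {
  if (any(essential_fraction < 0 | essential_fraction > 1)) {
    stop("essential_fraction must lie in [0, 1]", call. = FALSE)
  }
  mu_g * essential_fraction
}

#' Dilution-corrected marker frequency
#'
#' Frequency of a selectable or screenable marker (resistant colonies, blue
#' colonies, ...) relative to the total population, with independent plating
#' dilutions for the marker and total counts. A frequency above 1 after
#' dilution correction signals a bookkeeping error and raises rather than
#' clamping.
#'
#' @param counts_marker,counts_total Colony/plaque counts (>= 0).
#' @param dilution_marker,dilution_total Multiplicative dilution-correction
#'   factors applied to each count (> 0).
#' @return Frequency in `[0, 1]`.
#' @export
marker_frequency <- function(counts_marker, counts_total,
                             dilution_marker = 1, dilution_total = 1) {
  if (any(counts_marker < 0) || any(counts_total < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(dilution_marker <= 0) || any(dilution_total <= 0)) {
    stop("dilutions must be positive", call. = FALSE)
  }
  total <- counts_total * dilution_total
  if (any(total == 0)) {
    stop("frequency undefined: implied total population is zero", call. = FALSE)
  }
  f <- (counts_marker * dilution_marker) / total
  if (any(f > 1)) {
    stop(sprintf(
      "marker frequency %.3g exceeds 1 after dilution correction; check the dilution factors",
      max(f)), call. = FALSE)
  }
  f
}

#' Estimate mutation rates from a colony-count table
#'
#' The tidy front end to the fluctuation-assay estimator: takes one row per
#' sample with selective and non-selective colony counts and dilutions,
#' computes the resistant frequency `f`, the per-bp rate `mu_bp` and the
#' per-genome rate `mu_g`, and (optionally) fold change versus a named
#' baseline condition.
#'
#' @param counts Data frame with columns `sample_id`, `condition`,
#'   `colonies_selective`, `dilution_selective`, `colonies_nonselective`,
#'   `dilution_nonselective`, and a column `N` (final population size) or a
#'   single `N` passed as an argument.
#' @param R,N0,genome_len Assay constants, see [assay_defaults()].
#' @param N Final population size used for rows lacking an `N` column.
#' @param baseline Optional `condition` value used as the fold-change
#'   denominator (its mean `mu_bp` is used). With no baseline the `fold`
#'   column is omitted.
#' @return A tibble with one row per sample: the input identifiers plus
#'   `f`, `mu_bp`, `mu_g` (and `fold` when a baseline is given).
#' @export
estimate_rates <- function(counts, R = assay_defaults()$R,
                           N0 = assay_defaults()$N0,
                           genome_len = assay_defaults()$genome_len,
                           N = NULL, baseline = NULL) {
  need <- c("sample_id", "condition", "colonies_selective", "dilution_selective",
            "colonies_nonselective", "dilution_nonselective")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    stop(sprintf("colony-count table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(counts) == 0) stop("colony-count table is empty", call. = FALSE)
  if (!"N" %in% names(counts)) {
    if (is.null(N)) stop("supply a final population size N (column or argument)",
                         call. = FALSE)
    counts$N <- N
  }
  out <- counts |>
    tibble::as_tibble() |>
    dplyr::mutate(
      f = marker_frequency(.data$colonies_selective, .data$colonies_nonselective,
                           .data$dilution_selective, .data$dilution_nonselective),
      mu_bp = estimate_mu_bp(.data$f, R = R, N = .data$N, N0 = N0),
      mu_g = genome_rate(.data$mu_bp, genome_len)
    )
  if (!is.null(baseline)) {
    if (!baseline %in% out$condition) {
      warning(sprintf("baseline condition '%s' absent; fold column omitted", baseline),
              call. = FALSE)
    } else {
      base_mu <- mean(out$mu_bp[out$condition == baseline])
      out <- dplyr::mutate(out, fold = fold_change(.data$mu_bp, base_mu))
    }
  }
  out
}

#' Format a rate for reports
#'
#' Per-genome and per-bp rates are displayed at 2 significant figures in all
#' reports; full precision is retained in the underlying tibbles.
#'
#' @param x Numeric rates.
#' @return Character vector.
#' @export
format_rate <- function(x) {
  formatC(signif(x, 2), format = "g", digits = 2)
}
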