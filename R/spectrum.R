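#' The twelve strand-specific substitution classes
#'
#' A point substitution on double-stranded DNA can be recorded strand
#' specifically (12 ordered classes such as `C>T`) or collapsed with its
#' reverse complement into one of 6 base-pair classes (such as `G:C>A:T`).
#' Collapsed labels are written purine-first on the reference pair, the
#' convention used for bacterial mutation-reporter spectra; e.g. `C>T` and
#' `G>A` both belong to `G:C>A:T`.
#'
#' @return A tibble with one row per strand-specific class and columns
#'   `class` (e.g. `"C>T"`), `ref`, `alt`, `collapsed` (one of the 6
#'   pair labels), and `type` (`"transition"` or `"transversion"`).
#' @examples
#' mutation_classes()
#' @export
mutation_classes <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  tbl <- tibble::tibble(
    class = paste0(grid$ref, ">", grid$alt),
    ref = grid$ref,
    alt = grid$alt,
    collapsed = collapsed_label(grid$ref, grid$alt),
    type = ifelse(is_transition(grid$ref, grid$alt), "transition", "transversion")
  )
  dplyr::arrange(tbl, .data$collapsed, .data$class)
}

#' @rdname mutation_classes
#' @return `collapsed_classes()`: character vector of the 6 canonical
#'   base-pair labels.
#' @export
collapsed_classes <- function() {
  unique(mutation_classes()$collapsed)
}

comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}

is_transition <- function(ref, alt) {
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine)
}

collapsed_label <- function(ref, alt) {
  # purine-first on the reference pair; the alt pair keeps strand correspondence
  flip <- !(ref %in% c("A", "G"))
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  paste0(r, ":", comp_base(r), ">", a, ":", comp_base(a))
}

check_bases <- function(ref, alt, where = "substitution") {
  bases <- c("A", "C", "G", "T")
  bad <- !(ref %in% bases) | !(alt %in% bases)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "invalid %s at index %d: ref='%s', alt='%s' (bases must be one of A/C/G/T; ambiguity codes are rejected, pre-filter them)",
      where, i, ref[i], alt[i]
    ), call. = FALSE)
  }
  same <- ref == alt
  if (any(same)) {
    i <- which(same)[1]
    stop(sprintf(
      "invalid %s at index %d: ref and alt are both '%s'",
      where, i, ref[i]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify a base substitution
#'
#' @param ref,alt Single upper-case DNA bases (vectorised).
#' @param collapse If `TRUE`, return only the 6 complement-collapsed
#'   pair labels in the `class` column; the strand-specific label is kept
#'   in `strand_class`.
#' @return A tibble with columns `class`, `ref`, `alt`, `collapsed`, `type`
#'   (and `strand_class` when `collapse = TRUE`).
#' @examples
#' classify_substitution("C", "T")
#' classify_substitution(c("C", "G"), c("T", "A"), collapse = TRUE)
#' @export
classify_substitution <- function(ref, alt, collapse = FALSE) {
  stopifnot(length(ref) == length(alt))
  check_bases(ref, alt)
  out <- tibble::tibble(
    class = paste0(ref, ">", alt),
    ref = ref,
    alt = alt,
    collapsed = collapsed_label(ref, alt),
    type = ifelse(is_transition(ref, alt), "transition", "transversion")
  )
  if (collapse) {
    out <- dplyr::mutate(out,
      strand_class = .data$class,
      class = .data$collapsed, .after = 0
    )
  }
  out
}

#' Normalise a collapsed-class label to the canonical purine-first form
#'
#' Accepts the alternate pyrimidine-first orderings and unicode arrows seen
#' in the literature (e.g. `"C:G→T:A"` is the same class as `"G:C>A:T"`).
#'
#' @param label Character vector of collapsed labels.
#' @return Canonical labels as in [collapsed_classes()].
#' @export
normalize_collapsed_label <- function(label) {
  x <- gsub("→", ">", label)
  x <- gsub("\\s", "", x)
  m <- regmatches(x, regexec("^([ACGT]):([ACGT])>([ACGT]):([ACGT])$", x))
  vapply(seq_along(x), function(i) {
    p <- m[[i]]
    if (length(p) != 5) {
      stop(sprintf("cannot parse collapsed class label '%s'", label[i]), call. = FALSE)
    }
    ref <- p[2]; alt <- p[4]
    if (comp_base(p[2]) != p[3] || comp_base(p[4]) != p[5]) {
      stop(sprintf("'%s' is not a valid base-pair class label", label[i]), call. = FALSE)
    }
    collapsed_label(ref, alt)
  }, character(1))
}

#' Build a mutational spectrum from substitution pairs
#'
#' Tallies observed substitutions over the 12 strand-specific classes.
#' The input is either a data frame with `ref` and `alt` columns (the
#' usual tidy route: any table of substitution records works) or two
#' character vectors.
#'
#' @param x Data frame with columns `ref` and `alt`, or a character vector
#'   of reference bases.
#' @param alt Alternate bases when `x` is a character vector.
#' @return A `mutation_spectrum`: a tibble with one row per strand-specific
#'   class and columns `class`, `ref`, `alt`, `collapsed`, `type`, `count`,
#'   `fraction`, plus a `total` attribute. Fractions are `NA` when the
#'   total is zero.
#' @examples
#' mutation_spectrum(c("C", "G", "C"), c("T", "A", "A"))
#' @export
mutation_spectrum <- function(x, alt = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("ref", "alt") %in% names(x))) {
      stop("substitution table must have 'ref' and 'alt' columns", call. = FALSE)
    }
    ref <- as.character(x$ref)
    alt <- as.character(x$alt)
  } else {
    ref <- as.character(x)
    alt <- as.character(alt)
  }
  stopifnot(length(ref) == length(alt))
  if (length(ref) > 0) check_bases(ref, alt)
  n_obs <- length(ref)
  template <- mutation_classes()
  obs <- table(factor(paste0(ref, ">", alt), levels = template$class))
  spec <- dplyr::mutate(template,
    count = as.integer(obs[.data$class]),
    fraction = if (n_obs > 0) .data$count / n_obs else NA_real_
  )
  new_mutation_spectrum(spec, total = n_obs)
}

new_mutation_spectrum <- function(tbl, total) {
  structure(tbl, total = as.integer(total),
            class = c("mutation_spectrum", class(tibble::as_tibble(tbl))))
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("<mutation_spectrum: %d substitutions over %d classes>\n",
              attr(x, "total"), nrow(x)))
  NextMethod()
}

#' Total number of substitutions in a spectrum
#' @param spectrum A `mutation_spectrum`.
#' @return Integer count.
#' @export
spectrum_total <- function(spectrum) {
  attr(spectrum, "total")
}

#' Collapse a strand-specific spectrum to the 6 base-pair classes
#'
#' Complementary strand-specific counts (e.g. `C>T` and `G>A`) are summed
#' into their shared base-pair class.
#'
#' @param spectrum A 12-class `mutation_spectrum`.
#' @return A 6-row tibble with `class`, `type`, `count`, `fraction` and the
#'   same `total` attribute.
#' @export
collapse_spectrum <- function(spectrum) {
  out <- spectrum |>
    tibble::as_tibble() |>
    dplyr::group_by(class = .data$collapsed, type = .data$type) |>
    dplyr::summarise(count = sum(.data$count), fraction = sum(.data$fraction),
                     .groups = "drop") |>
    dplyr::arrange(class)
  new_mutation_spectrum(out, total = spectrum_total(spectrum))
}

#' Total-variation distance between two spectra
#'
#' `0.5 * sum(|a_i - b_i|)` over the 12 strand-specific class fractions;
#' 0 for identical spectra, 1 for spectra with disjoint support.
#'
#' @param a,b `mutation_spectrum` objects with total > 0, or any data frames
#'   with `class` and `fraction` columns over the same classes.
#' @return A number in `[0, 1]`.
#' @export
spectrum_distance <- function(a, b) {
  fa <- spectrum_fractions(a)
  fb <- spectrum_fractions(b)
  if (!identical(names(fa), names(fb))) {
    stop("spectra are over different class sets", call. = FALSE)
  }
  0.5 * sum(abs(fa - fb))
}

spectrum_fractions <- function(s) {
  if (any(is.na(s$fraction))) {
    stop("spectrum distance is undefined for an empty spectrum (total = 0)",
         call. = FALSE)
  }
  stats::setNames(s$fraction, s$class)
}

#' Read a substitution table from TSV
#'
#' Expects columns `position`, `ref`, `alt`; extra columns are kept.
#' Lines starting with `#` are treated as comments.
#'
#' @param path File path.
#' @return A tibble of substitution records.
#' @export
read_substitutions_tsv <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("position", "ref", "alt")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop(sprintf("substitution TSV %s lacks column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  tbl
}

#' Write a spectrum (or any result tibble) as schema-tagged TSV
#'
#' Output carries a `# schema: mutascope/1` comment line followed by a
#' header row, so reports are self-describing.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  writeLines("# schema: mutascope/1", path)
  readr::write_tsv(tibble::as_tibble(x), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a schema-tagged TSV report
#' @param path File path.
#' @return A tibble.
#' @export
read_tsv_report <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
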