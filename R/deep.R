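#' Mask low-quality bases and drop short reads
#'
#' Implements the quality filter as per-base masking: every base whose
#' Phred score is below `q_min` is replaced by `N` and excluded from all
#' downstream counts. Reads whose unmasked length falls below `min_len`
#' are dropped. A per-read mean-quality mode is available for comparison
#' (`mode = "read_mean"` drops whole reads with mean Phred < `q_min` and
#' masks nothing).
#'
#' @param reads Tibble with `read_id`, `seq`, `qual` (and optionally
#'   `offset`, `pair_id`), as from [read_fastq()] or [simulate_reads()].
#' @param q_min Minimum Phred score (default 30, i.e. >= 99.9% base
#'   accuracy).
#' @param min_len Minimum number of unmasked bases for a read to be kept.
#' @param mode `"base"` (default, per-base masking) or `"read_mean"`.
#' @return The filtered reads with `seq` masked, plus columns `n_masked`
#'   and `n_unmasked`; filter statistics are attached as the
#'   `"filter_stats"` attribute.
#' @export
quality_filter <- function(reads, q_min = 30, min_len = 20, mode = c("base", "read_mean")) {
  mode <- match.arg(mode)
  stopifnot(q_min >= 0)
  bad_len <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad_len)) {
    stop(sprintf("malformed read '%s': sequence and quality lengths differ",
                 reads$read_id[which(bad_len)[1]]), call. = FALSE)
  }
  quals <- phred_to_int(reads$qual)
  if (mode == "read_mean") {
    keep <- vapply(quals, mean, numeric(1)) >= q_min
    out <- reads[keep, , drop = FALSE]
    out$n_masked <- 0L
    out$n_unmasked <- nchar(out$seq)
  } else {
    masked_seq <- vapply(seq_len(nrow(reads)), function(i) {
      b <- strsplit(reads$seq[i], "")[[1]]
      b[quals[[i]] < q_min] <- "N"
      paste(b, collapse = "")
    }, character(1))
    n_masked <- vapply(quals, function(q) sum(q < q_min), integer(1))
    out <- reads
    out$seq <- masked_seq
    out$n_masked <- n_masked
    out$n_unmasked <- nchar(out$seq) - n_masked
    out <- out[out$n_unmasked >= min_len, , drop = FALSE]
  }
  stats <- list(
    n_in = nrow(reads), n_kept = nrow(out),
    bases_in = sum(nchar(reads$seq)),
    bases_masked = if (mode == "base") sum(out$n_masked) else 0L,
    q_min = q_min, mode = mode
  )
  attr(out, "filter_stats") <- stats
  out
}

reads_to_bases <- function(reads, ref_len) {
  if (!"offset" %in% names(reads)) {
    stop("reads lack an 'offset' column (0-based reference offset); join the offset sidecar or use read_sam_alignments()",
         call. = FALSE)
  }
  lens <- nchar(reads$seq)
  if (any(reads$offset < 0 | reads$offset + lens > ref_len)) {
    i <- which(reads$offset < 0 | reads$offset + lens > ref_len)[1]
    stop(sprintf("read '%s' overhangs the reference (offset %d, length %d, reference %d bp)",
                 reads$read_id[i], reads$offset[i], lens[i], ref_len), call. = FALSE)
  }
  base <- unlist(strsplit(reads$seq, ""), use.names = FALSE)
  tbl <- tibble::tibble(
    position = rep(reads$offset, lens) + sequence(lens),
    base = base
  )
  if ("pair_id" %in% names(reads)) {
    # paired reads covering the same position in one fragment count once
    tbl$pair_id <- rep(reads$pair_id, lens)
    tbl <- dplyr::distinct(tbl, .data$pair_id, .data$position, .keep_all = TRUE)
  }
  tbl[tbl$base != "N", c("position", "base")]
}

#' Per-position deviation fractions for an amplicon
#'
#' Counts, at every reference position, the unmasked bases observed and the
#' fraction of them that differ from the reference base. Reads must carry a
#' 0-based `offset` (from the synthetic-read sidecar or a SAM alignment);
#' alignments are substitution-only by construction.
#'
#' @param reads Masked reads from [quality_filter()], with `offset`.
#' @param ref_seq Reference amplicon sequence.
#' @return A tibble with one row per reference position: `position`, `ref`,
#'   `depth`, per-base counts `n_A` ... `n_T`, `dev_frac` (NA where depth
#'   is zero) and `covered`.
#' @export
per_position_fractions <- function(reads, ref_seq) {
  ref <- toupper(as.character(ref_seq))
  ref_b <- strsplit(ref, "")[[1]]
  L <- length(ref_b)
  bases <- reads_to_bases(reads, L)
  counts <- bases |>
    dplyr::count(.data$position, .data$base) |>
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  for (b in c("n_A", "n_C", "n_G", "n_T")) {
    if (!b %in% names(counts)) counts[[b]] <- 0L
  }
  out <- tibble::tibble(position = seq_len(L), ref = ref_b) |>
    dplyr::left_join(counts, by = "position") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"), ~ tidyr::replace_na(.x, 0L)))
  mat <- as.matrix(out[, c("n_A", "n_C", "n_G", "n_T")])
  depth <- rowSums(mat)
  ref_count <- mat[cbind(seq_len(L), match(ref_b, c("A", "C", "G", "T")))]
  out |>
    dplyr::mutate(
      depth = as.integer(depth),
      dev_frac = ifelse(depth > 0, (depth - ref_count) / depth, NA_real_),
      covered = depth > 0
    ) |>
    dplyr::select("position", "ref", "depth", dplyr::starts_with("n_"),
                  "dev_frac", "covered")
}

#' Background-subtracted per-position mutation fractions
#'
#' Subtracts the unmutagenised control's per-position deviation fraction
#' from the sample's, flooring at zero (a negative mutation fraction is
#' meaningless and would distort the treatment mean). Also computes the two
#' table-level statistics the call rule needs: `mean_corrected`, the mean
#' corrected fraction over all covered positions, and `sd_control`, the
#' standard deviation of the control's per-position deviation fractions.
#'
#' @param sample_table,control_table Per-position tables from
#'   [per_position_fractions()] over the same reference.
#' @return A `position_call_table`: per-position tibble with
#'   `dev_frac_sample`, `dev_frac_control`, `corrected_frac`, the sample
#'   base counts, and attributes `mean_corrected`, `sd_control`.
#' @export
corrected_fraction <- function(sample_table, control_table) {
  if (nrow(sample_table) != nrow(control_table) ||
      any(sample_table$position != control_table$position) ||
      any(sample_table$ref != control_table$ref)) {
    stop("sample and control tables must cover identical positions of the same reference",
         call. = FALSE)
  }
  tbl <- tibble::tibble(
    position = sample_table$position,
    ref = sample_table$ref,
    depth_sample = sample_table$depth,
    depth_control = control_table$depth,
    n_A = sample_table$n_A, n_C = sample_table$n_C,
    n_G = sample_table$n_G, n_T = sample_table$n_T,
    dev_frac_sample = sample_table$dev_frac,
    dev_frac_control = control_table$dev_frac,
    corrected_frac = pmax(0, sample_table$dev_frac - control_table$dev_frac)
  )
  structure(tbl,
    mean_corrected = mean(tbl$corrected_frac, na.rm = TRUE),
    sd_control = stats::sd(tbl$dev_frac_control[!is.na(tbl$dev_frac_control)]),
    class = c("position_call_table", class(tbl))
  )
}

#' @export
print.position_call_table <- function(x, ...) {
  cat(sprintf("<position_call_table: %d positions, mean corrected fraction %.3g, control s.d. %.3g>\n",
              nrow(x), attr(x, "mean_corrected"), attr(x, "sd_control")))
  NextMethod()
}

#' Call mutated positions from a corrected-fraction table
#'
#' A position is called mutated when its corrected fraction is both
#' (a) greater than the mean corrected fraction of the treatment and
#' (b) more than one standard deviation above the control's deviation
#' fraction at that position (`corrected_frac > dev_frac_control +
#' sd_control`, with `sd_control` the across-position dispersion of the
#' control). Each called position is annotated with its dominant alternate
#' base (highest sample count among non-reference bases; alphabetical
#' tie-break) for spectrum aggregation.
#'
#' @param table A `position_call_table` from [corrected_fraction()].
#' @return The table with `called` and `dominant_alt` columns added.
#' @export
call_mutations <- function(table) {
  if (nrow(table) == 0) stop("cannot call mutations on an empty table", call. = FALSE)
  mean_corrected <- attr(table, "mean_corrected")
  sd_control <- attr(table, "sd_control")
  if (is.null(mean_corrected) || is.null(sd_control)) {
    stop("table lacks mean_corrected/sd_control; build it with corrected_fraction()",
         call. = FALSE)
  }
  alt_base <- dominant_alt(table)
  out <- dplyr::mutate(tibble::as_tibble(table),
    called = !is.na(.data$corrected_frac) &
      .data$corrected_frac > mean_corrected &
      .data$corrected_frac > .data$dev_frac_control + sd_control,
    dominant_alt = ifelse(.data$called, alt_base, NA_character_)
  )
  structure(out, mean_corrected = mean_corrected, sd_control = sd_control,
            class = c("position_call_table", class(tibble::as_tibble(out))))
}

dominant_alt <- function(table) {
  bases <- c("A", "C", "G", "T")
  mat <- as.matrix(table[, paste0("n_", bases)])
  mat[cbind(seq_len(nrow(table)), match(table$ref, bases))] <- -1L
  top <- max.col(mat, ties.method = "first")
  alt <- bases[top]
  alt[apply(mat, 1, max) <= 0] <- NA_character_
  alt
}

#' Called positions from a table
#'
#' @param table Output of [call_mutations()].
#' @return Rows of the table where `called` is `TRUE`.
#' @export
called_positions <- function(table) {
  if (!"called" %in% names(table)) table <- call_mutations(table)
  dplyr::filter(tibble::as_tibble(table), .data$called)
}

#' Mutational spectrum of the called positions
#'
#' Tallies (reference base -> dominant alternate base) over called
#' positions into a 12-class spectrum.
#'
#' @param table Output of [call_mutations()] (or a `position_call_table`,
#'   which is called first).
#' @return A `mutation_spectrum`; all-zero with total 0 when nothing is
#'   called.
#' @export
spectrum_from_calls <- function(table) {
  calls <- called_positions(table)
  calls <- calls[!is.na(calls$dominant_alt), , drop = FALSE]
  mutation_spectrum(calls$ref, calls$dominant_alt)
}

#' Full deep-sequencing mutation-calling pipeline
#'
#' Quality-filters sample and control reads, computes per-position
#' deviation fractions against the reference, background-subtracts, and
#' applies the call rule.
#'
#' @param sample_reads,control_reads Read tibbles (`read_id`, `seq`,
#'   `qual`, `offset`).
#' @param ref_seq Reference amplicon sequence.
#' @param q_min,min_len Quality-filter settings, see [quality_filter()].
#' @return A called `position_call_table`.
#' @export
deep_call_pipeline <- function(sample_reads, control_reads, ref_seq,
                               q_min = 30, min_len = 20) {
  s <- quality_filter(sample_reads, q_min = q_min, min_len = min_len)
  c <- quality_filter(control_reads, q_min = q_min, min_len = min_len)
  st <- per_position_fractions(s, ref_seq)
  ct <- per_position_fractions(c, ref_seq)
  call_mutations(corrected_fraction(st, ct))
}
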