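#' Substitutions between a clone and its reference
#'
#' Position-wise comparison of a single Sanger-style clone sequence against
#' the reference amplicon. Sequences must be the same length; clones with
#' indels should first be screened with [has_indels()] (the assay sequences
#' are fixed-length amplicons, so gapped clones are rejected rather than
#' genotyped).
#'
#' @param clone_seq,ref_seq DNA sequences as single strings (or objects
#'   coercible via `as.character`).
#' @param clone_id Optional identifier stored in the output.
#' @return A tibble with columns `clone_id` (if given), `position`
#'   (1-based on the reference), `ref`, `alt`, sorted by position.
#' @examples
#' diff_clone("ACGTT", "ACGTA")
#' @export
diff_clone <- function(clone_seq, ref_seq, clone_id = NULL) {
  clone <- toupper(as.character(clone_seq))
  ref <- toupper(as.character(ref_seq))
  if (nchar(clone) != nchar(ref)) {
    stop(sprintf(
      "clone length (%d) differs from reference length (%d); position-wise diff needs equal lengths - screen for indels with has_indels() and exclude gapped clones",
      nchar(clone), nchar(ref)), call. = FALSE)
  }
  cb <- strsplit(clone, "")[[1]]
  rb <- strsplit(ref, "")[[1]]
  ok <- c("A", "C", "G", "T")
  if (!all(cb %in% ok) || !all(rb %in% ok)) {
    stop("sequences contain non-ACGT characters", call. = FALSE)
  }
  pos <- which(cb != rb)
  out <- tibble::tibble(position = pos, ref = rb[pos], alt = cb[pos])
  if (!is.null(clone_id)) out <- dplyr::mutate(out, clone_id = clone_id, .before = 1)
  out
}

#' Substitutions for a set of clones
#'
#' @param clones Named character vector, named list of sequences, or a
#'   `Biostrings::DNAStringSet` (e.g. from [read_fasta()]).
#' @param ref_seq Reference sequence.
#' @return Tibble of substitution records for all clones, with `clone_id`.
#' @export
diff_clones <- function(clones, ref_seq) {
  seqs <- as.character(clones)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("clone_", seq_along(seqs))
  purrr::map2_dfr(seqs, ids, function(s, id) diff_clone(s, ref_seq, clone_id = id))
}

#' Apply substitutions to a reference sequence
#'
#' Inverse of [diff_clone()]: writing each record's `alt` at its `position`
#' reconstructs the clone.
#'
#' @param ref_seq Reference sequence.
#' @param subs Tibble with `position`, `ref`, `alt`.
#' @return The mutated sequence as a single string.
#' @export
apply_substitutions <- function(ref_seq, subs) {
  b <- strsplit(toupper(as.character(ref_seq)), "")[[1]]
  if (nrow(subs) > 0) {
    if (any(subs$position < 1 | subs$position > length(b))) {
      stop("substitution position outside the reference", call. = FALSE)
    }
    if (any(b[subs$position] != subs$ref)) {
      stop("substitution ref base disagrees with the reference sequence", call. = FALSE)
    }
    b[subs$position] <- subs$alt
  }
  paste(b, collapse = "")
}

#' Detect indels between a clone and the reference by global alignment
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2) used
#' only to reject clones carrying insertions or deletions; indel genotyping
#' is out of scope.
#'
#' @param clone_seq,ref_seq DNA sequences.
#' @return `TRUE` if the optimal alignment contains any gap.
#' @export
has_indels <- function(clone_seq, ref_seq) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(clone_seq)),
    Biostrings::DNAString(as.character(ref_seq)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  Biostrings::nindel(aln)@insertion[1, "Length"] > 0 ||
    Biostrings::nindel(aln)@deletion[1, "Length"] > 0
}

#' Default rpoB cluster windows
#'
#' Amino-acid windows of the two rifampin-resistance clusters used as
#' defaults by [window_to_clusters()]: cluster I spans aa 451-754 and
#' cluster II aa 84-401 (in the rpoB numbering). The package does not ship
#' the rpoB sequence itself; windows and the numbering offset are
#' configuration.
#'
#' @return A tibble with columns `cluster`, `aa_start`, `aa_end`.
#' @export
rpoB_cluster_windows <- function() {
  tibble::tibble(
    cluster = c("I", "II"),
    aa_start = c(451L, 84L),
    aa_end = c(754L, 401L)
  )
}

#' Restrict substitutions to reporter cluster windows
#'
#' @param subs Tibble with a `codon_index` column (amino-acid numbering,
#'   e.g. from [call_aa_changes()]).
#' @param windows Tibble with `aa_start`, `aa_end` (and optionally
#'   `cluster`); defaults to [rpoB_cluster_windows()]. Windows must be
#'   non-empty and non-overlapping.
#' @return The rows of `subs` whose `codon_index` falls inside any window,
#'   input order preserved, with a `cluster` column when windows are named.
#' @export
window_to_clusters <- function(subs, windows = rpoB_cluster_windows()) {
  if (nrow(windows) == 0 || any(windows$aa_end < windows$aa_start)) {
    stop("cluster windows must be non-empty with aa_start <= aa_end", call. = FALSE)
  }
  if (nrow(windows) > 1) {
    w <- windows[order(windows$aa_start), ]
    if (any(w$aa_start[-1] <= w$aa_end[-nrow(w)])) {
      stop("cluster windows overlap; fix the window configuration", call. = FALSE)
    }
  }
  if (nrow(subs) == 0) return(subs)
  if (!"codon_index" %in% names(subs)) {
    stop("subs must carry a codon_index column (run call_aa_changes() first)",
         call. = FALSE)
  }
  hit <- purrr::map_chr(subs$codon_index, function(ci) {
    i <- which(ci >= windows$aa_start & ci <= windows$aa_end)
    if (length(i) == 0) NA_character_
    else if ("cluster" %in% names(windows)) as.character(windows$cluster[i[1]])
    else as.character(i[1])
  })
  out <- subs[!is.na(hit), , drop = FALSE]
  out$cluster <- hit[!is.na(hit)]
  out
}

#' Name amino-acid changes for clone substitutions
#'
#' Maps nucleotide substitutions onto codons of a coding sequence and names
#' the protein change in the conventional `RefAA + number + AltAA` form
#' (e.g. `"S531F"`). Multiple substitutions falling in one codon are
#' translated jointly, as a genotype is read from a clone. Synonymous
#' changes keep an empty `aa_change` but are retained. Substitutions
#' outside complete codons of the CDS are flagged in `in_cds` rather than
#' dropped.
#'
#' @param subs Tibble with `position`, `ref`, `alt` (reference nucleotide
#'   coordinates, 1-based).
#' @param ref_seq The reference nucleotide sequence containing the CDS.
#' @param cds_start 1-based position of the first base of the first codon.
#' @param numbering_offset Added to the codon number within the fragment to
#'   obtain the published amino-acid numbering (0 when the fragment starts
#'   at the annotated residue 1).
#' @return `subs` with added columns `codon_index`, `aa_ref`, `aa_alt`,
#'   `aa_change` (empty string when synonymous), `in_cds`.
#' @export
call_aa_changes <- function(subs, ref_seq, cds_start = 1L, numbering_offset = 0L) {
  ref <- toupper(as.character(ref_seq))
  n_codons <- (nchar(ref) - cds_start + 1L) %/% 3L
  if (nrow(subs) == 0) {
    return(dplyr::mutate(subs, codon_index = integer(), aa_ref = character(),
                         aa_alt = character(), aa_change = character(),
                         in_cds = logical()))
  }
  off <- subs$position - cds_start
  codon_in_frag <- off %/% 3L + 1L
  in_cds <- off >= 0 & codon_in_frag <= n_codons
  mutated <- apply_substitutions(ref, subs[in_cds, c("position", "ref", "alt")])

  translate_codon <- function(seq, codon) {
    s <- substr(seq, cds_start + 3L * (codon - 1L), cds_start + 3L * codon - 1L)
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }
  aa_ref <- aa_alt <- rep(NA_character_, nrow(subs))
  for (i in which(in_cds)) {
    aa_ref[i] <- translate_codon(ref, codon_in_frag[i])
    aa_alt[i] <- translate_codon(mutated, codon_in_frag[i])
  }
  codon_index <- ifelse(in_cds, codon_in_frag + numbering_offset, NA_integer_)
  dplyr::mutate(subs,
    codon_index = as.integer(codon_index),
    aa_ref = aa_ref,
    aa_alt = aa_alt,
    aa_change = dplyr::case_when(
      !in_cds ~ NA_character_,
      aa_ref == aa_alt ~ "",
      TRUE ~ paste0(aa_ref, codon_index, aa_alt)
    ),
    in_cds = in_cds
  )
}
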