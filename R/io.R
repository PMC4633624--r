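#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}

#' Read FASTQ reads into a tidy tibble
#'
#' @param path FASTQ file.
#' @return A tibble with columns `read_id`, `seq`, `qual` (Phred string,
#'   offset 33). Raises a parse error naming the record when a quality
#'   string length disagrees with its sequence.
#' @export
read_fastq <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(reads)$qualities)
  out <- tibble::tibble(
    read_id = sub("\\s.*$", "", names(reads)),
    seq = as.character(reads),
    qual = qual
  )
  bad <- nchar(out$seq) != nchar(out$qual)
  if (any(bad)) {
    stop(sprintf("malformed FASTQ record '%s': sequence and quality lengths differ",
                 out$read_id[which(bad)[1]]), call. = FALSE)
  }
  out
}

#' Write tidy reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$read_id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Decode a Phred quality string to integer scores
#'
#' @param qual Character vector of Phred-33 quality strings.
#' @return List of integer vectors.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Phred score corresponding to an error probability, and back
#'
#' `Q = -10 log10(p)`; `phred_accuracy()` gives the base-calling accuracy
#' implied by a quality threshold (Q30 corresponds to 99.9%).
#'
#' @param p Error probability.
#' @return Integer Phred score.
#' @export
error_to_phred <- function(p) {
  as.integer(round(-10 * log10(p)))
}

#' @rdname error_to_phred
#' @param q Phred score.
#' @return `phred_accuracy()`: accuracy fraction `1 - 10^(-q/10)`.
#' @export
phred_accuracy <- function(q) {
  1 - 10^(-q / 10)
}

#' Read substitution-only alignments from a SAM/BAM file
#'
#' Accepts coordinate-sorted alignments of amplicon reads against a single
#' reference. Only reads whose CIGAR is a single full-length match
#' (`<n>M`, substitution-only) are accepted; others raise an error since
#' gapped alignments are out of scope. Requires the Rsamtools package.
#'
#' @param path SAM or BAM file.
#' @return A tibble with `read_id`, `seq`, `qual`, `offset` (0-based
#'   reference offset), ready for [quality_filter()].
#' @export
read_sam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM/BAM requires the Rsamtools package", call. = FALSE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "pos", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos)
  cig <- rec$cigar[keep]
  if (any(!grepl("^[0-9]+M$", cig))) {
    stop("SAM contains gapped or clipped alignments; only substitution-only (full-match CIGAR) reads are supported",
         call. = FALSE)
  }
  tibble::tibble(
    read_id = rec$qname[keep],
    seq = as.character(rec$seq)[keep],
    qual = as.character(rec$qual)[keep],
    offset = rec$pos[keep] - 1L
  )
}

#' Write a provenance JSON for a run
#'
#' Records the configuration, seed and package version so any report can be
#' regenerated from it.
#'
#' @param config Named list of run parameters (must include any seed used).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, path) {
  payload <- list(
    package = "mutascope",
    version = as.character(utils::packageVersion("mutascope")),
    schema = "mutascope/1",
    config = config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a provenance JSON
#' @param path Provenance file written by [write_provenance()].
#' @return The parsed list.
#' @export
read_provenance <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
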