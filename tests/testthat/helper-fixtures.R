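# Fixtures built in code; nothing binary on disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A toy rpoB-like CDS fragment spanning amino acids 500-540 of the published
# numbering (numbering_offset = 499). Codon 6 of the fragment (aa 505) is TTT
# (Phe) and codon 32 (aa 531) is TCT (Ser); everything else is GCT (Ala).
toy_rpob_fragment <- function() {
  codons <- rep("GCT", 41)
  codons[6] <- "TTT"   # aa 505 Phe
  codons[32] <- "TCT"  # aa 531 Ser
  list(
    seq = paste(codons, collapse = ""),
    cds_start = 1L,
    numbering_offset = 499L,
    # first nt of codon k is 3*(k-1)+1
    nt_of_codon = function(k, within = 1L) 3L * (k - 1L) + within
  )
}

# All 12 (ref, alt) substitution pairs, one per strand-specific class.
all_12_pairs <- function() {
  cls <- mutation_classes()
  tibble::tibble(ref = cls$ref, alt = cls$alt)
}

# Uniform-coverage read set from one sequence: every read full-length, Q40.
perfect_reads <- function(seq, n, q = 40) {
  tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    seq = rep(seq, n),
    qual = strrep(rawToChar(as.raw(q + 33L)), nchar(seq)),
    offset = 0L
  )
}

random_substitution_pairs <- function(n) {
  cls <- mutation_classes()
  i <- sample.int(12, n, replace = TRUE)
  tibble::tibble(ref = cls$ref[i], alt = cls$alt[i])
}

revcomp_pairs <- function(pairs) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tibble::tibble(ref = unname(comp[pairs$ref]), alt = unname(comp[pairs$alt]))
}
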