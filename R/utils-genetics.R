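# Small genetic-code helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Complement / reverse-complement of base characters
#'
#' Thin vectorised wrappers around [chartr()] for per-base work; whole-read
#' reverse complements go through [Biostrings::reverseComplement()].
#'
#' @param x Character vector of bases or sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @keywords internal
comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' @rdname comp_base
#' @keywords internal
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Codon -> one-letter amino acid (standard genetic code, "*" = stop).
codon_to_aa <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  unname(aa)
}

# The 61 sense codons, used by the site-count oracle tests and the
# synthetic reference builder.
sense_codons <- function() {
  all64 <- names(Biostrings::GENETIC_CODE)
  all64[Biostrings::GENETIC_CODE != "*"]
}

# Split a single sequence string into a character vector of bases.
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

# Draw n random bases (uniform over A,C,G,T) using the current RNG stream.
random_bases <- function(n) {
  sample(DNA_BASES, n, replace = TRUE)
}

# For each reference base, draw a uniformly random *different* base.
random_alt <- function(ref) {
  n <- length(ref)
  if (n == 0L) return(character())
  # offset 1..3 from the ref index, cyclic over the 4 bases
  idx <- match(ref, DNA_BASES)
  alt_idx <- ((idx - 1L + sample(1:3, n, replace = TRUE)) %% 4L) + 1L
  DNA_BASES[alt_idx]
}
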