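# Shared fixtures and independent oracles.

# cache the synthetic reference across test files
ref_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_reference()
    cache
  }
})

# tiny toy model: one exon covering a short CDS, optional intron tail
toy_model <- function(cds = "ATGAAACCCGGGTTT", intron = "GTAAGTTTTTTT",
                      splice_pad = 2L) {
  seqn <- paste0(cds, intron)
  ref_model(seqn, tibble::tibble(start = 0L, end = nchar(cds)),
            name = "toy", splice_pad = splice_pad)
}

random_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    paste0(sample(sense, n_codons, replace = TRUE), collapse = "")
  })
}

# Brute-force consequence oracle: rebuild the codon string and
# retranslate, independent of the package's coordinate maps.
oracle_consequence <- function(cds, pos0, alt) {
  stopifnot(nchar(cds) %% 3 == 0)
  chars <- strsplit(cds, "")[[1]]
  ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  chars[pos0 + 1] <- alt
  alt_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste0(chars, collapse = ""))))
  d <- which(strsplit(ref_aa, "")[[1]] != strsplit(alt_aa, "")[[1]])
  if (length(d) == 0) return("synonymous")
  if (substr(alt_aa, d, d) == "*") return("stop_gained")
  "missense"
}

# Brute-force SSCS oracle: per-position tally over a character matrix.
oracle_sscs <- function(reads, majority) {
  w <- nchar(reads[1])
  m <- matrix(unlist(strsplit(reads, "")), nrow = w)
  out <- character(w)
  for (i in seq_len(w)) {
    obs <- m[i, ][m[i, ] != "N"]
    if (!length(obs)) { out[i] <- "N"; next }
    tab <- sort(table(obs), decreasing = TRUE)
    top <- tab[1] / length(obs)
    ok <- top >= majority - 1e-9 &&
      sum(tab / length(obs) >= majority - 1e-9) == 1
    out[i] <- if (ok) names(tab)[1] else "N"
  }
  paste0(out, collapse = "")
}

# Independent Nei-Gojobori enumeration for a single codon.
oracle_ng_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (gc[[mut]] == aa) syn <- syn + 1
    }
  }
  c(S = syn / 3, N = 3 - syn / 3)
}

# simple small simulation config on the shared reference
small_cfg <- function(model, layout, n_molecules = 400, subregions = "Up1",
                      ..., library_id = "libA") {
  sim_config(model, layout, subregions = subregions,
             n_molecules = n_molecules, library_id = library_id, ...)
}

# per-position non-reference allele totals of a pileup
pileup_alt_total <- function(pu) {
  m <- as.matrix(pu[, paste0("alt_", c("A", "C", "G", "T"))])
  refc <- m[cbind(seq_len(nrow(pu)), match(pu$ref, c("A", "C", "G", "T")))]
  pu$coverage - refc
}

# orient a pair of mate insert strings to transcript coordinates, using
# mismatch counts against the fragment (test-side stand-in for the
# package's orientation logic)
oracle_orient <- function(m1, m2, frag, ins) {
  L <- nchar(frag)
  left_t <- substr(frag, 1, min(ins, L))
  right_t <- substr(frag, max(L - ins, 0) + 1, L)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  mm <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (mm(m1, left_t) <= mm(m1, rc(right_t))) {
    list(left = m1, right = rc(m2))
  } else {
    list(left = m2, right = rc(m1))
  }
}
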