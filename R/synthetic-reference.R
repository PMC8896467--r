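#' Synthetic FGFR3-like reference and target layout
#'
#' Builds a synthetic stand-in for the targeted receptor-tyrosine-kinase
#' coding region studied by the pipeline: a ~4.4 kb genomic segment in
#' transcript orientation containing 13 exons (a partial CDS of 806 codons
#' framed from codon 1) separated by random introns, tiled by ten
#' subregions ("Up1".."Up5", "Down1".."Down5") that together cover 4405
#' sequenced positions, and three protein domains (IgI-III,
#' TM_inter-domain, TK).
#'
#' The sequence is random (sense codons only inside the CDS) but three
#' codons are pinned so that well-known receptor variants are reproduced by
#' the annotation code: codon 373 = TAC (so c.1118A>G gives p.Y373C),
#' codon 380 = GGG (c.1138G>A gives p.G380R) and codon 540 = AAC
#' (c.1620C>A and c.1620C>G both give p.N540K). This is a synthetic
#' construct for simulation and testing, not the real gene sequence.
#'
#' Domain residue boundaries are package defaults (IgI-III 23-369,
#' TM_inter-domain 370-471, TK 472-755), chosen to place residues 373/380
#' in the TM inter-domain region and residue 540 in the kinase domain as
#' described for the real protein; they are assumptions, not published
#' coordinates, and can be replaced via [target_layout()].
#'
#' @param seed Integer seed for the sequence draw (default 101), applied to
#'   a local RNG so the caller's RNG state is untouched.
#' @return A list with elements `model` ([ref_model]) and `layout`
#'   ([target_layout]).
#' @export
synthetic_reference <- function(seed = 101L) {
  n_codons <- 806L
  pinned <- c("373" = "TAC", "380" = "GGG", "540" = "AAC")
  cds <- withr::with_seed(seed, {
    codons <- sample(sense_codons(), n_codons, replace = TRUE)
    codons[as.integer(names(pinned))] <- pinned
    paste0(codons, collapse = "")
  })
  cds_len <- nchar(cds)  # 2418

  # 13 exons summing to the CDS length, separated by 12 introns; the layout
  # is padded so the ten subregions cover exactly 4405 positions.
  exon_sizes <- c(186L, 186L, 186L, 186L, 186L, 186L, 186L, 186L, 186L,
                  186L, 186L, 186L, 186L)
  exon_sizes[13L] <- cds_len - sum(exon_sizes[1:12])
  intron_size <- 138L
  n_intron <- 12L
  lead_pad <- 10L
  total <- lead_pad + sum(exon_sizes) + n_intron * intron_size
  # trailing pad so that the subregion tiling has room
  region_size_target <- 4405L
  tail_pad <- max(region_size_target + lead_pad - total, 10L)
  glen <- total + tail_pad

  intron_seq <- withr::with_seed(seed + 1L, {
    paste0(random_bases(glen - cds_len), collapse = "")
  })

  # interleave exons and introns
  bases <- seq_chars(intron_seq)
  genome <- character(glen)
  gpos <- 1L; cpos <- 1L; ipos <- 1L
  starts <- integer(13L); ends <- integer(13L)
  take_intron <- function(n) {
    out <- bases[ipos:(ipos + n - 1L)]
    ipos <<- ipos + n
    out
  }
  genome[gpos:(gpos + lead_pad - 1L)] <- take_intron(lead_pad)
  gpos <- gpos + lead_pad
  cds_bases <- seq_chars(cds)
  for (i in 1:13) {
    starts[i] <- gpos - 1L  # 0-based
    genome[gpos:(gpos + exon_sizes[i] - 1L)] <-
      cds_bases[cpos:(cpos + exon_sizes[i] - 1L)]
    gpos <- gpos + exon_sizes[i]
    cpos <- cpos + exon_sizes[i]
    ends[i] <- gpos - 1L
    if (i < 13) {
      genome[gpos:(gpos + intron_size - 1L)] <- take_intron(intron_size)
      gpos <- gpos + intron_size
    }
  }
  genome[gpos:glen] <- take_intron(glen - gpos + 1L)
  sequence <- paste0(genome, collapse = "")

  model <- ref_model(
    sequence,
    tibble::tibble(start = starts, end = ends),
    name = "RTK_synthetic",
    cds_start_offset = 0L,
    splice_pad = 2L
  )

  # ten subregions tiling [lead_pad, lead_pad + 4405)
  sub_sizes <- c(rep(441L, 5L), rep(440L, 5L))  # sums to 4405
  sub_names <- c(paste0("Up", 1:5), paste0("Down", 1:5))
  sub_start <- lead_pad + cumsum(c(0L, sub_sizes[-10L]))
  layout <- target_layout(
    tibble::tibble(name = sub_names, start = sub_start,
                   end = sub_start + sub_sizes),
    domains = tibble::tibble(
      name = c("IgI-III", "TM_inter-domain", "TK"),
      aa_start = c(23L, 370L, 472L),
      aa_end = c(369L, 471L, 755L)
    )
  )
  list(model = model, layout = layout)
}

#' Write a reference model and layout to FASTA + layout TSV
#'
#' Serialises the pair in the schema read back by [load_reference()]
#' (1-based inclusive intervals in the file).
#'
#' @param model A [ref_model].
#' @param layout A [target_layout].
#' @param fasta_path,layout_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_reference_files <- function(model, layout, fasta_path, layout_path) {
  seqs <- Biostrings::DNAStringSet(model$sequence)
  names(seqs) <- model$name
  Biostrings::writeXStringSet(seqs, fasta_path)
  rows <- dplyr::bind_rows(
    tibble::tibble(type = "param",
                   name = c("cds_start_offset", "splice_pad", "minus_strand"),
                   start = c(model$cds_start_offset, model$splice_pad,
                             as.integer(model$minus_strand)),
                   end = NA_integer_),
    tibble::tibble(type = "exon",
                   name = paste0("exon", seq_len(nrow(model$exons))),
                   start = model$exons$start + 1L, end = model$exons$end),
    tibble::tibble(type = "subregion", name = layout$subregions$name,
                   start = layout$subregions$start + 1L,
                   end = layout$subregions$end),
    tibble::tibble(type = "domain", name = layout$domains$name,
                   start = layout$domains$aa_start,
                   end = layout$domains$aa_end)
  )
  readr::write_tsv(rows, layout_path)
  invisible(list(fasta = fasta_path, layout = layout_path))
}
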