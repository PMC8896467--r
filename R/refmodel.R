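#' Reference model for a targeted coding region
#'
#' Holds the targeted genomic sequence (in transcript orientation), its exon
#' structure and codon framing, and precomputed coordinate maps used by every
#' downstream stage (site classification, consequence annotation, spectra and
#' dN/dS site enumeration).
#'
#' All internal coordinates are 0-based half-open; report and VCF-style output
#' is 1-based. Analyses run in transcript (CDS) orientation throughout; the
#' `minus_strand` flag merely records that the real gene may sit on the
#' genomic minus strand, and all substitution classes are reported in CDS
#' orientation.
#'
#' @param sequence Single string over A/C/G/T: the targeted region in
#'   transcript orientation (exons plus intervening introns).
#' @param exons Data frame with columns `start`, `end`: 0-based half-open
#'   exon intervals, non-overlapping and sorted. May be empty (all positions
#'   are then intronic).
#' @param name Reference/transcript name used in reports.
#' @param cds_start_offset Number of CDS bases upstream of the first modelled
#'   exon base (codon framing for a partial CDS). Residue numbering and
#'   `c.` positions include this offset, so a model of exons 3-15 keeps the
#'   full-transcript numbering.
#' @param splice_pad Width in bases of the splice region flanking each exon
#'   edge (default 2, the canonical splice dinucleotides).
#' @param minus_strand Logical bookkeeping flag (see above); does not change
#'   any computation.
#'
#' @return An object of class `ref_model`: a list with the validated fields
#'   plus precomputed maps `site_class` (per-position classification) and
#'   `cds_index` (per-position 1-based CDS coordinate, NA off-exon).
#' @export
ref_model <- function(sequence, exons, name = "region",
                      cds_start_offset = 0L, splice_pad = 2L,
                      minus_strand = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0L) {
    stop("non-ACGT character in reference sequence at position ", bad,
         " (1-based)")
  }
  len <- nchar(sequence)
  exons <- tibble::as_tibble(exons)
  if (nrow(exons) == 0L) {
    exons <- tibble::tibble(start = integer(), end = integer())
  }
  stopifnot(all(c("start", "end") %in% names(exons)))
  exons <- dplyr::arrange(exons, .data$start)
  if (any(exons$start < 0L) || any(exons$end > len)) {
    stop("exon interval outside sequence bounds [0, ", len, ")")
  }
  if (any(exons$end <= exons$start)) stop("empty or inverted exon interval")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("exon intervals overlap")
  }
  stopifnot(cds_start_offset >= 0L, splice_pad >= 0L)

  ## per-position site class and CDS coordinate map
  site_class <- rep("intronic", len)
  cds_index <- rep(NA_integer_, len)
  cds_seen <- 0L
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i]; e <- exons$end[i]
    site_class[(s + 1L):e] <- "exonic"
    cds_index[(s + 1L):e] <- cds_seen + seq_len(e - s)
    cds_seen <- cds_seen + (e - s)
  }
  if (splice_pad > 0L) {
    for (i in seq_len(nrow(exons))) {
      for (edge in c(exons$start[i] - splice_pad, exons$end[i])) {
        idx <- seq(edge, length.out = splice_pad)
        idx <- idx[idx >= 0L & idx < len]
        take <- site_class[idx + 1L] == "intronic"
        site_class[idx[take] + 1L] <- "splice_region"
      }
    }
  }

  structure(
    list(
      name = name,
      sequence = sequence,
      bases = seq_chars(sequence),
      length = len,
      exons = exons,
      cds_start_offset = as.integer(cds_start_offset),
      splice_pad = as.integer(splice_pad),
      minus_strand = isTRUE(minus_strand),
      site_class = site_class,
      cds_index = cds_index,
      cds_length = cds_seen
    ),
    class = "ref_model"
  )
}

#' @export
print.ref_model <- function(x, ...) {
  cat("<ref_model> ", x$name, ": ", x$length, " bp, ",
      nrow(x$exons), " exons (", x$cds_length, " CDS bases, offset ",
      x$cds_start_offset, "), splice_pad ", x$splice_pad, "\n", sep = "")
  invisible(x)
}

#' Target layout: subregions, protein domains and the analysis footprint
#'
#' @param subregions Data frame with columns `name`, `start`, `end`
#'   (0-based half-open sequenced intervals, e.g. ten ~500 bp restriction
#'   fragments "Up1".."Down5"). Names must be unique, intervals
#'   non-overlapping.
#' @param domains Optional data frame with columns `name`, `aa_start`,
#'   `aa_end` (1-based inclusive residue intervals, e.g. IgI-III /
#'   TM_inter-domain / TK). Must not overlap.
#' @param target_set Optional data frame with columns `name`, `target_set`
#'   assigning each subregion to a capture panel ("Up"/"Down"); defaults to
#'   the leading alpha prefix of the subregion name.
#'
#' @return An object of class `target_layout` with `region_size` equal to
#'   the total number of targeted sequenced positions.
#' @export
target_layout <- function(subregions, domains = NULL, target_set = NULL) {
  subregions <- tibble::as_tibble(subregions)
  stopifnot(all(c("name", "start", "end") %in% names(subregions)))
  if (anyDuplicated(subregions$name)) stop("subregion names must be unique")
  if (any(subregions$end <= subregions$start)) stop("empty subregion interval")
  o <- order(subregions$start)
  ss <- subregions[o, ]
  if (nrow(ss) > 1L && any(ss$start[-1L] < ss$end[-nrow(ss)])) {
    stop("subregion intervals overlap")
  }
  if (is.null(target_set)) {
    subregions$target_set <- sub("[0-9].*$", "", subregions$name)
  } else {
    subregions$target_set <-
      target_set$target_set[match(subregions$name, target_set$name)]
  }
  if (!is.null(domains)) {
    domains <- tibble::as_tibble(domains)
    stopifnot(all(c("name", "aa_start", "aa_end") %in% names(domains)))
    if (any(domains$aa_end < domains$aa_start)) stop("inverted domain interval")
    o <- order(domains$aa_start)
    dd <- domains[o, ]
    if (nrow(dd) > 1L && any(dd$aa_start[-1L] <= dd$aa_end[-nrow(dd)])) {
      stop("domain intervals overlap")
    }
  } else {
    domains <- tibble::tibble(name = character(), aa_start = integer(),
                              aa_end = integer())
  }
  structure(
    list(
      subregions = subregions,
      domains = domains,
      region_size = sum(subregions$end - subregions$start)
    ),
    class = "target_layout"
  )
}

#' @export
print.target_layout <- function(x, ...) {
  cat("<target_layout> ", nrow(x$subregions), " subregions (",
      x$region_size, " targeted positions), ", nrow(x$domains),
      " domains\n", sep = "")
  invisible(x)
}

#' Load a reference model and target layout from files
#'
#' Reads a single-record FASTA (via Biostrings) and a tab-separated layout
#' file with columns `type`, `name`, `start`, `end`. Rows of type `exon` and
#' `subregion` give 1-based inclusive sequence intervals; rows of type
#' `domain` give 1-based inclusive amino-acid intervals; rows of type `param`
#' carry scalar settings in the `start` column (`splice_pad`,
#' `cds_start_offset`, `minus_strand`). All intervals are validated against
#' the sequence bounds on load.
#'
#' @param fasta_path Path to a FASTA file with exactly one record.
#' @param layout_path Path to the layout TSV described above.
#' @return A list with elements `model` ([ref_model]) and `layout`
#'   ([target_layout]).
#' @export
load_reference <- function(fasta_path, layout_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(layout_path)) stop("layout file not found: ", layout_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("expected exactly one FASTA record, found ", length(seqs))
  }
  sequence <- as.character(seqs[[1L]])
  nm <- sub("\\s.*$", "", names(seqs)[1L])
  lay <- readr::read_tsv(layout_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           type = readr::col_character(),
                           name = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double()
                         ))
  len <- nchar(sequence)
  grab <- function(tp) dplyr::filter(lay, .data$type == tp)
  params <- grab("param")
  pval <- function(key, default) {
    hit <- params$start[params$name == key]
    if (length(hit) == 0L) default else hit[1L]
  }
  iv <- function(tbl, what, bound) {
    if (nrow(tbl) == 0L) {
      return(tibble::tibble(name = character(), start = integer(),
                            end = integer()))
    }
    if (any(is.na(tbl$start)) || any(is.na(tbl$end))) {
      stop("missing interval bounds for a ", what, " row")
    }
    if (any(tbl$start < 1) || any(tbl$end > bound)) {
      bad <- which(tbl$start < 1 | tbl$end > bound)[1L]
      stop(what, " interval '", tbl$name[bad], "' outside bounds [1, ",
           bound, "]")
    }
    # 1-based inclusive in the file -> 0-based half-open internally
    tibble::tibble(name = tbl$name, start = as.integer(tbl$start) - 1L,
                   end = as.integer(tbl$end))
  }
  exons <- iv(grab("exon"), "exon", len)
  subregions <- iv(grab("subregion"), "subregion", len)
  domains <- grab("domain")
  model <- ref_model(
    sequence, exons[, c("start", "end")], name = nm,
    cds_start_offset = as.integer(pval("cds_start_offset", 0)),
    splice_pad = as.integer(pval("splice_pad", 2)),
    minus_strand = pval("minus_strand", 0) != 0
  )
  layout <- target_layout(
    subregions,
    domains = if (nrow(domains)) {
      tibble::tibble(name = domains$name,
                     aa_start = as.integer(domains$start),
                     aa_end = as.integer(domains$end))
    } else NULL
  )
  list(model = model, layout = layout)
}

#' Classify sequence positions as exonic, splice region or intronic
#'
#' The three classes partition every position: exonic inside an exon,
#' splice_region within `splice_pad` bases of an exon edge but outside all
#' exons, intronic elsewhere.
#'
#' @param model A [ref_model].
#' @param pos Integer vector of 0-based positions.
#' @return Character vector in `{exonic, splice_region, intronic}`.
#' @export
classify_site <- function(model, pos) {
  stopifnot(inherits(model, "ref_model"))
  if (length(pos) && (min(pos) < 0L || max(pos) >= model$length)) {
    stop("position out of range [0, ", model$length, ")")
  }
  model$site_class[pos + 1L]
}

#' Annotate substitutions with codon-level consequences
#'
#' Translates the reference and alternate codon with the standard genetic
#' code and reports HGVS-like `c.` and `p.` strings. Categories: synonymous,
#' missense, stop_gained for exonic sites; splice_region and intronic
#' positions are passed through with a `g.` notation and no protein change.
#'
#' @param model A [ref_model].
#' @param pos Integer vector of 0-based positions.
#' @param ref,alt Character vectors of reference and alternate bases; `ref`
#'   must match the model sequence (checked, error names the expected base).
#' @return A tibble with one row per variant: `pos`, `ref`, `alt`,
#'   `category`, `hgvs_c`, `hgvs_p`, `residue`, `aa_ref`, `aa_alt`.
#' @export
consequence <- function(model, pos, ref, alt) {
  stopifnot(inherits(model, "ref_model"))
  n <- length(pos)
  stopifnot(length(ref) == n, length(alt) == n)
  if (n == 0L) {
    return(tibble::tibble(pos = integer(), ref = character(),
                          alt = character(), category = character(),
                          hgvs_c = character(), hgvs_p = character(),
                          residue = integer(), aa_ref = character(),
                          aa_alt = character()))
  }
  if (min(pos) < 0L || max(pos) >= model$length) {
    stop("position out of range [0, ", model$length, ")")
  }
  have <- model$bases[pos + 1L]
  if (any(have != ref)) {
    bad <- which(have != ref)[1L]
    stop("reference mismatch at 0-based position ", pos[bad],
         ": expected ", have[bad], ", got ", ref[bad])
  }
  if (any(alt == ref)) stop("alt equals ref for a supplied variant")

  cls <- model$site_class[pos + 1L]
  category <- cls
  hgvs_c <- paste0("g.", pos + 1L, ref, ">", alt)
  hgvs_p <- rep("", n)
  residue <- rep(NA_integer_, n)
  aa_ref <- rep(NA_character_, n)
  aa_alt <- rep(NA_character_, n)

  ex <- which(cls == "exonic")
  if (length(ex)) {
    cdsp <- model$cds_start_offset + model$cds_index[pos[ex] + 1L]  # 1-based
    hgvs_c[ex] <- paste0("c.", cdsp, ref[ex], ">", alt[ex])
    residue[ex] <- (cdsp - 1L) %/% 3L + 1L
    frame <- (cdsp - 1L) %% 3L  # 0,1,2 within codon
    # map full-CDS coordinate -> model position (NA when outside the model)
    cds_to_model <- rep(NA_integer_, model$cds_start_offset + model$cds_length)
    on_model <- which(!is.na(model$cds_index))
    cds_to_model[model$cds_start_offset + model$cds_index[on_model]] <-
      on_model - 1L
    for (j in seq_along(ex)) {
      mp <- cds_to_model[(residue[ex[j]] - 1L) * 3L + 1:3]
      if (anyNA(mp)) {
        stop("codon context unavailable for 0-based position ", pos[ex[j]],
             " (partial codon at the model boundary)")
      }
      cod_ref <- paste0(model$bases[mp + 1L], collapse = "")
      cod_alt_v <- model$bases[mp + 1L]
      cod_alt_v[frame[j] + 1L] <- alt[ex[j]]
      cod_alt <- paste0(cod_alt_v, collapse = "")
      aa_ref[ex[j]] <- codon_to_aa(cod_ref)
      aa_alt[ex[j]] <- codon_to_aa(cod_alt)
    }
    category[ex] <- dplyr::case_when(
      aa_alt[ex] == aa_ref[ex] ~ "synonymous",
      aa_alt[ex] == "*" ~ "stop_gained",
      TRUE ~ "missense"
    )
    hgvs_p[ex] <- paste0("p.", aa_ref[ex], residue[ex], aa_alt[ex])
    hgvs_p[ex][category[ex] == "synonymous"] <-
      paste0("p.", aa_ref[ex][category[ex] == "synonymous"],
             residue[ex][category[ex] == "synonymous"], "=")
  }
  tibble::tibble(pos = as.integer(pos), ref = ref, alt = alt,
                 category = category, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                 residue = residue, aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Protein domain containing a residue
#'
#' @param layout A [target_layout] with domain intervals.
#' @param residue Integer vector of 1-based residue numbers (NA allowed for
#'   non-coding variants).
#' @return Character vector of domain names, NA where the residue falls in
#'   no domain (a valid outcome, e.g. inter-domain linkers outside the
#'   configured intervals).
#' @export
domain_of <- function(layout, residue) {
  stopifnot(inherits(layout, "target_layout"))
  d <- layout$domains
  out <- rep(NA_character_, length(residue))
  if (nrow(d) == 0L) return(out)
  for (i in seq_len(nrow(d))) {
    hit <- !is.na(residue) & residue >= d$aa_start[i] & residue <= d$aa_end[i]
    out[hit] <- d$name[i]
  }
  out
}

#' Subregion containing each position
#'
#' @param layout A [target_layout].
#' @param pos Integer vector of 0-based positions.
#' @return Character vector of subregion names (NA outside the layout).
#' @export
subregion_of <- function(layout, pos) {
  s <- layout$subregions
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(s))) {
    hit <- pos >= s$start[i] & pos < s$end[i]
    out[hit] <- s$name[i]
  }
  out
}

#' Annotate a variant table with consequence, residue and domain
#'
#' Convenience wrapper joining [consequence()] and [domain_of()] onto a
#' variant tibble (columns `pos`, `ref`, `alt`; extra columns preserved).
#'
#' @param variants Data frame with columns `pos` (0-based), `ref`, `alt`.
#' @param model A [ref_model].
#' @param layout Optional [target_layout] for domain assignment.
#' @return The input tibble with `category`, `hgvs_c`, `hgvs_p`, `residue`,
#'   `aa_ref`, `aa_alt` and (if a layout is given) `domain` columns added.
#' @export
annotate_variants <- function(variants, model, layout = NULL) {
  variants <- tibble::as_tibble(variants)
  ann <- consequence(model, variants$pos, variants$ref, variants$alt)
  out <- dplyr::bind_cols(
    variants,
    ann[, c("category", "hgvs_c", "hgvs_p", "residue", "aa_ref", "aa_alt")]
  )
  if (!is.null(layout)) {
    out$domain <- domain_of(layout, out$residue)
  }
  out
}
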