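#' Group tagged read pairs into duplex families
#'
#' Reads carry a molecular tag of `tag_length` bases at the 5' end of each
#' mate. The family key is the canonical (sorted) concatenation of the two
#' tags; the two strand families of one source molecule are distinguished
#' by tag orientation: pairs whose first mate carries the
#' lexicographically smaller tag are labelled `"ab"`, the complementary
#' orientation `"ba"`. Pairs with an N inside either tag are discarded and
#' counted.
#'
#' @param reads Tibble with columns `read_id`, `mate1`, `mate2` (as
#'   produced by [simulate_library()] or [read_fastq()]). Read ids follow
#'   the `<library>:<subregion>:<serial>` convention of the simulator;
#'   the subregion field anchors each pair to its target interval
#'   (simulated reads are generated coordinate-anchored, so no mapper is
#'   involved).
#' @param tag_length Tag length in bases (default 12).
#' @return The input tibble with `subregion`, `tag1`, `tag2`,
#'   `family_key` and `strand` columns added; discarded-read count in
#'   attribute `n_discarded`.
#' @export
group_families <- function(reads, tag_length = 12L) {
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) == 0L) {
    out <- dplyr::mutate(reads, subregion = character(),
                         tag1 = character(), tag2 = character(),
                         family_key = character(), strand = character())
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  tag1 <- substr(reads$mate1, 1L, tag_length)
  tag2 <- substr(reads$mate2, 1L, tag_length)
  bad <- grepl("N", tag1, fixed = TRUE) | grepl("N", tag2, fixed = TRUE)
  out <- reads[!bad, , drop = FALSE]
  tag1 <- tag1[!bad]; tag2 <- tag2[!bad]
  out$subregion <- vapply(strsplit(out$read_id, ":", fixed = TRUE),
                          function(x) x[2], character(1))
  out$tag1 <- tag1
  out$tag2 <- tag2
  out$family_key <- paste(pmin(tag1, tag2), pmax(tag1, tag2), sep = "+")
  out$strand <- ifelse(tag1 <= tag2, "ab", "ba")
  attr(out, "n_discarded") <- sum(bad)
  out
}

#' Single-strand consensus over one read family side
#'
#' Per position, the consensus base is the unique base supported by at
#' least `majority` of the non-N observations; if no base reaches the
#' threshold, or two bases tie at it, the position becomes N. Families
#' with fewer than `min_family_size` reads are rejected (returns NULL).
#'
#' @param reads Character vector of equal-length read sequences, already
#'   oriented to a common strand.
#' @param min_family_size Minimum reads required to form an SSCS.
#' @param majority Support fraction threshold in (0.5, 1].
#' @return A list of class `sscs` with `sequence`, per-position `support`
#'   fraction, and `family_size`; or NULL if the family is too small.
#' @export
build_sscs <- function(reads, min_family_size = 3L, majority = 0.7) {
  if (length(reads) < min_family_size) return(NULL)
  w <- unique(nchar(reads))
  if (length(w) != 1L) stop("reads differ in length after alignment/trim")
  m <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
              nrow = w)
  seq_out <- character(w)
  supp <- numeric(w)
  for (i in seq_len(w)) {
    obs <- m[i, ]
    obs <- obs[obs != "N"]
    if (length(obs) == 0L) {
      seq_out[i] <- "N"; supp[i] <- 0
      next
    }
    tab <- table(obs)
    frac <- as.numeric(tab) / length(obs)
    winners <- which(frac >= majority - 1e-9)
    if (length(winners) == 1L) {
      seq_out[i] <- names(tab)[winners]
      supp[i] <- frac[winners]
    } else {
      seq_out[i] <- "N"
      supp[i] <- max(frac)
    }
  }
  structure(list(sequence = paste0(seq_out, collapse = ""),
                 support = supp,
                 family_size = length(reads)),
            class = "sscs")
}

#' Duplex consensus from two complementary single-strand consensuses
#'
#' Both SSCS must stem from the same family key, represent opposite
#' strands, and be supplied in a common orientation (the reverse strand
#' complemented). Positions where the two strands agree on a non-N base
#' are kept; any disagreement or N on either strand becomes N — a lesion
#' present on only one strand therefore never survives into the DCS.
#'
#' @param sscs_fwd,sscs_rev `sscs` objects (see [build_sscs()]).
#' @param family_key Optional pair of keys checked for equality.
#' @return A list of class `dcs` with `sequence` and the source family
#'   sizes.
#' @export
build_dcs <- function(sscs_fwd, sscs_rev, family_key = NULL) {
  stopifnot(inherits(sscs_fwd, "sscs"), inherits(sscs_rev, "sscs"))
  if (!is.null(family_key) && length(unique(family_key)) != 1L) {
    stop("SSCS pair stems from different family keys")
  }
  a <- seq_chars(sscs_fwd$sequence)
  b <- seq_chars(sscs_rev$sequence)
  if (length(a) != length(b)) stop("SSCS lengths differ")
  out <- ifelse(a == b & a != "N", a, "N")
  structure(list(sequence = paste0(out, collapse = ""),
                 family_sizes = c(sscs_fwd$family_size,
                                  sscs_rev$family_size)),
            class = "dcs")
}

## ---- batch consensus engine -------------------------------------------

# Sparse deviations of equal-width strings from a template.
# Returns tibble(str = index into strings, off = 1-based offset, base).
string_deviations <- function(strings, template) {
  w <- nchar(template)
  n <- length(strings)
  if (n == 0L) {
    return(tibble::tibble(str = integer(), off = integer(),
                          base = character()))
  }
  tr <- charToRaw(template)
  chunk <- max(1L, 4194304L %/% w)
  out <- list()
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    m <- charToRaw(paste0(strings[s:e], collapse = ""))
    neq <- which(m != rep(tr, times = e - s + 1L))
    if (length(neq)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        str = s - 1L + ((neq - 1L) %/% w) + 1L,
        off = ((neq - 1L) %% w) + 1L,
        base = strsplit(rawToChar(m[neq]), "", fixed = TRUE)[[1L]]
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(str = integer(), off = integer(), base = character())
}

# Per-string mismatch counts against a template (prefix comparison).
prefix_mismatches <- function(strings, template, width) {
  tpl <- substr(template, 1L, width)
  d <- string_deviations(substr(strings, 1L, width), tpl)
  tabulate(d$str, nbins = length(strings))
}

#' Build SSCS and DCS consensus calls for a whole library
#'
#' Batch equivalent of [build_sscs()]/[build_dcs()] over all families of a
#' grouped read table, organised around sparse deviations from the
#' subregion reference. Read-pair orientation (which mate covers which
#' fragment end) is resolved by comparing each first mate against the
#' forward left template and the reverse-complemented right template of
#' its subregion.
#'
#' @param families Output of [group_families()].
#' @param model A [ref_model].
#' @param layout A [target_layout].
#' @param tag_length Tag length in bases.
#' @param min_family_size Minimum reads per strand family (default 3).
#' @param majority Consensus support threshold in (0.5, 1] (default 0.7).
#' @return An object of class `dcs_set`: per-subregion consensus summaries
#'   (number of DCS/SSCS, sparse alternate and N records with per-strand
#'   family evidence), used by [dcs_pileup()], [sscs_pileup()] and
#'   [consensus_evidence()].
#' @export
call_consensus <- function(families, model, layout, tag_length = 12L,
                           min_family_size = 3L, majority = 0.7) {
  stopifnot(inherits(model, "ref_model"), inherits(layout, "target_layout"))
  if (majority <= 0.5 || majority > 1) {
    stop("majority must lie in (0.5, 1]")
  }
  subs <- unique(families$subregion)
  lay <- layout$subregions
  res <- list()
  for (sub_name in subs) {
    li <- which(lay$name == sub_name)
    if (length(li) != 1L) stop("reads map to unknown subregion: ", sub_name)
    gstart <- lay$start[li]
    L <- lay$end[li] - lay$start[li]
    frag <- substr(model$sequence, gstart + 1L, lay$end[li])
    fr <- families[families$subregion == sub_name, , drop = FALSE]
    res[[sub_name]] <- consensus_one_subregion(
      fr, frag, gstart, tag_length, min_family_size, majority)
  }
  structure(list(subregions = res,
                 params = list(min_family_size = min_family_size,
                               majority = majority)),
            class = "dcs_set")
}

consensus_one_subregion <- function(fr, frag, gstart, tag_length,
                                    min_family_size, majority) {
  L <- nchar(frag)
  i1 <- substring(fr$mate1, tag_length + 1L)
  i2 <- substring(fr$mate2, tag_length + 1L)
  ins <- nchar(i1[1L])
  ins_eff <- min(ins, L)
  r_start <- max(L - ins, 0L)
  left_t <- substr(frag, 1L, ins_eff)
  right_t <- substr(frag, r_start + 1L, L)

  ## orientation: does mate1 read the left end forward, or the right end
  ## in reverse complement?
  pw <- min(48L, ins_eff)
  mm_fwd <- prefix_mismatches(i1, left_t, pw)
  rc_right <- revcomp(right_t)
  mm_rev <- prefix_mismatches(i1, rc_right, pw)
  left1 <- mm_fwd <= mm_rev
  top_left <- ifelse(left1, i1, i2)
  raw_right <- ifelse(left1, i2, i1)
  top_right <- revcomp(raw_right)

  dl <- string_deviations(top_left, left_t)
  dr <- string_deviations(top_right, right_t)
  devs <- dplyr::bind_rows(
    tibble::tibble(pair = dl$str, pos = dl$off - 1L, base = dl$base),
    tibble::tibble(pair = dr$str, pos = r_start + dr$off - 1L,
                   base = dr$base)
  )

  ## strand family sizes
  fam_key <- paste(fr$family_key, fr$strand)
  fam_id <- match(fam_key, unique(fam_key))
  fam_tbl <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(fam = fam_id,
                                   family_key = fr$family_key,
                                   strand = fr$strand), .data$fam,
                    .data$family_key, .data$strand),
    f = dplyr::n(), .groups = "drop")
  fam_tbl$eligible <- fam_tbl$f >= min_family_size

  mult_of <- function(pos) (pos < ins_eff) + (pos >= r_start)
  fb <- seq_chars(frag)

  ## SSCS consensus at deviant positions of eligible strand families
  devs$fam <- fam_id[devs$pair]
  devs <- devs[fam_tbl$eligible[devs$fam], , drop = FALSE]
  if (nrow(devs)) {
    nn <- dplyr::count(devs[devs$base == "N", ], .data$fam, .data$pos,
                       name = "n_N")
    ad <- dplyr::count(devs[devs$base != "N", ], .data$fam, .data$pos,
                       .data$base, name = "cnt")
    grp <- dplyr::summarise(dplyr::group_by(ad, .data$fam, .data$pos),
                            alt_tot = sum(.data$cnt),
                            best_cnt = max(.data$cnt),
                            best_base = .data$base[which.max(.data$cnt)],
                            n_best = sum(.data$cnt == max(.data$cnt)),
                            .groups = "drop")
    grp <- dplyr::full_join(grp, nn, by = c("fam", "pos"))
    grp$alt_tot[is.na(grp$alt_tot)] <- 0L
    grp$best_cnt[is.na(grp$best_cnt)] <- 0L
    grp$n_best[is.na(grp$n_best)] <- 0L
    grp$n_N[is.na(grp$n_N)] <- 0L
    grp$f <- fam_tbl$f[grp$fam]
    grp$T <- grp$f * mult_of(grp$pos) - grp$n_N
    grp$ref_cnt <- grp$T - grp$alt_tot
    thr <- majority - 1e-9
    ref_win <- grp$T > 0L & grp$ref_cnt / grp$T >= thr
    alt_win <- grp$T > 0L & grp$best_cnt / grp$T >= thr & grp$n_best == 1L
    # majority > 0.5 makes ref and alt wins mutually exclusive
    sscs_rec <- tibble::tibble(
      fam = grp$fam, pos = grp$pos,
      base = dplyr::case_when(alt_win ~ grp$best_base, TRUE ~ "N"),
      support = ifelse(grp$T > 0L, grp$best_cnt / pmax(grp$T, 1L), 0),
      keep = !ref_win
    )
    sscs_rec <- sscs_rec[sscs_rec$keep, c("fam", "pos", "base", "support")]
  } else {
    sscs_rec <- tibble::tibble(fam = integer(), pos = integer(),
                               base = character(), support = double())
  }

  ## DCS: join the two strand families of each molecule key
  elig <- fam_tbl[fam_tbl$eligible, , drop = FALSE]
  n_str <- dplyr::count(elig, .data$family_key)
  duplex_keys <- n_str$family_key[n_str$n == 2L]
  n_dcs <- length(duplex_keys)
  sscs_rec$family_key <- fam_tbl$family_key[sscs_rec$fam]
  sscs_rec$strand <- fam_tbl$strand[sscs_rec$fam]
  drec <- sscs_rec[sscs_rec$family_key %in% duplex_keys, , drop = FALSE]
  if (nrow(drec)) {
    wide <- tidyr::pivot_wider(
      drec[, c("family_key", "strand", "pos", "base", "support")],
      names_from = "strand", values_from = c("base", "support"))
    for (col in c("base_ab", "base_ba")) {
      if (!col %in% names(wide)) wide[[col]] <- NA_character_
    }
    for (col in c("support_ab", "support_ba")) {
      if (!col %in% names(wide)) wide[[col]] <- NA_real_
    }
    agree <- !is.na(wide$base_ab) & !is.na(wide$base_ba) &
      wide$base_ab == wide$base_ba & wide$base_ab != "N"
    dcs_alt <- wide[agree, , drop = FALSE]
    dcs_alt <- tibble::tibble(
      family_key = dcs_alt$family_key, pos = dcs_alt$pos,
      alt = dcs_alt$base_ab,
      supp_ab = dcs_alt$support_ab, supp_ba = dcs_alt$support_ba)
    fsz <- tidyr::pivot_wider(elig[, c("family_key", "strand", "f")],
                              names_from = "strand", values_from = "f",
                              names_prefix = "f_")
    dcs_alt <- dplyr::left_join(dcs_alt, fsz, by = "family_key")
    dcs_n <- dplyr::count(wide[!agree, ], .data$pos, name = "n_N")
  } else {
    dcs_alt <- tibble::tibble(family_key = character(), pos = integer(),
                              alt = character(), supp_ab = double(),
                              supp_ba = double(), f_ab = integer(),
                              f_ba = integer())
    dcs_n <- tibble::tibble(pos = integer(), n_N = integer())
  }

  ## SSCS-level aggregates (both strands pooled, transcript coordinates)
  n_sscs <- nrow(elig)
  sscs_alt <- dplyr::count(sscs_rec[sscs_rec$base != "N", ],
                           .data$pos, .data$base, name = "cnt")
  sscs_n <- dplyr::count(sscs_rec[sscs_rec$base == "N", ],
                         .data$pos, name = "n_N")

  list(gstart = gstart, L = L, frag_bases = fb,
       n_pairs = nrow(fr), n_dcs = n_dcs, n_sscs = n_sscs,
       dcs_alt = dcs_alt, dcs_n = dcs_n,
       sscs_alt = sscs_alt, sscs_n = sscs_n)
}

#' @export
print.dcs_set <- function(x, ...) {
  n_dcs <- sum(vapply(x$subregions, function(s) s$n_dcs, numeric(1)))
  cat("<dcs_set> ", length(x$subregions), " subregions, ",
      n_dcs, " duplex consensus sequences\n", sep = "")
  invisible(x)
}

#' Per-position DCS pileup
#'
#' Coverage counts non-N duplex consensus bases per position; allele
#' counts split the coverage by base, so allele counts always sum to the
#' coverage.
#'
#' @param dcs A `dcs_set` from [call_consensus()].
#' @param model A [ref_model].
#' @return Tibble with `subregion`, `pos` (0-based model coordinate),
#'   `ref`, `coverage`, and `alt_A`/`alt_C`/`alt_G`/`alt_T` counts
#'   (the reference base column holds the reference-supporting count).
#' @export
dcs_pileup <- function(dcs, model) {
  stopifnot(inherits(dcs, "dcs_set"))
  out <- lapply(names(dcs$subregions), function(sub_name) {
    s <- dcs$subregions[[sub_name]]
    pos <- seq_len(s$L) - 1L
    cov <- rep(s$n_dcs, s$L)
    if (nrow(s$dcs_n)) cov[s$dcs_n$pos + 1L] <- cov[s$dcs_n$pos + 1L] -
        s$dcs_n$n_N
    counts <- matrix(0L, nrow = s$L, ncol = 4L,
                     dimnames = list(NULL, DNA_BASES))
    if (nrow(s$dcs_alt)) {
      ac <- dplyr::count(s$dcs_alt, .data$pos, .data$alt, name = "cnt")
      counts[cbind(ac$pos + 1L, match(ac$alt, DNA_BASES))] <- ac$cnt
    }
    ref_idx <- match(s$frag_bases, DNA_BASES)
    alt_tot <- rowSums(counts)
    counts[cbind(seq_len(s$L), ref_idx)] <- cov - alt_tot
    tibble::tibble(subregion = sub_name, pos = s$gstart + pos,
                   ref = s$frag_bases, coverage = cov,
                   alt_A = counts[, "A"], alt_C = counts[, "C"],
                   alt_G = counts[, "G"], alt_T = counts[, "T"])
  })
  dplyr::bind_rows(out)
}

#' Per-position SSCS pileup (both strands pooled)
#'
#' Same shape as [dcs_pileup()] but at the single-strand consensus level;
#' used to quantify the artifact excess that duplex consensus removes.
#'
#' @inheritParams dcs_pileup
#' @return Tibble as in [dcs_pileup()].
#' @export
sscs_pileup <- function(dcs, model) {
  stopifnot(inherits(dcs, "dcs_set"))
  out <- lapply(names(dcs$subregions), function(sub_name) {
    s <- dcs$subregions[[sub_name]]
    pos <- seq_len(s$L) - 1L
    cov <- rep(s$n_sscs, s$L)
    if (nrow(s$sscs_n)) cov[s$sscs_n$pos + 1L] <- cov[s$sscs_n$pos + 1L] -
        s$sscs_n$n_N
    counts <- matrix(0L, nrow = s$L, ncol = 4L,
                     dimnames = list(NULL, DNA_BASES))
    if (nrow(s$sscs_alt)) {
      counts[cbind(s$sscs_alt$pos + 1L,
                   match(s$sscs_alt$base, DNA_BASES))] <- s$sscs_alt$cnt
    }
    ref_idx <- match(s$frag_bases, DNA_BASES)
    alt_tot <- rowSums(counts)
    counts[cbind(seq_len(s$L), ref_idx)] <- cov - alt_tot
    tibble::tibble(subregion = sub_name, pos = s$gstart + pos,
                   ref = s$frag_bases, coverage = cov,
                   alt_A = counts[, "A"], alt_C = counts[, "C"],
                   alt_G = counts[, "G"], alt_T = counts[, "T"])
  })
  dplyr::bind_rows(out)
}

#' Family-level evidence behind each duplex alternate call
#'
#' @param dcs A `dcs_set`.
#' @return Tibble with one row per supporting DCS family and variant:
#'   `subregion`, `pos` (model coordinate), `alt`, `family_key`, strand
#'   family sizes `f_ab`/`f_ba` and consensus support fractions
#'   `supp_ab`/`supp_ba`.
#' @export
consensus_evidence <- function(dcs) {
  stopifnot(inherits(dcs, "dcs_set"))
  out <- lapply(names(dcs$subregions), function(sub_name) {
    s <- dcs$subregions[[sub_name]]
    if (nrow(s$dcs_alt) == 0L) return(NULL)
    tibble::tibble(subregion = sub_name, pos = s$gstart + s$dcs_alt$pos,
                   alt = s$dcs_alt$alt, family_key = s$dcs_alt$family_key,
                   f_ab = s$dcs_alt$f_ab, f_ba = s$dcs_alt$f_ba,
                   supp_ab = s$dcs_alt$supp_ab, supp_ba = s$dcs_alt$supp_ba)
  })
  dplyr::bind_rows(out)
}
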