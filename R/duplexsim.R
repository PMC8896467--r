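#' Simulation configuration for a duplex sequencing library
#'
#' Describes one synthetic library over the subregions of a target layout:
#' double-barcoded read families from both strands of each source molecule,
#' a configurable family-size law, true mutations at set molecular
#' fractions, strand-asymmetric DNA damage (8-oxo-G read as G>T on the
#' damaged strand; cytosine deamination read as C>T), PCR jackpot errors on
#' a branching duplication tree, and per-base sequencing error.
#'
#' Default rates are the package's model of the study conditions: a mean
#' family size of 6 read pairs per strand, 12-base tags, 300-base reads,
#' deamination damage dominating oxidative damage (2e-5 vs 5e-6 per base),
#' a high-fidelity polymerase error rate of 1e-6 per base per duplication
#' over 20 cycles, and an Illumina-like 1e-3 per-base sequencing error.
#' `n_molecules = 23000` per subregion yields a per-position duplex
#' consensus coverage of roughly 11,000 once both strands must reach the
#' minimum family size of 3 reads.
#'
#' @param model A [ref_model].
#' @param layout A [target_layout].
#' @param subregions Character vector of subregion names to simulate
#'   (default: all in the layout).
#' @param n_molecules Source molecules per subregion (>= 1).
#' @param family_size List `list(law = "geometric", mean = 6)`: read pairs
#'   per strand family are drawn iid as `1 + rgeom(prob = 1/mean)`
#'   (support >= 1); or `list(law = "fixed", size = k)`.
#' @param tag_length Length of the random molecular tag at the 5' end of
#'   each read (default 12).
#' @param read_length Total read length including the tag (default 300).
#'   The two mates must jointly cover each fragment:
#'   `2 * (read_length - tag_length)` must be at least the longest
#'   simulated subregion.
#' @param true_variants Data frame with columns `pos` (0-based model
#'   coordinate), `ref`, `alt`, `fraction` (molecular fraction in (0, 1]).
#'   Each molecule carries each variant independently with probability
#'   `fraction`, on both strands.
#' @param damage_rate_oxoG Per-base probability of an 8-oxo-G lesion on a
#'   G of one strand before amplification (top strand: G>T; bottom strand:
#'   read as C>A in transcript coordinates).
#' @param damage_rate_deam Per-base probability of cytosine deamination on
#'   one strand (top: C>T; bottom: read as G>A).
#' @param pcr_error_rate Per-base per-duplication polymerase error
#'   probability; errors are placed on the branching duplication tree and
#'   propagate to all descendant reads (jackpot errors).
#' @param pcr_cycles Depth of the duplication tree.
#' @param seq_error_rate Per-base sequencing error probability per read.
#' @param library_id Library name used in read ids and reports.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model, layout,
                       subregions = NULL,
                       n_molecules = 23000L,
                       family_size = list(law = "geometric", mean = 6),
                       tag_length = 12L,
                       read_length = 300L,
                       true_variants = NULL,
                       damage_rate_oxoG = 5e-6,
                       damage_rate_deam = 2e-5,
                       pcr_error_rate = 1e-6,
                       pcr_cycles = 20L,
                       seq_error_rate = 1e-3,
                       library_id = "lib1") {
  stopifnot(inherits(model, "ref_model"), inherits(layout, "target_layout"))
  if (is.null(subregions)) subregions <- layout$subregions$name
  if (!all(subregions %in% layout$subregions$name)) {
    stop("unknown subregion name(s): ",
         paste(setdiff(subregions, layout$subregions$name), collapse = ", "))
  }
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  rates <- c(damage_rate_oxoG = damage_rate_oxoG,
             damage_rate_deam = damage_rate_deam,
             pcr_error_rate = pcr_error_rate,
             seq_error_rate = seq_error_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("all error/damage rates must lie in [0, 1]")
  }
  if (is.null(true_variants)) {
    true_variants <- tibble::tibble(pos = integer(), ref = character(),
                                    alt = character(), fraction = double())
  }
  true_variants <- tibble::as_tibble(true_variants)
  if (nrow(true_variants)) {
    stopifnot(all(c("pos", "ref", "alt", "fraction") %in% names(true_variants)))
    if (any(true_variants$fraction < 0 | true_variants$fraction > 1)) {
      stop("variant fractions must lie in [0, 1]")
    }
    have <- model$bases[true_variants$pos + 1L]
    if (any(have != true_variants$ref)) {
      stop("true_variants ref does not match the reference sequence")
    }
    sr <- subregion_of(layout, true_variants$pos)
    if (any(is.na(sr)) || !all(sr %in% subregions)) {
      stop("true_variants must fall inside the simulated subregions")
    }
  }
  ins <- read_length - tag_length
  widths <- with(layout$subregions, end - start)[
    layout$subregions$name %in% subregions]
  if (2L * ins < max(widths)) {
    stop("read pairs do not cover the widest subregion: need ",
         "2*(read_length - tag_length) >= ", max(widths))
  }
  structure(
    list(model = model, layout = layout, subregions = subregions,
         n_molecules = as.integer(n_molecules), family_size = family_size,
         tag_length = as.integer(tag_length),
         read_length = as.integer(read_length),
         true_variants = true_variants,
         damage_rate_oxoG = damage_rate_oxoG,
         damage_rate_deam = damage_rate_deam,
         pcr_error_rate = pcr_error_rate,
         pcr_cycles = as.integer(pcr_cycles),
         seq_error_rate = seq_error_rate,
         library_id = library_id),
    class = "sim_config"
  )
}

# family sizes per strand family
draw_family_sizes <- function(fs, n) {
  law <- fs$law %||% "geometric"
  switch(law,
    geometric = 1L + stats::rgeom(n, prob = 1 / fs$mean),
    fixed = rep(as.integer(fs$size), n),
    stop("unknown family_size law: ", law)
  )
}

make_tags <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Apply sparse single-base edits to a character vector of equal-width
# strings. `idx` indexes into `strings`; several edits per string are
# applied in successive vectorised rounds.
apply_edits <- function(strings, idx, off, base) {
  if (length(idx) == 0L) return(strings)
  ord <- order(idx)
  idx <- idx[ord]; off <- off[ord]; base <- base[ord]
  round_of <- stats::ave(seq_along(idx), idx, FUN = seq_along)
  for (r in seq_len(max(round_of))) {
    sel <- which(round_of == r)
    i <- idx[sel]
    s <- strings[i]
    substr(s, off[sel], off[sel]) <- base[sel]
    strings[i] <- s
  }
  strings
}

#' Simulate one duplex sequencing library
#'
#' Generates tagged paired reads and the full ground truth for one library.
#' Each source molecule yields two read families (one per strand)
#' distinguished by tag orientation; true variants appear on both strands
#' of carrier molecules; damage lesions sit on exactly one strand; PCR
#' errors are injected at duplication-tree edges and propagate to all
#' descendant reads; sequencing errors hit single reads. Deterministic
#' given `seed`.
#'
#' @param cfg A [sim_config].
#' @param seed Integer seed controlling every random draw.
#' @return An object of class `duplex_sim`: list with `reads` (tibble
#'   `read_id`, `mate1`, `mate2`; tags are the first `tag_length` bases of
#'   each mate), `truth` (list of tibbles `molecules`, `variants`,
#'   `artifacts`), and the `config`/`seed` used.
#' @export
simulate_library <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(as.integer(seed), simulate_library_impl(cfg))
}

simulate_library_impl <- function(cfg) {
  model <- cfg$model
  lay <- cfg$layout$subregions
  lay <- lay[lay$name %in% cfg$subregions, , drop = FALSE]
  ins <- cfg$read_length - cfg$tag_length

  reads_all <- vector("list", nrow(lay))
  mol_all <- vector("list", nrow(lay))
  var_all <- vector("list", nrow(lay))
  art_all <- vector("list", nrow(lay))

  for (si in seq_len(nrow(lay))) {
    sub_name <- lay$name[si]
    gstart <- lay$start[si]
    L <- lay$end[si] - lay$start[si]
    frag <- substr(model$sequence, gstart + 1L, lay$end[si])
    fb <- seq_chars(frag)
    n <- cfg$n_molecules

    ## molecules and tags -------------------------------------------------
    tag_a <- make_tags(n, cfg$tag_length)
    tag_b <- make_tags(n, cfg$tag_length)

    ## true variant carriers ---------------------------------------------
    tv <- cfg$true_variants
    tv <- tv[subregion_of(cfg$layout, tv$pos) == sub_name, , drop = FALSE]
    mol_diffs <- list()
    var_truth <- NULL
    if (nrow(tv)) {
      carrier_list <- lapply(tv$fraction,
                             function(f) which(stats::runif(n) < f))
      mol_diffs[[length(mol_diffs) + 1L]] <- tibble::tibble(
        mol = unlist(carrier_list),
        strand = 0L,  # both strands
        pos = rep(tv$pos - gstart, lengths(carrier_list)),
        alt = rep(tv$alt, lengths(carrier_list))
      )
      var_truth <- tibble::tibble(
        subregion = sub_name, pos = tv$pos, ref = tv$ref, alt = tv$alt,
        fraction = tv$fraction,
        n_carriers = lengths(carrier_list),
        n_molecules = n,
        expected_vaf = lengths(carrier_list) / n
      )
    }

    ## strand-asymmetric damage -------------------------------------------
    g_sites <- which(fb == "G") - 1L
    c_sites <- which(fb == "C") - 1L
    art <- list()
    draw_lesions <- function(sites, rate, strand, alt_to, type) {
      if (length(sites) == 0L || rate <= 0) return(NULL)
      k <- stats::rbinom(n, length(sites), rate)
      hit <- which(k > 0L)
      if (!length(hit)) return(NULL)
      mol <- rep(hit, k[hit])
      pos <- sites[ceiling(stats::runif(length(mol)) * length(sites))]
      tibble::tibble(mol = mol, strand = strand, pos = pos, alt = alt_to,
                     type = type)
    }
    # top strand (strand 1): oxo-G at G -> T; deamination at C -> T
    # bottom strand (strand 2), in transcript coordinates:
    #   oxo-G on the bottom G (a top C) -> read as C>A
    #   deamination of a bottom C (a top G) -> read as G>A
    art[[1]] <- draw_lesions(g_sites, cfg$damage_rate_oxoG, 1L, "T", "oxoG")
    art[[2]] <- draw_lesions(c_sites, cfg$damage_rate_deam, 1L, "T", "deam")
    art[[3]] <- draw_lesions(c_sites, cfg$damage_rate_oxoG, 2L, "A", "oxoG")
    art[[4]] <- draw_lesions(g_sites, cfg$damage_rate_deam, 2L, "A", "deam")
    art_tbl <- dplyr::bind_rows(art)
    if (nrow(art_tbl)) {
      mol_diffs[[length(mol_diffs) + 1L]] <-
        art_tbl[, c("mol", "strand", "pos", "alt")]
    }
    mol_diffs <- dplyr::bind_rows(mol_diffs)

    ## read pairs per strand family ---------------------------------------
    f <- draw_family_sizes(cfg$family_size, 2L * n)
    fam_mol <- rep(seq_len(n), 2L)
    fam_strand <- rep(1:2, each = n)
    P <- sum(f)
    pair_mol <- rep(fam_mol, f)
    pair_strand <- rep(fam_strand, f)
    pair_u <- stats::runif(P)  # lineage path through the duplication tree

    ## PCR errors on the spanned duplication-tree edges --------------------
    pcr <- NULL
    if (cfg$pcr_error_rate > 0 && cfg$pcr_cycles > 0L) {
      C <- cfg$pcr_cycles
      fam_id <- (pair_mol - 1L) * 2L + pair_strand
      edges <- dplyr::distinct(tibble::tibble(
        fam = rep(fam_id, each = C),
        c = rep(seq_len(C), times = P),
        anc = floor(rep(pair_u, each = C) * 2^rep(seq_len(C), times = P))
      ))
      k <- stats::rbinom(nrow(edges), L, cfg$pcr_error_rate)
      ev <- edges[k > 0L, , drop = FALSE]
      k <- k[k > 0L]
      if (nrow(ev)) {
        ev <- ev[rep(seq_len(nrow(ev)), k), , drop = FALSE]
        ev$pos <- ceiling(stats::runif(nrow(ev)) * L) - 1L
        ev$alt <- random_alt(fb[ev$pos + 1L])
        ev$event <- seq_len(nrow(ev))
        pairs_tbl <- tibble::tibble(pair = seq_len(P), fam = fam_id,
                                    u = pair_u)
        hits <- dplyr::inner_join(ev, pairs_tbl, by = "fam",
                                  relationship = "many-to-many")
        hits <- hits[floor(hits$u * 2^hits$c) == hits$anc, , drop = FALSE]
        pcr <- tibble::tibble(pair = hits$pair, pos = hits$pos,
                              alt = hits$alt)
      }
    }

    ## expand template-level diffs to per-read observations ----------------
    # sides: "L" covers [0, ins), "R" covers [L - ins, L)
    ins_eff <- min(ins, L)
    r_start <- max(L - ins, 0L)
    tmpl <- list()
    if (nrow(mol_diffs)) {
      # join molecule/strand diffs onto pairs
      md1 <- mol_diffs[mol_diffs$strand == 0L, c("mol", "pos", "alt")]
      md_s <- mol_diffs[mol_diffs$strand != 0L, ]
      pj <- tibble::tibble(pair = seq_len(P), mol = pair_mol,
                           strand = pair_strand)
      both <- dplyr::inner_join(pj, md1, by = "mol",
                                relationship = "many-to-many")
      one <- dplyr::inner_join(pj, md_s, by = c("mol", "strand"),
                               relationship = "many-to-many")
      tmpl[[1]] <- tibble::tibble(pair = both$pair, pos = both$pos,
                                  alt = both$alt)
      tmpl[[2]] <- tibble::tibble(pair = one$pair, pos = one$pos,
                                  alt = one$alt)
    }
    if (!is.null(pcr)) tmpl[[length(tmpl) + 1L]] <- pcr
    tmpl <- if (length(tmpl)) dplyr::bind_rows(tmpl) else
      tibble::tibble(pair = integer(), pos = integer(), alt = character())
    # de-duplicate conflicting template diffs at one (pair, pos): damage and
    # PCR override the molecule base (last layer wins in bind order)
    tmpl <- dplyr::slice_tail(dplyr::group_by(tmpl, .data$pair, .data$pos),
                              n = 1L)
    tmpl <- dplyr::ungroup(tmpl)

    obs_t <- list()
    onL <- tmpl$pos < ins_eff
    onR <- tmpl$pos >= r_start
    obs_t[[1]] <- tibble::tibble(pair = tmpl$pair[onL], side = "L",
                                 pos = tmpl$pos[onL], alt = tmpl$alt[onL],
                                 prio = 1L)
    obs_t[[2]] <- tibble::tibble(pair = tmpl$pair[onR], side = "R",
                                 pos = tmpl$pos[onR], alt = tmpl$alt[onR],
                                 prio = 1L)

    ## sequencing errors ---------------------------------------------------
    for (side in c("L", "R")) {
      w <- if (side == "L") ins_eff else L - r_start
      k <- stats::rbinom(P, w, cfg$seq_error_rate)
      hit <- which(k > 0L)
      if (!length(hit)) next
      pr <- rep(hit, k[hit])
      off <- ceiling(stats::runif(length(pr)) * w)
      pos <- if (side == "L") off - 1L else r_start + off - 1L
      obs_t[[length(obs_t) + 1L]] <- tibble::tibble(
        pair = pr, side = side, pos = pos,
        alt = random_alt(fb[pos + 1L]), prio = 2L)
    }
    obs <- dplyr::bind_rows(obs_t)

    ## resolve collisions: sequencing error on top of a template diff keeps
    ## the error, redrawn relative to the template base it actually replaced
    if (nrow(obs)) {
      obs <- dplyr::arrange(obs, .data$pair, .data$side, .data$pos,
                            .data$prio)
      grp <- paste(obs$pair, obs$side, obs$pos)
      last <- !duplicated(grp, fromLast = TRUE)
      first <- !duplicated(grp)
      multi <- which(last & !first)
      if (length(multi)) {
        gfirst <- match(grp[multi], grp)
        needs <- obs$prio[multi] == 2L & obs$prio[gfirst] == 1L
        obs$alt[multi[needs]] <- random_alt(obs$alt[gfirst[needs]])
      }
      obs <- obs[last, , drop = FALSE]
      obs <- obs[obs$alt != fb[obs$pos + 1L], , drop = FALSE]
    }

    ## materialize read strings -------------------------------------------
    left_t <- substr(frag, 1L, ins_eff)
    right_t <- substr(frag, r_start + 1L, L)
    sL <- rep(left_t, P)
    sR <- rep(right_t, P)
    oL <- obs[obs$side == "L", , drop = FALSE]
    oR <- obs[obs$side == "R", , drop = FALSE]
    sL <- apply_edits(sL, oL$pair, oL$pos + 1L, oL$alt)
    sR <- apply_edits(sR, oR$pair, oR$pos - r_start + 1L, oR$alt)
    sR_rc <- revcomp(sR)

    ta <- tag_a[pair_mol]
    tb <- tag_b[pair_mol]
    isA <- pair_strand == 1L
    mate1 <- character(P)
    mate2 <- character(P)
    # strand A: R1 reads the left side forward, R2 the right side reverse;
    # strand B: mirrored, with the tags swapped
    mate1[isA] <- paste0(ta[isA], sL[isA])
    mate2[isA] <- paste0(tb[isA], sR_rc[isA])
    mate1[!isA] <- paste0(tb[!isA], sR_rc[!isA])
    mate2[!isA] <- paste0(ta[!isA], sL[!isA])

    reads_all[[si]] <- tibble::tibble(
      read_id = sprintf("%s:%s:%07d", cfg$library_id, sub_name, seq_len(P)),
      mate1 = mate1, mate2 = mate2
    )
    mol_all[[si]] <- tibble::tibble(
      subregion = sub_name, mol = seq_len(n), tag_a = tag_a, tag_b = tag_b,
      f_top = f[seq_len(n)], f_bottom = f[n + seq_len(n)]
    )
    var_all[[si]] <- var_truth
    if (nrow(art_tbl)) {
      art_tbl$pos <- art_tbl$pos + gstart
      art_tbl$subregion <- sub_name
      art_all[[si]] <- art_tbl
    }
  }

  structure(
    list(
      library_id = cfg$library_id,
      reads = dplyr::bind_rows(reads_all),
      truth = list(
        molecules = dplyr::bind_rows(mol_all),
        variants = dplyr::bind_rows(var_all),
        artifacts = dplyr::bind_rows(art_all)
      ),
      config = cfg
    ),
    class = "duplex_sim"
  )
}

#' @export
print.duplex_sim <- function(x, ...) {
  cat("<duplex_sim> ", x$library_id, ": ", nrow(x$reads), " read pairs, ",
      nrow(x$truth$molecules), " molecules, ",
      nrow(x$truth$variants), " true variants\n", sep = "")
  invisible(x)
}

#' Simulate a spike-in dilution series
#'
#' One library per dilution, each carrying `variants_per_library` spiked
#' variants at the stated molecular fraction (the nominal dilution equals
#' the expected variant allele frequency). Spiked positions are distinct
#' across the whole series and drawn from exonic positions of the simulated
#' subregions; the combined truth table records nominal and realised
#' fractions per variant.
#'
#' @param base_cfg A [sim_config] used as the template for every library
#'   (its `true_variants` are replaced by the spike-ins).
#' @param dilutions Numeric vector of molecular fractions in (0, 1), e.g.
#'   `c(0.1, 0.01, 0.001, 0.0001)`.
#' @param variants_per_library Spiked variants per library (default 4).
#' @param seed Integer seed for position draws and library simulation.
#' @param positions Optional integer vector of 0-based spike positions
#'   (length `length(dilutions) * variants_per_library`, all distinct);
#'   drawn at random when NULL.
#' @return A list with `libraries` (list of [simulate_library()] results,
#'   one per dilution, library ids `<id>_d<k>`) and `truth` (combined
#'   spike-in truth tibble with `library_id`).
#' @export
simulate_spikein_series <- function(base_cfg, dilutions,
                                    variants_per_library = 4L,
                                    seed = 1L, positions = NULL) {
  stopifnot(inherits(base_cfg, "sim_config"))
  if (length(dilutions) == 0L) {
    return(list(libraries = list(),
                truth = tibble::tibble(library_id = character())))
  }
  if (any(dilutions <= 0 | dilutions >= 1)) {
    stop("dilutions must lie in (0, 1)")
  }
  model <- base_cfg$model
  lay <- base_cfg$layout
  n_spike <- length(dilutions) * variants_per_library
  if (is.null(positions)) {
    lay_sub <- lay$subregions[lay$subregions$name %in% base_cfg$subregions, ]
    cand <- unlist(lapply(seq_len(nrow(lay_sub)), function(i) {
      seq(lay_sub$start[i], lay_sub$end[i] - 1L)
    }))
    cand <- cand[classify_site(model, cand) == "exonic"]
    positions <- withr::with_seed(as.integer(seed) + 7777L,
                                  sample(cand, n_spike))
  }
  if (anyDuplicated(positions)) stop("duplicate spiked positions")
  if (length(positions) != n_spike) {
    stop("need ", n_spike, " spike positions, got ", length(positions))
  }
  alts <- withr::with_seed(as.integer(seed) + 7778L,
                           random_alt(model$bases[positions + 1L]))
  libs <- vector("list", length(dilutions))
  truth <- vector("list", length(dilutions))
  for (k in seq_along(dilutions)) {
    idx <- (k - 1L) * variants_per_library + seq_len(variants_per_library)
    cfg_k <- base_cfg
    cfg_k$library_id <- sprintf("%s_d%d", base_cfg$library_id, k)
    cfg_k$true_variants <- tibble::tibble(
      pos = as.integer(positions[idx]),
      ref = model$bases[positions[idx] + 1L],
      alt = alts[idx],
      fraction = dilutions[k]
    )
    libs[[k]] <- simulate_library(cfg_k, seed = as.integer(seed) + k)
    tt <- libs[[k]]$truth$variants
    tt$library_id <- cfg_k$library_id
    truth[[k]] <- tt
  }
  list(libraries = libs, truth = dplyr::bind_rows(truth))
}

#' Write / read simulated paired reads as FASTQ
#'
#' Standard 4-line FASTQ with constant base qualities (Q37); files are
#' written as `<library_id>_R1.fastq` / `_R2.fastq` (optionally gzipped).
#'
#' @param sim A `duplex_sim` object.
#' @param dir Output directory (created if needed).
#' @param gzip Compress output files.
#' @return Invisibly, the two file paths.
#' @export
write_fastq <- function(sim, dir, gzip = FALSE) {
  stopifnot(inherits(sim, "duplex_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- file.path(dir, paste0(sim$library_id, c("_R1", "_R2"), ext))
  qual <- strrep("F", nchar(sim$reads$mate1[1]))
  for (m in 1:2) {
    seqs <- sim$reads[[paste0("mate", m)]]
    rec <- paste0("@", sim$reads$read_id, "/", m, "\n", seqs, "\n+\n", qual)
    con <- if (gzip) gzfile(paths[m], "wb") else file(paths[m], "wb")
    writeLines(rec, con)
    close(con)
  }
  invisible(paths)
}

#' @rdname write_fastq
#' @param r1,r2 Paths to the two mate FASTQ files.
#' @return `read_fastq()`: a tibble with `read_id`, `mate1`, `mate2`.
#' @export
read_fastq <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  ids <- sub("/[12]$", "", sub("\\s.*$", "", names(s1)))
  tibble::tibble(read_id = ids,
                 mate1 = unname(as.character(s1)),
                 mate2 = unname(as.character(s2)))
}
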