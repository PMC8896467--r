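#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' Per codon, each of the three positions contributes a fractional
#' synonymous-site count equal to (number of synonymous single-base
#' changes at that position) / 3; the nonsynonymous sites are the
#' complement, so every codon contributes exactly 3 sites in total.
#' Changes creating a stop codon count as nonsynonymous. The region is
#' assumed to contain sense codons only (a stop codon in the input is an
#' error).
#'
#' @param cds_region In-frame coding sequence (string, length a multiple
#'   of 3, sense codons only).
#' @return One-row tibble with `N_sites`, `S_sites`, `n_codons`.
#' @export
ng_site_counts <- function(cds_region) {
  n <- nchar(cds_region)
  if (n %% 3L != 0L) stop("coding region length is not a multiple of 3")
  codons <- substring(cds_region, seq(1L, n, 3L), seq(3L, n, 3L))
  if (any(codon_to_aa(codons) == "*")) {
    stop("stop codon inside the coding region")
  }
  tab <- ng_codon_syn_table()
  s <- sum(tab[codons])
  tibble::tibble(N_sites = 3 * length(codons) - s, S_sites = s,
                 n_codons = length(codons))
}

# Synonymous sites per codon (cached): enumerate the 9 single-base
# changes of each sense codon; fraction of synonymous ones / 3 per
# position summed over the codon.
ng_codon_syn_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- sense_codons()
    syn <- vapply(codons, function(cod) {
      b <- seq_chars(cod)
      aa <- codon_to_aa(cod)
      k <- 0L
      for (p in 1:3) {
        for (nb in setdiff(DNA_BASES, b[p])) {
          b2 <- b
          b2[p] <- nb
          if (codon_to_aa(paste0(b2, collapse = "")) == aa) k <- k + 1L
        }
      }
      k / 3
    }, numeric(1))
    cache <<- syn
    cache
  }
})

#' Observed dN/dS ratio
#'
#' dN is the number of nonsynonymous mutations per nonsynonymous site,
#' dS the number of synonymous mutations per synonymous site
#' (Nei-Gojobori site counts). Stop-gained variants count as
#' nonsynonymous; splice-region and intronic variants are excluded.
#'
#' @param variants Variant table with a `category` column (rows are
#'   counted as supplied; collapse beforehand if desired).
#' @param site_counts Output of [ng_site_counts()] for the region.
#' @return One-row tibble: `n_nonsyn`, `n_syn`, `dN`, `dS`, `dnds`
#'   (NA when `dS` is 0 — undefined, not infinite).
#' @export
dnds <- function(variants, site_counts) {
  n_nonsyn <- sum(variants$category %in% c("missense", "stop_gained"))
  n_syn <- sum(variants$category == "synonymous")
  dN <- n_nonsyn / site_counts$N_sites
  dS <- n_syn / site_counts$S_sites
  tibble::tibble(n_nonsyn = n_nonsyn, n_syn = n_syn,
                 dN = dN, dS = dS,
                 dnds = ifelse(dS > 0, dN / dS, NA_real_))
}

# Per-site, per-class change table for a coding region: for every
# position and every pyrimidine-centred class compatible with its
# reference base, whether the induced change is synonymous.
ng_change_table <- function(cds_region) {
  n <- nchar(cds_region)
  if (n %% 3L != 0L) stop("coding region length is not a multiple of 3")
  b <- seq_chars(cds_region)
  classes <- sbs_classes()
  pyr <- substr(classes, 1L, 1L)
  alt <- substr(classes, 3L, 3L)
  codon_idx <- (seq_len(n) - 1L) %/% 3L
  frame <- (seq_len(n) - 1L) %% 3L
  codons <- substring(cds_region, 3L * codon_idx + 1L, 3L * codon_idx + 3L)
  aa0 <- codon_to_aa(codons)
  out <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    match_pyr <- b == pyr[k]
    match_pur <- b == comp_base(pyr[k])
    sites <- which(match_pyr | match_pur)
    if (!length(sites)) {
      out[[k]] <- tibble::tibble(class = character(), pos = integer(),
                                 syn = logical())
      next
    }
    induced <- ifelse(b[sites] == pyr[k], alt[k], comp_base(alt[k]))
    cod <- codons[sites]
    fr <- frame[sites]
    cod_new <- cod
    substr(cod_new, fr + 1L, fr + 1L) <- induced
    syn <- codon_to_aa(cod_new) == aa0[sites]
    out[[k]] <- tibble::tibble(class = classes[k], pos = sites - 1L,
                               syn = syn)
  }
  dplyr::bind_rows(out)
}

#' Spectrum-preserving randomization null for dN/dS
#'
#' Distribution of dN/dS ratios expected if the observed spectrum of
#' mutational changes fell at random with respect to nonsynonymous and
#' synonymous sites: each iteration places `n_mutations` by drawing a
#' substitution class from the observed 6-class spectrum and then a
#' uniformly random compatible site of the region (with replacement),
#' classifies each induced change, and computes dN/dS with the region's
#' Nei-Gojobori site counts.
#'
#' @param spectrum Observed 6-class spectrum: a `spectrum_matrix`, or a
#'   numeric vector of 6 counts/weights in [sbs_classes()] order.
#' @param cds_region In-frame sense-codon sequence of the region.
#' @param n_mutations Number of mutations to place per iteration (>= 1).
#' @param iterations Number of draws (default 1000).
#' @param seed Integer seed; draws are reproducible.
#' @param range `"percentile"` reports the 2.5/97.5 percentiles of the
#'   draws as the null range, `"minmax"` the extremes.
#' @return Object of class `dnds_null`: list with `draws` (NA where a
#'   draw had no synonymous placements), `null_median`, `null_lower`,
#'   `null_upper`, `n`, `iterations`.
#' @export
dnds_null <- function(spectrum, cds_region, n_mutations,
                      iterations = 1000L, seed = 1L,
                      range = c("percentile", "minmax")) {
  range <- match.arg(range)
  if (inherits(spectrum, "spectrum_matrix")) spectrum <- spectrum$count
  stopifnot(length(spectrum) == 6L)
  if (n_mutations < 1L) stop("n_mutations must be >= 1")
  if (sum(spectrum) <= 0) stop("empty spectrum")
  prob <- spectrum / sum(spectrum)
  tab <- ng_change_table(cds_region)
  syn_by_class <- split(tab$syn, factor(tab$class, levels = sbs_classes()))
  empty <- vapply(syn_by_class, length, integer(1)) == 0L
  if (any(prob > 0 & empty)) {
    stop("spectrum class with positive mass but no compatible sites: ",
         paste(sbs_classes()[prob > 0 & empty], collapse = ", "))
  }
  sc <- ng_site_counts(cds_region)
  draws <- withr::with_seed(as.integer(seed), {
    m <- as.integer(iterations) * as.integer(n_mutations)
    cls <- sample.int(6L, m, replace = TRUE, prob = prob)
    syn <- logical(m)
    for (k in 1:6) {
      sel <- cls == k
      if (any(sel)) {
        pool <- syn_by_class[[k]]
        syn[sel] <- pool[ceiling(stats::runif(sum(sel)) * length(pool))]
      }
    }
    it <- rep(seq_len(iterations), each = n_mutations)
    n_syn <- as.vector(rowsum(as.integer(syn), it))
    n_non <- n_mutations - n_syn
    dn <- n_non / sc$N_sites
    ds <- n_syn / sc$S_sites
    ifelse(ds > 0, dn / ds, NA_real_)
  })
  lim <- if (range == "percentile") {
    stats::quantile(draws, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  } else {
    c(min(draws, na.rm = TRUE), max(draws, na.rm = TRUE))
  }
  structure(list(draws = draws,
                 null_median = stats::median(draws, na.rm = TRUE),
                 null_lower = lim[1], null_upper = lim[2],
                 n = as.integer(n_mutations),
                 iterations = as.integer(iterations),
                 range = range),
            class = "dnds_null")
}

#' @export
print.dnds_null <- function(x, ...) {
  cat("<dnds_null> median ", round(x$null_median, 3), " [",
      round(x$null_lower, 3), ", ", round(x$null_upper, 3), "] (",
      x$iterations, " iterations, n = ", x$n, ")\n", sep = "")
  invisible(x)
}

# Coding sequence of a model (concatenated exons), optionally restricted
# to whole codons of an amino-acid interval.
cds_sequence <- function(model, aa_start = NULL, aa_end = NULL) {
  cds <- paste0(model$bases[!is.na(model$cds_index)][
    order(model$cds_index[!is.na(model$cds_index)])], collapse = "")
  if (is.null(aa_start)) return(cds)
  off <- model$cds_start_offset
  total_aa <- (off + nchar(cds)) %/% 3L
  aa_start <- max(aa_start, off %/% 3L + 1L)
  aa_end <- min(aa_end, total_aa)
  if (aa_end < aa_start) return("")
  from <- (aa_start - 1L) * 3L + 1L - off
  to <- aa_end * 3L - off
  substr(cds, from, to)
}

#' dN/dS report across strata with randomization nulls
#'
#' One row per stratum (overall plus each combination of the `by`
#' columns): observed nonsynonymous/synonymous counts, dN/dS over the
#' stratum's coding region (the domain's codons for domain strata, the
#' whole modelled CDS otherwise), the randomization-null summary, and a
#' flag for ratios outside the null range. Splice-region and intronic
#' variants are excluded; strata with no synonymous observations report
#' an undefined (NA) ratio.
#'
#' @param variants Annotated variant table (needs `category`; `domain`
#'   and any grouping columns referenced in `by`).
#' @param model A [ref_model].
#' @param layout A [target_layout] (for domain codon intervals).
#' @param by Character vector of stratifying columns (e.g.
#'   `c("domain", "age_group")`); NULL for the overall row only.
#' @param spectrum 6-class spectrum used for every null (default: the
#'   spectrum of all supplied coding variants — a shared, stable
#'   estimate of the mutational process).
#' @param iterations,seed,range Passed to [dnds_null()].
#' @return Tibble with one row per stratum: counts, `dN`, `dS`, `dnds`,
#'   `null_median`, `null_lower`, `null_upper`, `outside_null`.
#' @export
dnds_report <- function(variants, model, layout, by = NULL,
                        spectrum = NULL, iterations = 1000L, seed = 1L,
                        range = c("percentile", "minmax")) {
  range <- match.arg(range)
  coding <- variants[variants$category %in%
                       c("synonymous", "missense", "stop_gained"), ,
                     drop = FALSE]
  if (is.null(spectrum)) {
    spectrum <- mutation_spectrum(coding, model, context = 6)
  }
  strata <- list(list(label = "all", rows = coding, domain = NA))
  if (!is.null(by) && nrow(coding)) {
    combos <- dplyr::distinct(coding[, by, drop = FALSE])
    combos <- combos[stats::complete.cases(combos), , drop = FALSE]
    for (i in seq_len(nrow(combos))) {
      sel <- rep(TRUE, nrow(coding))
      for (col in by) sel <- sel & coding[[col]] %in% combos[[col]][i]
      lab <- paste(unlist(combos[i, ]), collapse = " / ")
      dom <- if ("domain" %in% by) combos$domain[i] else NA
      strata[[length(strata) + 1L]] <-
        list(label = lab, rows = coding[sel, , drop = FALSE], domain = dom)
    }
  }
  rows <- lapply(strata, function(s) {
    cds <- if (!is.na(s$domain)) {
      d <- layout$domains[layout$domains$name == s$domain, ]
      cds_sequence(model, d$aa_start, d$aa_end)
    } else {
      cds_sequence(model)
    }
    sc <- ng_site_counts(cds)
    obs <- dnds(s$rows, sc)
    n <- obs$n_nonsyn + obs$n_syn
    if (n >= 1L) {
      nl <- dnds_null(spectrum, cds, n, iterations = iterations,
                      seed = seed, range = range)
      nm <- nl$null_median; lo <- nl$null_lower; hi <- nl$null_upper
    } else {
      nm <- NA_real_; lo <- NA_real_; hi <- NA_real_
    }
    tibble::tibble(stratum = s$label, n_nonsyn = obs$n_nonsyn,
                   n_syn = obs$n_syn, N_sites = sc$N_sites,
                   S_sites = sc$S_sites, dN = obs$dN, dS = obs$dS,
                   dnds = obs$dnds, null_median = nm, null_lower = lo,
                   null_upper = hi,
                   outside_null = !is.na(obs$dnds) & !is.na(lo) &
                     (obs$dnds < lo | obs$dnds > hi))
  })
  dplyr::bind_rows(rows)
}
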