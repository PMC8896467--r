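#' Pyrimidine-centred substitution classes
#'
#' Fixed class order used throughout: C>A, C>G, C>T, T>A, T>C, T>G.
#' Variants with a purine reference are folded onto these classes by
#' reverse complement. In 96-context mode each class carries the 16
#' 5'/3' flanking-base combinations, ordered alphabetically within the
#' class (e.g. `A[C>A]A`, `A[C>A]C`, ...).
#'
#' @return Character vector of class labels.
#' @export
sbs_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' @rdname sbs_classes
#' @export
sbs_contexts_96 <- function() {
  cls <- sbs_classes()
  unlist(lapply(cls, function(k) {
    ref <- substr(k, 1L, 1L)
    ctx <- expand.grid(three = DNA_BASES, five = DNA_BASES,
                       stringsAsFactors = FALSE)
    ctx <- ctx[order(ctx$five, ctx$three), ]
    paste0(ctx$five, "[", k, "]", ctx$three)
  }))
}

# Fold a variant to its pyrimidine-centred class; returns list with
# class ref/alt and whether folding (reverse complement) was applied.
fold_substitution <- function(ref, alt) {
  flip <- ref %in% c("A", "G")
  tibble::tibble(
    class_ref = ifelse(flip, comp_base(ref), ref),
    class_alt = ifelse(flip, comp_base(alt), alt),
    folded = flip
  )
}

#' Mutational spectrum with opportunity counts
#'
#' Counts variants per substitution class (6 pyrimidine-centred classes,
#' or 96 trinucleotide contexts) and, for each category, the number of
#' reference alleles/contexts available in the analysed region (the
#' opportunity used for normalisation).
#'
#' @param variants Data frame with `pos` (0-based), `ref`, `alt`; the
#'   same variant may appear several times (e.g. per library) and every
#'   row is counted.
#' @param model A [ref_model].
#' @param context `6` or `96`.
#' @param positions Optional integer vector of 0-based positions defining
#'   the analysed region (default: every position of the model). In
#'   96-context mode, positions at the sequence edge (without both
#'   flanking bases) raise an error naming the position.
#' @return A tibble of class `spectrum_matrix` with `category`, `count`,
#'   `opportunity`; attributes `context` and `region_size`.
#' @export
mutation_spectrum <- function(variants, model, context = 6,
                              positions = NULL) {
  context <- as.integer(context)
  stopifnot(context %in% c(6L, 96L))
  if (is.null(positions)) positions <- seq_len(model$length) - 1L
  region_size <- length(positions)
  ref_bases <- model$bases[positions + 1L]
  variants <- tibble::as_tibble(variants)
  have <- model$bases[variants$pos + 1L]
  if (nrow(variants) && any(have != variants$ref)) {
    stop("variant ref does not match the reference sequence")
  }
  fold <- fold_substitution(variants$ref, variants$alt)
  if (context == 6L) {
    cats <- sbs_classes()
    lab <- if (nrow(variants)) {
      paste0(fold$class_ref, ">", fold$class_alt)
    } else character()
    counts <- table(factor(lab, levels = cats))
    pyr_count <- c(C = sum(ref_bases %in% c("C", "G")),
                   T = sum(ref_bases %in% c("A", "T")))
    opportunity <- pyr_count[substr(cats, 1L, 1L)]
  } else {
    cats <- sbs_contexts_96()
    if (nrow(variants)) {
      if (any(variants$pos < 1L | variants$pos >= model$length - 1L)) {
        bad <- variants$pos[variants$pos < 1L |
                              variants$pos >= model$length - 1L][1L]
        stop("no trinucleotide context at 0-based position ", bad)
      }
      five <- model$bases[variants$pos]
      three <- model$bases[variants$pos + 2L]
      f5 <- ifelse(fold$folded, comp_base(three), five)
      f3 <- ifelse(fold$folded, comp_base(five), three)
      lab <- paste0(f5, "[", fold$class_ref, ">", fold$class_alt, "]", f3)
    } else {
      lab <- character()
    }
    counts <- table(factor(lab, levels = cats))
    ## context opportunities over the region, folded to pyrimidine centre
    inner <- positions[positions >= 1L & positions <= model$length - 2L]
    ctr <- model$bases[inner + 1L]
    l5 <- model$bases[inner]
    r3 <- model$bases[inner + 2L]
    flip <- ctr %in% c("A", "G")
    tri <- paste0(ifelse(flip, comp_base(r3), l5),
                  ifelse(flip, comp_base(ctr), ctr),
                  ifelse(flip, comp_base(l5), r3))
    tri_counts <- table(tri)
    ctx_of <- paste0(substr(cats, 1L, 1L), substr(cats, 3L, 3L),
                     substr(cats, 7L, 7L))
    opportunity <- as.integer(tri_counts[ctx_of])
    opportunity[is.na(opportunity)] <- 0L
  }
  out <- tibble::tibble(category = cats,
                        count = as.integer(counts),
                        opportunity = as.integer(opportunity))
  class(out) <- c("spectrum_matrix", class(out))
  attr(out, "context") <- context
  attr(out, "region_size") <- region_size
  out
}

#' Marginalise a 96-context spectrum to the 6 substitution classes
#'
#' @param spectrum A 96-context `spectrum_matrix`.
#' @return A 6-class `spectrum_matrix`; counts sum within class, context
#'   opportunities collapse to per-class reference-allele counts.
#' @export
collapse_spectrum <- function(spectrum) {
  stopifnot(attr(spectrum, "context") == 96L)
  cls <- substr(spectrum$category, 3L, 5L)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(category = factor(cls,
                                                     levels = sbs_classes()),
                                   count = spectrum$count,
                                   opportunity = spectrum$opportunity),
                    .data$category),
    count = sum(.data$count), opportunity = sum(.data$opportunity),
    .groups = "drop")
  out$category <- as.character(out$category)
  class(out) <- c("spectrum_matrix", class(out))
  attr(out, "context") <- 6L
  attr(out, "region_size") <- attr(spectrum, "region_size")
  out
}

#' Opportunity-normalised per-class mutation frequencies
#'
#' Frequency of each substitution class per sequenced nucleotide of that
#' class: `count / ((opportunity / region_size) * sum(mean_coverage_i *
#' region_size_i))`. Classes with zero count and zero opportunity report
#' 0; a nonzero count with zero opportunity is an error.
#'
#' @param spectrum A `spectrum_matrix`.
#' @param summaries [library_summaries()] output.
#' @return The spectrum tibble with a `frequency` column added.
#' @export
normalized_frequency_spectrum <- function(spectrum, summaries) {
  region_size <- attr(spectrum, "region_size")
  exposure <- sum(summaries$mean_coverage * summaries$region_size)
  if (any(spectrum$count > 0L & spectrum$opportunity == 0L)) {
    stop("nonzero count with zero opportunity")
  }
  denom <- (spectrum$opportunity / region_size) * exposure
  out <- spectrum
  out$frequency <- ifelse(spectrum$count == 0L & denom == 0, 0,
                          spectrum$count / denom)
  out
}

#' Strand-assigned substitution spectrum
#'
#' Assigns each variant to the untranscribed (coding) or transcribed
#' strand according to where the pyrimidine of its folded class lies: a
#' pyrimidine reference on the coding strand is counted as
#' untranscribed.
#'
#' @inheritParams mutation_spectrum
#' @return Tibble with `category`, `strand`, `count` (12 rows).
#' @export
strand_spectrum <- function(variants, model) {
  variants <- tibble::as_tibble(variants)
  fold <- fold_substitution(variants$ref, variants$alt)
  lab <- if (nrow(variants)) {
    paste0(fold$class_ref, ">", fold$class_alt)
  } else character()
  strand <- ifelse(fold$folded, "transcribed", "untranscribed")
  tab <- table(factor(lab, levels = sbs_classes()),
               factor(strand, levels = c("untranscribed", "transcribed")))
  out <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("category", "strand", "count")
  out
}

#' Cosine similarity between two spectra
#'
#' @param a,b Non-negative numeric vectors over the same category space,
#'   or `spectrum_matrix` tibbles (their `count` columns are used).
#' @return Cosine similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (inherits(a, "spectrum_matrix")) a <- a$count
  if (inherits(b, "spectrum_matrix")) b <- b$count
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Bootstrap reference distribution of cosine similarity
#'
#' Expected cosine similarity when `n` mutations are drawn from the
#' reference spectrum: each iteration resamples `n` mutations from the
#' reference's category distribution and computes the cosine of the
#' resample against the original reference (`n` is the number of
#' mutations in the query spectrum). With `resample_both = TRUE` two
#' independent resamples of size `n` are compared instead.
#'
#' @param reference Reference spectrum (`spectrum_matrix` or count
#'   vector), total > 0.
#' @param n Number of mutations to draw per iteration (>= 1).
#' @param iterations Number of bootstrap draws (default 1000).
#' @param seed Integer seed; draws are reproducible.
#' @param resample_both See above (default FALSE).
#' @return Object of class `cosine_bootstrap`: list with `draws`
#'   (length `iterations`), `n`, `iterations`.
#' @export
bootstrap_cosine_reference <- function(reference, n, iterations = 1000L,
                                       seed = 1L, resample_both = FALSE) {
  if (inherits(reference, "spectrum_matrix")) reference <- reference$count
  if (n < 1L) stop("n must be >= 1")
  tot <- sum(reference)
  if (tot <= 0) stop("reference spectrum is empty")
  prob <- reference / tot
  draws <- withr::with_seed(as.integer(seed), {
    res <- stats::rmultinom(iterations, n, prob)
    other <- if (resample_both) {
      stats::rmultinom(iterations, n, prob)
    } else {
      matrix(reference, nrow = length(reference), ncol = iterations)
    }
    vapply(seq_len(iterations),
           function(i) cosine_similarity(res[, i], other[, i]),
           numeric(1))
  })
  structure(list(draws = draws, n = as.integer(n),
                 iterations = as.integer(iterations)),
            class = "cosine_bootstrap")
}

#' Compare a query spectrum against a reference with a bootstrap null
#'
#' @param query,reference Spectra over the same category space.
#' @param iterations,seed Passed to [bootstrap_cosine_reference()].
#' @return Object of class `cosine_comparison`: observed cosine, the
#'   bootstrap reference distribution at `n = sum(query)`, and the
#'   empirical fraction of bootstrap draws below the observed value.
#' @export
compare_spectra <- function(query, reference, iterations = 1000L,
                            seed = 1L) {
  if (inherits(query, "spectrum_matrix")) query <- query$count
  obs <- cosine_similarity(query, reference)
  boot <- bootstrap_cosine_reference(reference, n = sum(query),
                                     iterations = iterations, seed = seed)
  structure(list(observed = obs, bootstrap = boot,
                 frac_below = mean(boot$draws < obs)),
            class = "cosine_comparison")
}

#' @export
print.cosine_comparison <- function(x, ...) {
  q <- stats::quantile(x$bootstrap$draws, c(0.025, 0.975))
  cat("<cosine_comparison> observed ", round(x$observed, 4),
      "; bootstrap reference 95% [", round(q[1], 4), ", ",
      round(q[2], 4), "] at n = ", x$bootstrap$n, "\n", sep = "")
  invisible(x)
}
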