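#' Variant allele frequency
#'
#' Alternate-supporting DCS count divided by DCS coverage at the
#' position.
#'
#' @param alt_count,coverage Non-negative integers, `coverage > 0`.
#' @return Numeric vector of exact ratios.
#' @export
vaf <- function(alt_count, coverage) {
  if (any(coverage <= 0)) stop("coverage must be positive")
  if (any(alt_count < 0 | alt_count > coverage)) {
    stop("alt_count must lie in [0, coverage]")
  }
  alt_count / coverage
}

#' Per-library summaries for the mutation-frequency formula
#'
#' Builds one row per library: the variant count after within-library
#' collapse (identical substitutions inside one library counted once),
#' the mean DCS coverage over the analysis scope, and the number of
#' targeted positions in scope. These are the three symbols of the
#' mutation-frequency formula.
#'
#' @param calls Final variant calls for one or more libraries.
#' @param pileups Combined [dcs_pileup()] tibble with a `library_id`
#'   column covering the same libraries.
#' @param model A [ref_model].
#' @param scope `"exonic"` restricts coverage averaging and region size
#'   to exonic positions (consistent with exonic variant numerators);
#'   `"all"` uses every sequenced position.
#' @return Tibble with `library_id`, `variant_count`, `mean_coverage`,
#'   `region_size`.
#' @export
library_summaries <- function(calls, pileups, model,
                              scope = c("exonic", "all")) {
  scope <- match.arg(scope)
  pp <- pileups
  if (scope == "exonic") {
    pp <- pp[classify_site(model, pp$pos) == "exonic", , drop = FALSE]
  }
  cov <- dplyr::summarise(dplyr::group_by(pp, .data$library_id),
                          mean_coverage = mean(.data$coverage),
                          region_size = dplyr::n(), .groups = "drop")
  vc <- dplyr::summarise(
    dplyr::group_by(calls, .data$library_id),
    variant_count = dplyr::n_distinct(paste(.data$pos, .data$ref,
                                            .data$alt)),
    .groups = "drop")
  out <- dplyr::left_join(cov, vc, by = "library_id")
  out$variant_count[is.na(out$variant_count)] <- 0L
  out[, c("library_id", "variant_count", "mean_coverage", "region_size")]
}

#' Overall mutation frequency (substitutions per sequenced base pair)
#'
#' Computes `sum(variant_count_i) / sum(mean_coverage_i * region_size_i)`
#' over libraries: the number of distinct variants per library (the same
#' substitution in different libraries counts once per library; repeats
#' within a library count once) divided by the total number of duplex-
#' sequenced nucleotides. The confidence interval is an exact (Garwood)
#' Poisson interval on the count, divided by the denominator.
#'
#' @param summaries Tibble from [library_summaries()] (columns
#'   `variant_count`, `mean_coverage`, `region_size`).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `numerator`, `denominator`, `frequency`,
#'   `ci_lower`, `ci_upper`.
#' @export
mutation_frequency <- function(summaries, level = 0.95) {
  stopifnot(nrow(summaries) >= 1L)
  num <- sum(summaries$variant_count)
  den <- sum(summaries$mean_coverage * summaries$region_size)
  if (den <= 0) stop("zero denominator: no sequenced nucleotides")
  ci <- poisson_ci(num, den, level = level)
  tibble::tibble(numerator = num, denominator = den,
                 frequency = num / den,
                 ci_lower = ci$lower, ci_upper = ci$upper)
}

#' Stratified mutation frequencies
#'
#' Applies the mutation-frequency formula within strata. For strata that
#' partition libraries (e.g. `age_group`, present in `summaries`), each
#' stratum uses its own libraries' denominators. For strata that
#' partition positions (e.g. protein `domain` or consequence class), the
#' numerator is restricted to the stratum and the denominator uses the
#' stratum footprint supplied in `region_sizes` combined with every
#' library's mean coverage.
#'
#' @param calls Final variant calls carrying the stratum column.
#' @param summaries [library_summaries()] output; must carry the stratum
#'   column too when stratifying by a library property.
#' @param by Name of the stratum column.
#' @param region_sizes Optional tibble `stratum`, `region_size` giving
#'   the per-stratum position footprint (required when `by` is not a
#'   column of `summaries`). Strata listed here but absent from the
#'   calls are reported with frequency 0 and a one-sided interval.
#' @param level Confidence level.
#' @return Tibble with one row per stratum: counts, denominator,
#'   frequency and Poisson interval.
#' @export
stratified_frequency <- function(calls, summaries, by,
                                 region_sizes = NULL, level = 0.95) {
  if (!by %in% names(calls)) stop("unknown stratum column: ", by)
  collapse_count <- function(df) {
    dplyr::n_distinct(paste(df$library_id, df$pos, df$ref, df$alt))
  }
  if (by %in% names(summaries)) {
    strata <- unique(c(calls[[by]], summaries[[by]]))
    rows <- lapply(strata, function(s) {
      num <- collapse_count(calls[calls[[by]] %in% s, , drop = FALSE])
      sm <- summaries[summaries[[by]] %in% s, , drop = FALSE]
      den <- sum(sm$mean_coverage * sm$region_size)
      tibble::tibble(stratum = s, numerator = num, denominator = den)
    })
  } else {
    if (is.null(region_sizes)) {
      stop("region_sizes required when '", by,
           "' is not a library property in summaries")
    }
    total_cov <- sum(summaries$mean_coverage)
    strata <- unique(c(calls[[by]], region_sizes$stratum))
    strata <- strata[!is.na(strata)]
    rows <- lapply(strata, function(s) {
      num <- collapse_count(calls[!is.na(calls[[by]]) &
                                    calls[[by]] == s, , drop = FALSE])
      rs <- region_sizes$region_size[region_sizes$stratum == s]
      if (length(rs) != 1L) stop("no region_size for stratum: ", s)
      tibble::tibble(stratum = s, numerator = num,
                     denominator = total_cov * rs)
    })
  }
  out <- dplyr::bind_rows(rows)
  ci <- poisson_ci(out$numerator, out$denominator, level = level)
  out$frequency <- out$numerator / out$denominator
  out$ci_lower <- ci$lower
  out$ci_upper <- ci$upper
  out
}

#' Variant count summaries under the three deduplication semantics
#'
#' @param calls Final variant calls.
#' @return One-row tibble: `n_unique` distinct substitutions
#'   (position, ref, alt), `n_positions` distinct positions, and
#'   `n_collapsed` variants after within-library collapse (cross-library
#'   recurrences counted per library) — the numerator semantics of the
#'   mutation-frequency formula.
#' @export
unique_variant_counts <- function(calls) {
  tibble::tibble(
    n_unique = dplyr::n_distinct(paste(calls$pos, calls$ref, calls$alt)),
    n_positions = dplyr::n_distinct(calls$pos),
    n_collapsed = dplyr::n_distinct(paste(calls$library_id, calls$pos,
                                          calls$ref, calls$alt))
  )
}

#' Exact (Garwood) Poisson confidence interval on a rate
#'
#' Chi-square quantile interval for a Poisson count divided by its
#' exposure; `count = 0` gives a one-sided interval with lower bound 0,
#' `level = 0` degenerates to the point estimate.
#'
#' @param count Non-negative integer vector of event counts.
#' @param exposure Positive exposure (denominator) vector.
#' @param level Confidence level in `[0, 1)`.
#' @return Tibble with `rate`, `lower`, `upper`.
#' @export
poisson_ci <- function(count, exposure = 1, level = 0.95) {
  if (any(exposure <= 0)) stop("exposure must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  if (level < 0 || level >= 1) stop("level must lie in [0, 1)")
  alpha <- 1 - level
  lower <- ifelse(count == 0, 0,
                  stats::qchisq(alpha / 2, 2 * count) / 2)
  upper <- stats::qchisq(1 - alpha / 2, 2 * count + 2) / 2
  if (level == 0) {
    lower <- count
    upper <- count
  }
  tibble::tibble(rate = count / exposure, lower = lower / exposure,
                 upper = upper / exposure)
}

#' Pairwise chi-square rate tests with Bonferroni-Holm correction
#'
#' For every pair of strata, tests the 2x2 table of (variant count,
#' exposure - count) and applies the Holm step-down adjustment.
#'
#' @param strata Tibble with columns `stratum`, `count`, `exposure`
#'   (exposure = mean coverage x region size summed over the stratum's
#'   libraries).
#' @return Tibble with `stratum1`, `stratum2`, `p_value`, `p_adj`
#'   (Holm), sorted as supplied.
#' @export
pairwise_chisq_holm <- function(strata) {
  stopifnot(nrow(strata) >= 2L)
  if (any(strata$exposure <= 0)) stop("stratum with zero exposure")
  pairs <- utils::combn(nrow(strata), 2L)
  p <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    tab <- matrix(c(strata$count[i], strata$exposure[i] - strata$count[i],
                    strata$count[j], strata$exposure[j] - strata$count[j]),
                  nrow = 2L, byrow = TRUE)
    suppressWarnings(stats::chisq.test(tab)$p.value)
  })
  p[is.nan(p)] <- 1  # both strata empty
  tibble::tibble(stratum1 = strata$stratum[pairs[1L, ]],
                 stratum2 = strata$stratum[pairs[2L, ]],
                 p_value = p,
                 p_adj = stats::p.adjust(p, method = "holm"))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return The two-sided exact p-value.
#' @export
fisher_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  stats::fisher.test(table)$p.value
}
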