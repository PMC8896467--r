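#' Desk-scale validation experiments
#'
#' Two self-contained experiments that exercise the whole pipeline on the
#' synthetic reference under the study-like default conditions; both are
#' deterministic given `seed` and are the basis of the package's
#' acceptance checks.
#'
#' `study_spikein()` simulates spike-in dilution series (four libraries
#' per series with four spiked variants each at molecular fractions 0.1,
#' 0.01, 0.001 and 0.0001, one ~440 bp subregion per library at a duplex
#' consensus coverage of roughly 11,000), runs the full pipeline and
#' evaluates recovery: variants detected out of 16 and the squared
#' Pearson correlation between log10 expected and log10 measured VAF.
#'
#' `study_error_suppression()` simulates a null library (no true
#' variants) with strand-asymmetric damage, PCR and sequencing error
#' enabled, and contrasts the single-strand (SSCS) variant frequency
#' with the duplex (DCS) frequency, splitting counts into the
#' damage-associated folded classes (C>A and C>T) versus all others.
#'
#' @param seed Integer master seed.
#' @param n_series Number of independent spike-in series to average over
#'   (default 3).
#' @param n_molecules Source molecules per subregion.
#' @param dilutions Molecular fractions of the series.
#' @return `study_spikein()`: a list with `per_series` (one row per
#'   series: `detected`, `total`, `r2_loglog`, `median_coverage`),
#'   `mean_detected`, `mean_r2`, and the last series' `pipeline` result.
#'   `study_error_suppression()`: a one-row tibble with SSCS/DCS
#'   frequencies, their ratio and per-class confinement counts.
#' @export
study_spikein <- function(seed = 1L, n_series = 3L, n_molecules = 23000L,
                          dilutions = c(0.1, 0.01, 0.001, 0.0001)) {
  ref <- synthetic_reference()
  rows <- vector("list", n_series)
  pipe <- NULL
  for (s in seq_len(n_series)) {
    base <- sim_config(ref$model, ref$layout, subregions = "Up1",
                       n_molecules = n_molecules,
                       library_id = sprintf("spike_s%d", s))
    series <- simulate_spikein_series(base, dilutions,
                                      seed = as.integer(seed) + 100L * s)
    pipe <- run_pipeline(series$libraries, ref$model, ref$layout,
                         seed = as.integer(seed) + 100L * s,
                         spike_truth = series$truth, iterations = 200L)
    ev <- pipe$spikein
    rows[[s]] <- tibble::tibble(
      series = s, detected = ev$n_detected, total = ev$n_total,
      r2_loglog = ev$r2_loglog,
      median_coverage = stats::median(pipe$pileups$coverage))
    rm(series)
  }
  per_series <- dplyr::bind_rows(rows)
  list(per_series = per_series,
       mean_detected = mean(per_series$detected),
       mean_r2 = mean(per_series$r2_loglog),
       mean_coverage = mean(per_series$median_coverage),
       pipeline = pipe)
}

#' @rdname study_spikein
#' @export
study_error_suppression <- function(seed = 1L, n_molecules = 3000L) {
  ref <- synthetic_reference()
  cfg <- sim_config(ref$model, ref$layout, subregions = "Up1",
                    n_molecules = n_molecules, library_id = "null_lib")
  sim <- simulate_library(cfg, seed = as.integer(seed))
  fams <- group_families(sim$reads)
  cons <- call_consensus(fams, ref$model, ref$layout)
  su <- sscs_pileup(cons, ref$model)
  pu <- dcs_pileup(cons, ref$model)
  class_counts <- function(pileup) {
    counts <- c(damage = 0L, other = 0L)
    for (b in DNA_BASES) {
      col <- pileup[[paste0("alt_", b)]]
      sel <- pileup$ref != b & col > 0L
      if (!any(sel)) next
      fold <- fold_substitution(pileup$ref[sel], rep(b, sum(sel)))
      cls <- paste0(fold$class_ref, ">", fold$class_alt)
      dmg <- cls %in% c("C>A", "C>T")
      counts["damage"] <- counts["damage"] + sum(col[sel][dmg])
      counts["other"] <- counts["other"] + sum(col[sel][!dmg])
    }
    counts
  }
  sc <- class_counts(su)
  dc <- class_counts(pu)
  sscs_freq <- sum(sc) / sum(su$coverage)
  dcs_freq <- sum(dc) / sum(pu$coverage)
  tibble::tibble(
    sscs_alt = sum(sc), sscs_obs = sum(su$coverage),
    dcs_alt = sum(dc), dcs_obs = sum(pu$coverage),
    sscs_freq = sscs_freq, dcs_freq = dcs_freq,
    suppression_ratio = ifelse(dcs_freq > 0, sscs_freq / dcs_freq, Inf),
    sscs_damage = sc[["damage"]], sscs_other = sc[["other"]],
    dcs_damage = dc[["damage"]], dcs_other = dc[["other"]])
}
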