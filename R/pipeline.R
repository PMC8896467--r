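#' Run the full duplex analysis pipeline on one or more libraries
#'
#' Orchestrates simulate (optional) -> family grouping -> SSCS/DCS
#' consensus -> pileup -> variant calling -> tier assignment -> SNP
#' masking -> filtering -> mutation-frequency, spectrum and dN/dS
#' reports, deterministically under the supplied seed. Inputs may be
#' [sim_config] objects (simulated on the fly with per-library seeds
#' derived from `seed`) or pre-built `duplex_sim` objects.
#'
#' @param libraries List of [sim_config] or `duplex_sim` objects.
#' @param model A [ref_model].
#' @param layout A [target_layout].
#' @param meta Library metadata tibble (`library_id`, `donor_pool`,
#'   `age_group`, `target_set`); a single-pool default is derived when
#'   NULL.
#' @param seed Integer master seed.
#' @param min_family_size,majority Consensus parameters
#'   (see [call_consensus()]).
#' @param tier [tier_thresholds()].
#' @param snp_vaf_threshold SNP masking threshold (see [mask_snps()]).
#' @param min_coverage Final coverage filter (see [filter_variants()]).
#' @param scope Analysis scope for denominators: `"exonic"` or `"all"`.
#' @param spike_truth Optional spike-in truth table (from
#'   [simulate_spikein_series()]) to evaluate recovery.
#' @param dnds_by Stratifying columns for the dN/dS report (default
#'   domain and age group when available).
#' @param iterations Randomization/bootstrap iterations.
#' @param out_dir Optional directory: writes variant table (TSV + VCF),
#'   frequency, spectrum and dN/dS reports and a run log.
#' @param keep_sims Keep per-library SSCS pileups and simulation objects
#'   in the return value (memory-hungry at full scale; default FALSE).
#' @return Object of class `duplex_pipeline`: list with `calls` (final
#'   variant table), `all_calls` (pre-filter), `summaries`,
#'   `frequency`, `stratified`, `spectrum6`, `spectrum96`,
#'   `dnds`, `spikein` (or NULL), `sscs_dcs` per-library error summary,
#'   and the run `params`.
#' @export
run_pipeline <- function(libraries, model, layout, meta = NULL, seed = 1L,
                         min_family_size = 3L, majority = 0.7,
                         tier = tier_thresholds(),
                         snp_vaf_threshold = 0.05, min_coverage = 1000L,
                         scope = c("exonic", "all"), spike_truth = NULL,
                         dnds_by = NULL, iterations = 1000L,
                         out_dir = NULL, keep_sims = FALSE) {
  scope <- match.arg(scope)
  stopifnot(length(libraries) >= 1L)
  calls_l <- list(); ev_l <- list(); pu_l <- list(); err_l <- list()
  sims <- list()
  for (i in seq_along(libraries)) {
    lib <- libraries[[i]]
    if (inherits(lib, "sim_config")) {
      lib <- simulate_library(lib, seed = as.integer(seed) + 1000L * i)
    }
    stopifnot(inherits(lib, "duplex_sim"))
    lid <- lib$library_id
    tl <- lib$config$tag_length
    fams <- group_families(lib$reads, tag_length = tl)
    cons <- call_consensus(fams, model, layout, tag_length = tl,
                           min_family_size = min_family_size,
                           majority = majority)
    pu <- dcs_pileup(cons, model)
    pu$library_id <- lid
    su <- sscs_pileup(cons, model)
    se <- pileup_error_counts(su)
    de <- pileup_error_counts(pu)
    err_l[[lid]] <- tibble::tibble(
      library_id = lid,
      sscs_alt = se[["alt"]], sscs_cov = se[["cov"]],
      dcs_alt = de[["alt"]], dcs_cov = de[["cov"]]
    )
    cl <- call_variants(pu, model, layout, library_id = lid)
    ev <- consensus_evidence(cons)
    ev$library_id <- lid
    calls_l[[lid]] <- cl
    ev_l[[lid]] <- ev
    pu_l[[lid]] <- pu
    if (keep_sims) sims[[lid]] <- lib
  }
  all_calls <- dplyr::bind_rows(calls_l)
  evidence <- dplyr::bind_rows(ev_l)
  pileups <- dplyr::bind_rows(pu_l)
  sscs_dcs <- dplyr::bind_rows(err_l)
  sscs_dcs$sscs_freq <- sscs_dcs$sscs_alt / sscs_dcs$sscs_cov
  sscs_dcs$dcs_freq <- sscs_dcs$dcs_alt / sscs_dcs$dcs_cov

  if (is.null(meta)) {
    meta <- tibble::tibble(
      library_id = unique(all_calls$library_id %||% character()),
      donor_pool = "pool1", age_group = "younger", target_set = "all")
    if (nrow(meta) == 0L) {
      meta <- tibble::tibble(library_id = names(calls_l),
                             donor_pool = "pool1", age_group = "younger",
                             target_set = "all")
    }
  }
  if (nrow(all_calls)) {
    all_calls <- assign_tier(all_calls, evidence, thresholds = tier)
    all_calls <- mask_snps(all_calls, meta,
                           snp_vaf_threshold = snp_vaf_threshold)
    final <- filter_variants(all_calls, min_coverage = min_coverage)
  } else {
    final <- all_calls
  }
  final <- dplyr::left_join(final,
                            meta[, c("library_id", "donor_pool",
                                     "age_group")],
                            by = "library_id")

  summaries <- library_summaries(final, pileups, model, scope = scope)
  summaries <- dplyr::left_join(summaries,
                                meta[, c("library_id", "age_group")],
                                by = "library_id")
  freq <- mutation_frequency(summaries)
  strat <- list()
  if (nrow(final)) {
    strat$age_group <- stratified_frequency(final, summaries,
                                            by = "age_group")
    strat$category <- stratified_frequency(
      final, summaries, by = "category",
      region_sizes = tibble::tibble(
        stratum = unique(final$category),
        region_size = mean(summaries$region_size)))
  }

  scope_pos <- analysis_positions(model, layout, scope)
  spec6 <- mutation_spectrum(final, model, context = 6,
                             positions = scope_pos)
  spec96 <- mutation_spectrum(final, model, context = 96,
                              positions = scope_pos)
  if (is.null(dnds_by)) {
    dnds_by <- intersect(c("domain", "age_group"), names(final))
    if (nrow(layout$domains) == 0L) dnds_by <- setdiff(dnds_by, "domain")
    if (length(dnds_by) == 0L) dnds_by <- NULL
  }
  dnds_tbl <- dnds_report(final, model, layout, by = dnds_by,
                          iterations = iterations,
                          seed = as.integer(seed) + 77L)
  spike <- if (!is.null(spike_truth)) {
    spikein_evaluation(spike_truth, final)
  } else NULL

  out <- structure(
    list(calls = final, all_calls = all_calls, evidence = evidence,
         pileups = pileups, summaries = summaries, frequency = freq,
         stratified = strat, spectrum6 = spec6, spectrum96 = spec96,
         dnds = dnds_tbl, spikein = spike, sscs_dcs = sscs_dcs,
         sims = if (keep_sims) sims else NULL,
         params = list(seed = seed, min_family_size = min_family_size,
                       majority = majority, tier = tier,
                       snp_vaf_threshold = snp_vaf_threshold,
                       min_coverage = min_coverage, scope = scope,
                       iterations = iterations)),
    class = "duplex_pipeline")
  if (!is.null(out_dir)) write_pipeline_reports(out, model, out_dir)
  out
}

# total non-reference and total coverage of a pileup
pileup_error_counts <- function(pu) {
  m <- as.matrix(pu[, paste0("alt_", DNA_BASES)])
  refc <- m[cbind(seq_len(nrow(pu)), match(pu$ref, DNA_BASES))]
  c(alt = sum(pu$coverage - refc), cov = sum(pu$coverage))
}

# positions of the layout footprint, optionally exonic-only
analysis_positions <- function(model, layout, scope) {
  s <- layout$subregions
  pos <- unlist(lapply(seq_len(nrow(s)),
                       function(i) seq(s$start[i], s$end[i] - 1L)))
  if (scope == "exonic") pos <- pos[classify_site(model, pos) == "exonic"]
  pos
}

#' Serialise a pipeline result bundle to a report directory
#'
#' Writes the final variant table (TSV + VCF-style), library summaries,
#' mutation-frequency, spectrum and dN/dS reports, and a run log naming
#' the seed and every threshold.
#'
#' @param x A `duplex_pipeline` result.
#' @param model The [ref_model] used in the run.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_reports <- function(x, model, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(x$calls, model,
                      tsv_path = file.path(out_dir, "variants.tsv"),
                      vcf_path = file.path(out_dir, "variants.vcf"))
  readr::write_tsv(x$summaries, file.path(out_dir, "library_summaries.tsv"))
  readr::write_tsv(x$frequency, file.path(out_dir, "mutation_frequency.tsv"))
  readr::write_tsv(tibble::as_tibble(x$spectrum6),
                   file.path(out_dir, "spectrum6.tsv"))
  readr::write_tsv(tibble::as_tibble(x$spectrum96),
                   file.path(out_dir, "spectrum96.tsv"))
  readr::write_tsv(x$dnds, file.path(out_dir, "dnds.tsv"))
  p <- x$params
  writeLines(c(
    paste0("duplexr run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed=", p$seed),
    paste0("min_family_size=", p$min_family_size),
    paste0("majority=", p$majority),
    paste0("tier1_min_reads=", p$tier$tier1_min_reads),
    paste0("tier1_min_fraction=", p$tier$tier1_min_fraction),
    paste0("snp_vaf_threshold=", p$snp_vaf_threshold),
    paste0("min_coverage=", p$min_coverage),
    paste0("scope=", p$scope)
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.duplex_pipeline <- function(x, ...) {
  cat("<duplex_pipeline> ", nrow(x$summaries), " libraries, ",
      nrow(x$calls), " final variant calls, overall mutation frequency ",
      signif(x$frequency$frequency, 3), "\n", sep = "")
  invisible(x)
}

#' Evaluate spike-in recovery against the simulation truth
#'
#' A spiked variant counts as detected when the identical substitution
#' appears in the final variant table of its library. The squared
#' Pearson correlation between log10 expected molecular fraction and
#' log10 observed VAF is computed over the detected variants (undefined,
#' NA, with fewer than two detections); the linear-scale R^2 is also
#' reported.
#'
#' @param truth Spike-in truth table (`library_id`, `pos`, `ref`, `alt`,
#'   `fraction`).
#' @param calls Final variant table.
#' @return Object of class `spikein_eval`: list with the per-variant
#'   `table` (expected and observed VAF, detected flag), `n_detected`,
#'   `n_total`, `r2_loglog`, `r2_linear`.
#' @export
spikein_evaluation <- function(truth, calls) {
  truth <- tibble::as_tibble(truth)
  obs <- calls[, intersect(c("library_id", "pos", "ref", "alt", "vaf"),
                           names(calls))]
  tab <- dplyr::left_join(truth, obs,
                          by = c("library_id", "pos", "ref", "alt"))
  tab$detected <- !is.na(tab$vaf)
  det <- tab[tab$detected & tab$vaf > 0, , drop = FALSE]
  r2_log <- if (nrow(det) >= 2L) {
    stats::cor(log10(det$fraction), log10(det$vaf))^2
  } else NA_real_
  r2_lin <- if (nrow(det) >= 2L) {
    stats::cor(det$fraction, det$vaf)^2
  } else NA_real_
  structure(list(table = tab, n_detected = sum(tab$detected),
                 n_total = nrow(tab), r2_loglog = r2_log,
                 r2_linear = r2_lin),
            class = "spikein_eval")
}

#' @export
print.spikein_eval <- function(x, ...) {
  cat("<spikein_eval> ", x$n_detected, "/", x$n_total,
      " spiked variants detected; log-log R^2 = ",
      ifelse(is.na(x$r2_loglog), "NA", round(x$r2_loglog, 3)),
      "\n", sep = "")
  invisible(x)
}
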