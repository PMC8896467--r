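#' Tier thresholds for duplex variant confidence
#'
#' Tier 1 requires every supporting DCS family to reach
#' `tier1_min_reads` reads on both strands with an alternate-allele
#' consensus support fraction of at least `tier1_min_fraction` on both
#' strands. Tier 2 requires at least `tier2_min_reads` per strand with
#' support at `tier2_min_fraction` (default full agreement). Anything
#' weaker is "lower". The thresholds are configuration, not constants of
#' nature, and are logged with every run.
#'
#' @param tier1_min_reads,tier1_min_fraction Tier-1 thresholds.
#' @param tier2_min_reads,tier2_min_fraction Tier-2 thresholds.
#' @return A named list of thresholds.
#' @export
tier_thresholds <- function(tier1_min_reads = 3L, tier1_min_fraction = 0.75,
                            tier2_min_reads = 1L, tier2_min_fraction = 1.0) {
  list(tier1_min_reads = tier1_min_reads,
       tier1_min_fraction = tier1_min_fraction,
       tier2_min_reads = tier2_min_reads,
       tier2_min_fraction = tier2_min_fraction)
}

#' Call substitution variants from a DCS pileup
#'
#' Emits one call per (position, alternate base) with at least one
#' supporting duplex consensus; substitutions only. The variant allele
#' frequency is the alternate-supporting DCS count divided by the DCS
#' coverage at the position.
#'
#' @param pileup Output of [dcs_pileup()].
#' @param model A [ref_model].
#' @param layout Optional [target_layout] for domain annotation.
#' @param library_id Library label attached to each call.
#' @return Tibble with `library_id`, `subregion`, `pos`, `ref`, `alt`,
#'   `alt_count`, `dcs_coverage`, `vaf` plus consequence annotation
#'   columns from [annotate_variants()].
#' @export
call_variants <- function(pileup, model, layout = NULL,
                          library_id = "lib1") {
  long <- tidyr::pivot_longer(pileup,
                              cols = dplyr::all_of(paste0("alt_", DNA_BASES)),
                              names_to = "alt", names_prefix = "alt_",
                              values_to = "alt_count")
  long <- long[long$alt != long$ref & long$alt_count > 0L, , drop = FALSE]
  calls <- tibble::tibble(
    library_id = library_id,
    subregion = long$subregion,
    pos = long$pos, ref = long$ref, alt = long$alt,
    alt_count = long$alt_count,
    dcs_coverage = long$coverage,
    vaf = long$alt_count / long$coverage
  )
  annotate_variants(calls, model, layout)
}

#' Assign confidence tiers from per-family consensus evidence
#'
#' A variant call is tier 1 only if every supporting DCS family meets the
#' tier-1 read-count and support thresholds on both strands; tier 2 if
#' every supporting family meets the weaker tier-2 thresholds; otherwise
#' "lower".
#'
#' @param calls Variant calls from [call_variants()] (any tibble with
#'   `pos`, `alt` and, if multi-library, `library_id`).
#' @param evidence Family evidence from [consensus_evidence()], with a
#'   matching `library_id` column when calls span libraries.
#' @param thresholds See [tier_thresholds()].
#' @return `calls` with a `tier` column (`"1"`, `"2"` or `"lower"`).
#' @export
assign_tier <- function(calls, evidence, thresholds = tier_thresholds()) {
  keys <- intersect(c("library_id", "pos", "alt"), names(calls))
  keys <- intersect(keys, names(evidence))
  eps <- 1e-9
  ev <- dplyr::summarise(
    dplyr::group_by(evidence, dplyr::across(dplyr::all_of(keys))),
    t1 = all(.data$f_ab >= thresholds$tier1_min_reads &
               .data$f_ba >= thresholds$tier1_min_reads &
               .data$supp_ab >= thresholds$tier1_min_fraction - eps &
               .data$supp_ba >= thresholds$tier1_min_fraction - eps),
    t2 = all(.data$f_ab >= thresholds$tier2_min_reads &
               .data$f_ba >= thresholds$tier2_min_reads &
               .data$supp_ab >= thresholds$tier2_min_fraction - eps &
               .data$supp_ba >= thresholds$tier2_min_fraction - eps),
    .groups = "drop")
  out <- dplyr::left_join(calls, ev, by = keys)
  if (anyNA(out$t1)) {
    stop("missing family evidence for ", sum(is.na(out$t1)), " call(s)")
  }
  out$tier <- dplyr::case_when(out$t1 ~ "1", out$t2 ~ "2",
                               TRUE ~ "lower")
  out$t1 <- NULL
  out$t2 <- NULL
  out
}

#' Flag shared high-frequency variants as SNPs
#'
#' A variant is categorised as a SNP when it is detected in all libraries
#' that share the same donor pool / target region combination at a
#' frequency of at least `snp_vaf_threshold` in each (the study's "~10%"
#' rule, implemented as a configurable threshold, default 0.05).
#'
#' @param calls Multi-library variant calls (columns `library_id`, `pos`,
#'   `ref`, `alt`, `vaf`).
#' @param meta Library metadata: columns `library_id`, `donor_pool`,
#'   `age_group`, `target_set`.
#' @param snp_vaf_threshold Per-library VAF floor for the SNP rule.
#' @return `calls` with a logical `snp` column.
#' @export
mask_snps <- function(calls, meta, snp_vaf_threshold = 0.05) {
  meta <- tibble::as_tibble(meta)
  unknown <- setdiff(unique(calls$library_id), meta$library_id)
  if (length(unknown)) {
    stop("unknown library_id in calls: ", paste(unknown, collapse = ", "))
  }
  group_size <- dplyr::count(meta, .data$donor_pool, .data$target_set,
                             name = "n_lib")
  hits <- dplyr::filter(calls, .data$vaf >= snp_vaf_threshold)
  hits <- dplyr::left_join(hits,
                           meta[, c("library_id", "donor_pool", "target_set")],
                           by = "library_id")
  hits <- dplyr::distinct(hits, .data$pos, .data$ref, .data$alt,
                          .data$donor_pool, .data$target_set,
                          .data$library_id)
  hits <- dplyr::count(hits, .data$pos, .data$ref, .data$alt,
                       .data$donor_pool, .data$target_set, name = "n_hit")
  hits <- dplyr::left_join(hits, group_size,
                           by = c("donor_pool", "target_set"))
  snp_vars <- dplyr::distinct(
    dplyr::filter(hits, .data$n_hit == .data$n_lib),
    .data$pos, .data$ref, .data$alt)
  key <- paste(calls$pos, calls$ref, calls$alt)
  calls$snp <- key %in% paste(snp_vars$pos, snp_vars$ref, snp_vars$alt)
  calls
}

#' Apply the final variant filters
#'
#' Discards SNP-flagged and intronic calls and calls with DCS coverage
#' below `min_coverage`; of the rest, keeps tier-1 calls and tier-2 calls
#' whose identical substitution (position, ref, alt) is detected more
#' than once across the analysis set. Detection counting is invariant to
#' library order.
#'
#' @param calls Tiered, SNP-flagged, annotated calls.
#' @param min_coverage Minimum DCS coverage at the variant position.
#' @return The filtered variant table, with an `n_detections` column.
#' @export
filter_variants <- function(calls, min_coverage = 1000L) {
  keep <- !calls$snp & calls$category != "intronic" &
    calls$dcs_coverage >= min_coverage
  out <- calls[keep, , drop = FALSE]
  key <- paste(out$pos, out$ref, out$alt)
  out$n_detections <- as.integer(table(key)[key])
  out[out$tier == "1" | (out$tier == "2" & out$n_detections >= 2L), ,
      drop = FALSE]
}

#' Write / read the final variant table
#'
#' `write_variant_table()` writes a plain TSV and a VCF-like text file
#' (CHROM = transcript name, 1-based POS, REF/ALT, INFO carrying library,
#' tier, VAF and consequence); `read_variant_table()` reads the TSV back
#' and reproduces the original tibble.
#'
#' @param calls Final variant table.
#' @param model A [ref_model] (for the CHROM name).
#' @param tsv_path,vcf_path Output paths (either may be NULL to skip).
#' @return Invisibly, the written paths.
#' @export
write_variant_table <- function(calls, model, tsv_path = NULL,
                                vcf_path = NULL) {
  if (!is.null(tsv_path)) {
    readr::write_tsv(calls, tsv_path)
  }
  if (!is.null(vcf_path)) {
    header <- c("##fileformat=VCFv4.3",
                paste0("##contig=<ID=", model$name, ",length=",
                       model$length, ">"),
                "##INFO=<ID=LIB,Number=1,Type=String,Description=\"Library\">",
                "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Confidence tier\">",
                "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
                "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
                paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
    body <- if (nrow(calls)) {
      paste(model$name, calls$pos + 1L, ".", calls$ref, calls$alt, ".",
            "PASS",
            paste0("LIB=", calls$library_id, ";TIER=", calls$tier,
                   ";VAF=", signif(calls$vaf, 6), ";CSQ=", calls$category,
                   "|", calls$hgvs_c, "|", calls$hgvs_p),
            sep = "\t")
    } else character()
    writeLines(c(header, body), vcf_path)
  }
  invisible(list(tsv = tsv_path, vcf = vcf_path))
}

#' @rdname write_variant_table
#' @param path Path to a TSV written by `write_variant_table()`.
#' @export
read_variant_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(tier = readr::col_character(),
                                          .default = readr::col_guess()))
}
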