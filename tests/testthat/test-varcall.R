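make_pileup <- function(model, rows) {
  # rows: tibble(pos, alt, alt_count, coverage)
  base <- tibble::tibble(
    subregion = "Up1", pos = rows$pos, ref = model$bases[rows$pos + 1L],
    coverage = rows$coverage, alt_A = 0L, alt_C = 0L, alt_G = 0L,
    alt_T = 0L)
  for (i in seq_len(nrow(rows))) {
    col <- paste0("alt_", rows$alt[i])
    base[[col]][i] <- rows$alt_count[i]
  }
  for (i in seq_len(nrow(base))) {
    rc <- paste0("alt_", base$ref[i])
    base[[rc]][i] <- base$coverage[i] -
      sum(unlist(base[i, paste0("alt_", c("A", "C", "G", "T"))]))
  }
  base
}

test_that("variant calls carry exact VAFs and split multi-allelic sites", {
  ref <- ref_fixture()
  m <- ref$model
  p <- ref$layout$subregions$start[1] + 30L
  alts <- setdiff(c("A", "C", "G", "T"), m$bases[p + 1L])
  pu <- make_pileup(m, tibble::tibble(pos = c(p, p + 1L),
                                      alt = c(alts[1], "A"),
                                      alt_count = c(3L, 0L),
                                      coverage = c(30000L, 10000L)))
  # two distinct alternates at one position become two calls
  pu[[paste0("alt_", alts[2])]][1] <- 2L
  pu[[paste0("alt_", m$bases[p + 1L])]][1] <- 30000L - 5L
  calls <- call_variants(pu, m, ref$layout, library_id = "L1")
  expect_equal(nrow(calls), 2)  # zero-count position yields no call
  expect_setequal(calls$alt, alts[1:2])
  expect_equal(calls$vaf[calls$alt == alts[1]], 1e-4)
  expect_true(all(c("category", "hgvs_c", "domain") %in% names(calls)))
})

test_that("tier assignment follows the all-supporting-families rule", {
  calls <- tibble::tibble(library_id = "L1", pos = c(10L, 20L, 30L),
                          alt = "A")
  evidence <- tibble::tibble(
    library_id = "L1",
    pos = c(10L, 10L, 20L, 30L),
    alt = "A",
    f_ab = c(5L, 4L, 1L, 3L),
    f_ba = c(5L, 6L, 4L, 3L),
    supp_ab = c(1, 1, 1, 0.6),
    supp_ba = c(1, 0.8, 1, 0.6))
  out <- assign_tier(calls, evidence)
  # pos 10: two families, one with support 0.8 < 0.75? (0.8 >= 0.75) tier 1
  expect_equal(out$tier[out$pos == 10], "1")
  # pos 20: a single-read strand family fails tier 1, full agreement -> 2
  expect_equal(out$tier[out$pos == 20], "2")
  # pos 30: support below the tier-2 floor on both strands -> lower
  expect_equal(out$tier[out$pos == 30], "lower")

  expect_error(assign_tier(tibble::tibble(library_id = "L1", pos = 99L,
                                          alt = "A"), evidence),
               "missing family evidence")
})

test_that("SNP masking needs every sharing library above threshold", {
  meta <- tibble::tibble(library_id = c("L1", "L2", "L3", "L4"),
                         donor_pool = c("p1", "p1", "p1", "p2"),
                         age_group = "younger",
                         target_set = c("Up", "Up", "Up", "Up"))
  base_call <- function(lib, vaf) {
    tibble::tibble(library_id = lib, pos = 100L, ref = "C", alt = "T",
                   vaf = vaf)
  }
  # present at >= threshold in all three sharing libraries -> SNP
  calls <- dplyr::bind_rows(base_call("L1", 0.10), base_call("L2", 0.12),
                            base_call("L3", 0.09))
  expect_true(all(mask_snps(calls, meta)$snp))
  # in only 2 of 3 sharing libraries -> not a SNP
  calls2 <- dplyr::bind_rows(base_call("L1", 0.10), base_call("L2", 0.12),
                             base_call("L3", 1e-4))
  expect_false(any(mask_snps(calls2, meta)$snp))
  # an ultra-rare call is never a SNP
  expect_false(any(mask_snps(base_call("L4", 1e-4), meta)$snp))
  # a single-library pool/target combination can satisfy the rule alone
  expect_true(all(mask_snps(base_call("L4", 0.2), meta)$snp))
  expect_error(mask_snps(base_call("LX", 0.2), meta), "unknown library_id")
})

test_that("final filters drop low coverage, intronic and lone tier-2 calls", {
  tpl <- tibble::tibble(
    library_id = c("L1", "L1", "L2", "L1", "L1"),
    pos = c(1L, 2L, 2L, 3L, 4L),
    ref = "C", alt = "T",
    dcs_coverage = c(999L, 5000L, 6000L, 5000L, 5000L),
    category = c("missense", "synonymous", "synonymous", "missense",
                 "intronic"),
    tier = c("1", "2", "2", "2", "1"),
    snp = FALSE)
  out <- filter_variants(tpl, min_coverage = 1000L)
  # tier-1 at coverage 999 removed; intronic tier-1 removed; the tier-2
  # variant seen twice (pos 2 in two libraries) kept, the lone one removed
  expect_equal(sort(out$pos), c(2L, 2L))
  expect_equal(unique(out$n_detections), 2L)
  # detection counting is invariant to row order
  out2 <- filter_variants(tpl[rev(seq_len(nrow(tpl))), ])
  expect_equal(dplyr::arrange(out2, .data$library_id, .data$pos),
               dplyr::arrange(out, .data$library_id, .data$pos))
  # SNP-flagged calls are dropped even at high tier
  tpl$snp[2:3] <- TRUE
  expect_equal(nrow(filter_variants(tpl)), 0)
})

test_that("variant tables round-trip through TSV and VCF text", {
  ref <- ref_fixture()
  m <- ref$model
  p <- ref$layout$subregions$start[1] + c(30L, 30L, 45L)
  calls <- tibble::tibble(
    library_id = c("L1", "L1", "L2"), subregion = "Up1", pos = p,
    ref = m$bases[p + 1L],
    alt = c(setdiff(c("A", "C", "G", "T"), m$bases[p[1] + 1L])[1:2],
            setdiff(c("A", "C", "G", "T"), m$bases[p[3] + 1L])[1]),
    alt_count = c(3L, 2L, 5L), dcs_coverage = 10000L,
    vaf = c(3e-4, 2e-4, 5e-4), tier = c("1", "2", "1"),
    category = "missense", hgvs_c = "c.x", hgvs_p = "p.x")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(calls, m, tsv_path = tsv, vcf_path = vcf)
  back <- read_variant_table(tsv)
  expect_equal(as.data.frame(back), as.data.frame(calls))
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 3)  # multi-allelic site -> two records
  expect_true(all(grepl(paste0("^", m$name, "\t"), body)))
  pos_vcf <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  expect_equal(pos_vcf, p + 1L)  # 1-based output

  # empty call set still writes a valid header-only file
  write_variant_table(calls[0, ], m, vcf_path = vcf)
  lines0 <- readLines(vcf)
  expect_true(all(startsWith(lines0, "#")))
  expect_gt(length(lines0), 1)
})
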