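test_that("tag orientation groups complementary pairs into one family", {
  a <- strrep("A", 12); b <- strrep("C", 12)
  ins <- "ACGTACGT"
  reads <- tibble::tibble(
    read_id = c("l:Up1:1", "l:Up1:2"),
    mate1 = c(paste0(a, ins), paste0(b, ins)),
    mate2 = c(paste0(b, ins), paste0(a, ins)))
  fams <- group_families(reads)
  expect_equal(dplyr::n_distinct(fams$family_key), 1)
  expect_setequal(fams$strand, c("ab", "ba"))

  # unique tags give singleton families
  reads2 <- tibble::tibble(
    read_id = c("l:Up1:1", "l:Up1:2"),
    mate1 = c(paste0(strrep("G", 12), ins), paste0(strrep("T", 12), ins)),
    mate2 = c(paste0(strrep("A", 12), ins), paste0(strrep("C", 12), ins)))
  fams2 <- group_families(reads2)
  expect_equal(dplyr::n_distinct(fams2$family_key), 2)

  # tags containing N are discarded and counted
  reads$mate1[1] <- paste0("N", substr(reads$mate1[1], 2, 500))
  fams3 <- group_families(reads)
  expect_equal(nrow(fams3), 1)
  expect_equal(attr(fams3, "n_discarded"), 1L)

  empty <- group_families(reads[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("build_sscs applies the majority rule and size threshold", {
  # 5 reads, 4 with the alternate at one position: support 0.8 >= 0.7
  reads <- c("AAAA", "AAAA", "AAAA", "AAAA", "ACAA")
  reads_alt <- c(rep("ACAA", 4), "AAAA")
  s <- build_sscs(reads_alt, min_family_size = 3, majority = 0.7)
  expect_equal(substr(s$sequence, 2, 2), "C")
  expect_equal(s$support[2], 0.8)
  expect_equal(s$family_size, 5)

  # below the family-size threshold: rejection
  expect_null(build_sscs(reads[1:2], min_family_size = 3))

  # 2/1 split at majority 0.7: no base reaches the threshold -> N
  s2 <- build_sscs(c("AAAA", "ACAA", "ACAA"), min_family_size = 3,
                   majority = 0.7)
  expect_equal(substr(s2$sequence, 2, 2), "N")

  # enumerated support fractions: k of n reads support the alternate
  for (n in 3:6) {
    for (k in 0:n) {
      fam <- c(rep("AC", k), rep("AA", n - k))
      s3 <- build_sscs(fam, min_family_size = 3, majority = 0.7)
      expected <- if (k / n >= 0.7 - 1e-9) "C"
        else if ((n - k) / n >= 0.7 - 1e-9) "A" else "N"
      expect_equal(substr(s3$sequence, 2, 2), expected,
                   label = sprintf("k=%d n=%d", k, n))
    }
  }

  expect_error(build_sscs(c("AAA", "AAAA", "AAA")), "length")
})

test_that("build_dcs keeps agreement and masks single-strand evidence", {
  fwd <- build_sscs(rep("ACGT", 3))
  rev <- build_sscs(rep("ACGT", 3))
  expect_equal(build_dcs(fwd, rev)$sequence, "ACGT")

  alt_both_f <- build_sscs(rep("ATGT", 3))
  alt_both_r <- build_sscs(rep("ATGT", 4))
  expect_equal(build_dcs(alt_both_f, alt_both_r)$sequence, "ATGT")

  # lesion on one strand only: disagreement becomes N, no variant survives
  d <- build_dcs(alt_both_f, rev)
  expect_equal(d$sequence, "ANGT")

  # N on either strand propagates
  n_str <- build_sscs(c("ANGT", "ANGT", "ANGT"))
  expect_equal(build_dcs(n_str, rev)$sequence, "ANGT")

  expect_error(build_dcs(fwd, rev, family_key = c("k1", "k2")),
               "family keys")
})

test_that("batch consensus equals per-family brute force on a small library", {
  ref <- ref_fixture()
  vpos <- ref$layout$subregions$start[1] + c(50L, 200L)
  cfg <- small_cfg(ref$model, ref$layout, n_molecules = 40,
                   seq_error_rate = 0.01, damage_rate_deam = 1e-3,
                   pcr_error_rate = 1e-4,
                   true_variants = data.frame(
                     pos = vpos, ref = ref$model$bases[vpos + 1L],
                     alt = ifelse(ref$model$bases[vpos + 1L] == "A",
                                  "C", "A"),
                     fraction = c(0.3, 0.15)))
  sim <- simulate_library(cfg, seed = 21)
  fams <- group_families(sim$reads)
  cons <- call_consensus(fams, ref$model, ref$layout,
                         min_family_size = 3, majority = 0.7)
  sub <- cons$subregions[["Up1"]]
  lay <- ref$layout$subregions
  gstart <- lay$start[lay$name == "Up1"]
  L <- lay$end[lay$name == "Up1"] - gstart
  frag <- substr(ref$model$sequence, gstart + 1, lay$end[lay$name == "Up1"])
  ins <- cfg$read_length - cfg$tag_length

  # independent per-family reconstruction via the string contract ops
  fams$i1 <- substring(fams$mate1, 13)
  fams$i2 <- substring(fams$mate2, 13)
  keys <- unique(fams$family_key)
  got_alt <- sub$dcs_alt[order(sub$dcs_alt$family_key, sub$dcs_alt$pos), ]
  n_checked <- 0
  exp_alt <- list()
  n_dcs_oracle <- 0
  for (key in keys) {
    fk <- fams[fams$family_key == key, ]
    sscs_of <- function(strand) {
      fr <- fk[fk$strand == strand, ]
      if (nrow(fr) < 3) return(NULL)
      # every mate is one observation over its covered interval; emulate
      # the per-position tally by padding each segment with N to full
      # fragment width (the overlap is then observed twice per pair)
      fr_obs <- unlist(lapply(seq_len(nrow(fr)), function(j) {
        o <- oracle_orient(fr$i1[j], fr$i2[j], frag, ins)
        c(paste0(o$left, strrep("N", L - ins)),
          paste0(strrep("N", L - ins), o$right))
      }))
      oracle <- oracle_sscs(fr_obs, majority = 0.7)
      list(seq = oracle, f = nrow(fr))
    }
    sa <- sscs_of("ab"); sb <- sscs_of("ba")
    if (is.null(sa) || is.null(sb)) next
    n_dcs_oracle <- n_dcs_oracle + 1
    a <- strsplit(sa$seq, "")[[1]]; b <- strsplit(sb$seq, "")[[1]]
    dcs <- ifelse(a == b & a != "N", a, "N")
    fb <- strsplit(frag, "")[[1]]
    alt_pos <- which(dcs != fb & dcs != "N")
    if (length(alt_pos)) {
      exp_alt[[key]] <- tibble::tibble(family_key = key, pos = alt_pos - 1L,
                                       alt = dcs[alt_pos])
    }
    n_checked <- n_checked + 1
  }
  expect_equal(sub$n_dcs, n_dcs_oracle)
  exp_alt <- dplyr::bind_rows(exp_alt)
  expect_gt(nrow(exp_alt), 0)  # the fixture must exercise alternate calls
  exp_alt <- exp_alt[order(exp_alt$family_key, exp_alt$pos), ]
  expect_equal(got_alt[, c("family_key", "pos", "alt")], exp_alt,
               ignore_attr = TRUE)
  expect_gt(n_checked, 5)
})

test_that("pileup coverage excludes N and allele counts sum to coverage", {
  ref <- ref_fixture()
  cfg <- small_cfg(ref$model, ref$layout, n_molecules = 150,
                   seq_error_rate = 5e-3)
  sim <- simulate_library(cfg, seed = 31)
  cons <- call_consensus(group_families(sim$reads), ref$model, ref$layout)
  pu <- dcs_pileup(cons, ref$model)
  sums <- pu$alt_A + pu$alt_C + pu$alt_G + pu$alt_T
  expect_equal(sums, pu$coverage)
  sub <- cons$subregions[["Up1"]]
  expect_true(all(pu$coverage <= sub$n_dcs))
  expect_equal(sum(sub$n_dcs - pu$coverage), sum(sub$dcs_n$n_N))
  # DCS cannot outnumber the weaker strand family count
  ev <- consensus_evidence(cons)
  if (nrow(ev)) expect_true(all(ev$f_ab >= 3 & ev$f_ba >= 3))
})
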