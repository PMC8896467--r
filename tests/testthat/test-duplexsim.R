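test_that("simulation is deterministic and conserves read counts", {
  ref <- ref_fixture()
  cfg <- small_cfg(ref$model, ref$layout, n_molecules = 120)
  s1 <- simulate_library(cfg, seed = 5)
  s2 <- simulate_library(cfg, seed = 5)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_library(cfg, seed = 6)
  expect_false(identical(s1$reads, s3$reads))
  # conservation: read pairs = sum of both strands' family sizes
  expect_equal(nrow(s1$reads),
               sum(s1$truth$molecules$f_top + s1$truth$molecules$f_bottom))

  # FASTQ round trip preserves ids and sequences
  dir <- withr::local_tempdir()
  paths <- write_fastq(s1, dir)
  back <- read_fastq(paths[1], paths[2])
  expect_equal(back, s1$reads)
})

test_that("with zero error rates a full-fraction variant dominates every read", {
  ref <- ref_fixture()
  pos <- ref$layout$subregions$start[1] + 25L
  cfg <- small_cfg(ref$model, ref$layout, n_molecules = 60,
                   true_variants = data.frame(
                     pos = pos, ref = ref$model$bases[pos + 1L],
                     alt = setdiff(c("A", "C", "G", "T"),
                                   ref$model$bases[pos + 1L])[1],
                     fraction = 1.0),
                   damage_rate_oxoG = 0, damage_rate_deam = 0,
                   pcr_error_rate = 0, seq_error_rate = 0)
  sim <- simulate_library(cfg, seed = 3)
  expect_equal(sim$truth$variants$n_carriers, 60L)
  fams <- group_families(sim$reads)
  cons <- call_consensus(fams, ref$model, ref$layout, min_family_size = 1L)
  pu <- dcs_pileup(cons, ref$model)
  row <- pu[pu$pos == pos, ]
  alt_col <- paste0("alt_", cfg$true_variants$alt)
  expect_equal(row[[alt_col]], row$coverage)  # VAF 1.0
  # and with rates zero, nothing else deviates from the reference
  expect_equal(sum(pileup_alt_total(pu)), row[[alt_col]])
})

test_that("zero or invalid configurations are rejected", {
  ref <- ref_fixture()
  expect_error(small_cfg(ref$model, ref$layout, n_molecules = 0),
               "n_molecules")
  expect_error(small_cfg(ref$model, ref$layout, seq_error_rate = 1.2),
               "rates")
  expect_error(small_cfg(ref$model, ref$layout,
                         true_variants = data.frame(pos = 10, ref = "A",
                                                    alt = "C",
                                                    fraction = 2)),
               "fraction")
  # ref mismatch against the model sequence
  pos <- ref$layout$subregions$start[1] + 3L
  wrong <- setdiff(c("A", "C", "G", "T"), ref$model$bases[pos + 1L])[1]
  expect_error(small_cfg(ref$model, ref$layout,
                         true_variants = data.frame(pos = pos, ref = wrong,
                                                    alt = "T",
                                                    fraction = 0.1)),
               "does not match")
})

test_that("strand-specific lesions appear in SSCS but never in DCS", {
  ref <- ref_fixture()
  cfg <- small_cfg(ref$model, ref$layout, n_molecules = 250,
                   damage_rate_oxoG = 2e-4, damage_rate_deam = 1e-3,
                   pcr_error_rate = 0, seq_error_rate = 0)
  sim <- simulate_library(cfg, seed = 9)
  art <- sim$truth$artifacts
  expect_gt(nrow(art), 0)
  expect_true(all(art$strand %in% 1:2))
  # deamination dominates and is C>T on one strand / G>A on the other
  expect_true(all(art$type %in% c("oxoG", "deam")))

  fams <- group_families(sim$reads)
  cons <- call_consensus(fams, ref$model, ref$layout)
  su <- sscs_pileup(cons, ref$model)
  pu <- dcs_pileup(cons, ref$model)
  sscs_alt <- pileup_alt_total(su)
  dcs_alt <- pileup_alt_total(pu)
  expect_gt(sum(sscs_alt), 0)        # artifact excess visible in SSCS
  expect_equal(sum(dcs_alt), 0)      # removed by duplex agreement
})

test_that("spike-in series produces one library per dilution with truth", {
  ref <- ref_fixture()
  base <- small_cfg(ref$model, ref$layout, n_molecules = 150,
                    library_id = "spk")
  series <- simulate_spikein_series(base, c(0.1, 0.01), seed = 2)
  expect_length(series$libraries, 2)
  expect_equal(nrow(series$truth), 8)  # four variants per library
  expect_equal(unique(series$truth$fraction), c(0.1, 0.01))
  expect_false(anyDuplicated(series$truth$pos) > 0)
  expect_equal(series$truth$expected_vaf,
               series$truth$n_carriers / series$truth$n_molecules)

  expect_error(
    simulate_spikein_series(base, c(0.1, 0.01), seed = 2,
                            positions = rep(ref$layout$subregions$start[1] +
                                              5L, 8)),
    "duplicate")
  empty <- simulate_spikein_series(base, numeric(0))
  expect_length(empty$libraries, 0)

  # Poisson-thinning scale: carriers are Binomial(n, fraction)
  expect_true(all(series$truth$n_carriers <= 150))
})
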