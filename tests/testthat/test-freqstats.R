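test_that("vaf is an exact ratio with guarded inputs", {
  expect_equal(vaf(3, 30000), 1e-4)
  expect_equal(vaf(0, 10000), 0)
  expect_error(vaf(1, 0), "coverage")
  expect_error(vaf(5, 3), "alt_count")
})

test_that("mutation frequency follows the summed formula", {
  s1 <- tibble::tibble(library_id = "L1", variant_count = 2L,
                       mean_coverage = 10000, region_size = 4405L)
  r <- mutation_frequency(s1)
  expect_equal(r$frequency, 2 / (10000 * 4405))
  expect_true(r$ci_lower <= r$frequency & r$frequency <= r$ci_upper)

  # the same variant in two libraries: numerator 2 over both exposures
  s2 <- tibble::tibble(library_id = c("A", "B"), variant_count = 1L,
                       mean_coverage = 8000, region_size = 441L)
  r2 <- mutation_frequency(s2)
  expect_equal(r2$numerator, 2)
  expect_equal(r2$denominator, 2 * 8000 * 441)

  # invariant to library order and to splitting a library with the same
  # coverage x size total
  expect_equal(mutation_frequency(s2[2:1, ]), r2)
  s3 <- tibble::tibble(library_id = c("A", "A2", "B"),
                       variant_count = c(1L, 0L, 1L),
                       mean_coverage = c(8000, 8000, 8000),
                       region_size = c(200L, 241L, 441L))
  expect_equal(mutation_frequency(s3)$frequency, r2$frequency)

  expect_error(mutation_frequency(
    tibble::tibble(variant_count = 1L, mean_coverage = 0,
                   region_size = 0L)), "denominator")
})

test_that("stratified frequencies restrict numerators and denominators", {
  calls <- tibble::tibble(
    library_id = c("L1", "L1", "L2"), pos = c(1L, 2L, 2L), ref = "C",
    alt = "T", age_group = c("younger", "younger", "older"),
    domain = c("TK", "TK", "IgI-III"))
  summaries <- tibble::tibble(
    library_id = c("L1", "L2"), variant_count = c(2L, 1L),
    mean_coverage = c(10000, 12000), region_size = 2418L,
    age_group = c("younger", "older"))
  by_age <- stratified_frequency(calls, summaries, by = "age_group")
  expect_equal(sort(by_age$numerator), c(1, 2))
  y <- by_age[by_age$stratum == "younger", ]
  expect_equal(y$frequency, 2 / (10000 * 2418))

  # a single stratum holding everything reproduces the overall figure
  calls1 <- dplyr::mutate(calls, grp = "all")
  summaries1 <- dplyr::mutate(summaries, grp = "all")
  one <- stratified_frequency(calls1, summaries1, by = "grp")
  expect_equal(one$frequency, mutation_frequency(summaries)$frequency)

  # position-partition strata need footprints; empty strata report zero
  by_dom <- stratified_frequency(
    calls, summaries, by = "domain",
    region_sizes = tibble::tibble(stratum = c("TK", "IgI-III", "TM"),
                                  region_size = c(840L, 1041L, 300L)))
  expect_equal(by_dom$numerator[by_dom$stratum == "TM"], 0)
  expect_equal(by_dom$ci_lower[by_dom$stratum == "TM"], 0)
  tk <- by_dom[by_dom$stratum == "TK", ]
  expect_equal(tk$denominator, (10000 + 12000) * 840)

  # weighted class frequencies recover the pooled numerator exactly
  expect_equal(sum(by_age$frequency * by_age$denominator),
               mutation_frequency(summaries)$numerator)
  expect_error(stratified_frequency(calls, summaries, by = "nope"),
               "unknown stratum")
})

test_that("variant count semantics distinguish the three dedup rules", {
  calls <- tibble::tibble(
    library_id = c("L1", "L2", "L1", "L1"),
    pos = c(5L, 5L, 9L, 9L), ref = c("C", "C", "G", "G"),
    alt = c("T", "T", "A", "T"))
  out <- unique_variant_counts(calls)
  expect_equal(out$n_unique, 3)      # (5,C,T), (9,G,A), (9,G,T)
  expect_equal(out$n_positions, 2)
  expect_equal(out$n_collapsed, 4)   # per-library occurrences
  empty <- unique_variant_counts(calls[0, ])
  expect_equal(unlist(empty), c(n_unique = 0L, n_positions = 0L,
                                n_collapsed = 0L))
})

test_that("Garwood intervals match chi-square quantiles and nominal level", {
  ci3 <- poisson_ci(3)
  expect_equal(ci3$lower, qchisq(0.025, 6) / 2, tolerance = 1e-6)
  expect_equal(ci3$upper, qchisq(0.975, 8) / 2, tolerance = 1e-6)
  expect_equal(round(ci3$lower, 3), 0.619)
  expect_equal(round(ci3$upper, 3), 8.767)
  expect_equal(poisson_ci(0)$lower, 0)
  d <- poisson_ci(4, exposure = 2, level = 0)
  expect_equal(c(d$lower, d$upper), c(2, 2))  # degenerate at the estimate
  expect_error(poisson_ci(1, exposure = 0), "exposure")

  # empirical coverage of the exact interval is at least nominal
  set.seed(99)
  k <- rpois(1000, 5)
  ci <- poisson_ci(k)
  covered <- mean(ci$lower <= 5 & 5 <= ci$upper)
  expect_gte(covered, 0.95)
})

test_that("pairwise chi-square with Holm adjustment behaves", {
  strata <- tibble::tibble(stratum = c("a", "b", "c"),
                           count = c(30L, 30L, 60L),
                           exposure = c(1e6, 1e6, 1e6))
  out <- pairwise_chisq_holm(strata)
  expect_equal(nrow(out), 3)  # all pairs
  expect_gte(out$p_value[out$stratum1 == "a" & out$stratum2 == "b"], 0.9)
  expect_true(all(out$p_adj >= out$p_value))
  # closed-form Holm on two raw p-values
  expect_equal(p.adjust(c(0.01, 0.04), method = "holm"), c(0.02, 0.04))
  # monotone after sorting
  o <- order(out$p_value)
  expect_true(all(diff(out$p_adj[o]) >= -1e-12))
  expect_error(pairwise_chisq_holm(
    tibble::tibble(stratum = c("a", "b"), count = c(1L, 1L),
                   exposure = c(0, 1))), "zero exposure")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  # all 252 ways to split 10 into two margins of 5: the two extreme
  # tables have probability 1/252 each, two-sided p = 2/252
  expect_equal(fisher_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-9)
  tab <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(fisher_2x2(tab), fisher_2x2(t(tab)))
})
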