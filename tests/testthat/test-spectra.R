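spec_model <- function() {
  # short single-exon model with known composition
  cds <- paste0(rep("ACGTGC", 60), collapse = "")  # 360 bp
  ref_model(cds, tibble::tibble(start = 0L, end = nchar(cds)),
            name = "specToy")
}

test_that("six-class spectra count and fold substitutions", {
  m <- spec_model()
  # a single C>T lands in the C>T class
  v <- tibble::tibble(pos = 1L, ref = "C", alt = "T")
  s <- mutation_spectrum(v, m, context = 6)
  expect_equal(s$count, c(0L, 0L, 0L, 0L, 0L, 0L) +
                 as.integer(s$category == "C>T"))
  # G>A folds onto C>T
  g <- which(m$bases == "G")[1] - 1L
  s2 <- mutation_spectrum(tibble::tibble(pos = g, ref = "G", alt = "A"),
                          m, context = 6)
  expect_equal(s2$count[s2$category == "C>T"], 1L)
  # folding is an involution: folding the folded class changes nothing
  f1 <- duplexr:::fold_substitution("G", "A")
  f2 <- duplexr:::fold_substitution(f1$class_ref, f1$class_alt)
  expect_equal(f2$class_ref, f1$class_ref)
  expect_equal(f2$class_alt, f1$class_alt)
  # opportunities count reference alleles in the region
  expect_equal(unique(s$opportunity[startsWith(s$category, "C")]),
               sum(m$bases %in% c("C", "G")))
  expect_equal(unique(s$opportunity[startsWith(s$category, "T")]),
               sum(m$bases %in% c("A", "T")))
})

test_that("trinucleotide spectra use folded context and marginalise to 6", {
  m <- spec_model()
  # T[C>T]G: position 5 of ACGTGC|ACGTGC... has 5'=T, C, 3'=A? pick explicitly
  pos <- which(m$bases == "C")
  pos <- pos[pos > 1 & pos < m$length][2] - 1L
  ctx <- paste0(m$bases[pos], "[C>T]", m$bases[pos + 2L])
  s <- mutation_spectrum(tibble::tibble(pos = pos, ref = "C", alt = "T"),
                         m, context = 96)
  expect_equal(s$count[s$category == ctx], 1L)
  expect_equal(sum(s$count), 1L)

  # a CpG transition lands in the N[C>T]G bin
  cpg <- which(m$bases == "C" & dplyr::lead(m$bases) == "G")
  cpg <- cpg[cpg > 1][1] - 1L
  s_cpg <- mutation_spectrum(tibble::tibble(pos = cpg, ref = "C",
                                            alt = "T"), m, context = 96)
  hit <- s_cpg$category[s_cpg$count == 1L]
  expect_equal(substr(hit, 2L, 6L), "[C>T]")
  expect_equal(substr(hit, 7L, 7L), "G")

  # position without a 3' neighbour has no context
  expect_error(mutation_spectrum(
    tibble::tibble(pos = m$length - 1L, ref = m$bases[m$length],
                   alt = setdiff(c("A", "C", "G", "T"),
                                 m$bases[m$length])[1]),
    m, context = 96), "context at 0-based position")

  # random variant set: the 96-context spectrum marginalises exactly
  set.seed(4)
  idx <- sample(2:(m$length - 1L), 40, replace = TRUE)
  vs <- tibble::tibble(pos = idx - 1L, ref = m$bases[idx],
                       alt = vapply(m$bases[idx], function(b)
                         sample(setdiff(c("A", "C", "G", "T"), b), 1), ""))
  s96 <- mutation_spectrum(vs, m, context = 96)
  s6 <- mutation_spectrum(vs, m, context = 6)
  expect_equal(collapse_spectrum(s96)$count, s6$count)
})

test_that("opportunity normalisation follows the per-type formula", {
  # toy: 1 C>T variant, 100 C/G sites in a 400 bp region, one library at
  # coverage 10,000 -> 1 / ((100/400) * 10,000 * 400) = 1e-6
  spec <- tibble::tibble(category = sbs_classes(),
                         count = c(0L, 0L, 1L, 0L, 0L, 0L),
                         opportunity = c(100L, 100L, 100L, 300L, 300L,
                                         300L))
  class(spec) <- c("spectrum_matrix", class(spec))
  attr(spec, "context") <- 6L
  attr(spec, "region_size") <- 400L
  summ <- tibble::tibble(mean_coverage = 10000, region_size = 400L)
  out <- normalized_frequency_spectrum(spec, summ)
  expect_equal(out$frequency[out$category == "C>T"], 1e-6)
  expect_equal(out$frequency[out$category == "T>A"], 0)

  # doubling every coverage halves every class frequency
  out2 <- normalized_frequency_spectrum(
    spec, dplyr::mutate(summ, mean_coverage = 20000))
  expect_equal(out2$frequency, out$frequency / 2)

  # uniform opportunities make the normalised spectrum proportional to
  # raw counts
  spec$count <- c(2L, 1L, 3L, 0L, 1L, 1L)
  spec$opportunity <- rep(200L, 6)
  out3 <- normalized_frequency_spectrum(spec, summ)
  expect_equal(out3$frequency / max(out3$frequency),
               spec$count / max(spec$count))

  spec$opportunity[1] <- 0L
  expect_error(normalized_frequency_spectrum(spec, summ),
               "zero opportunity")
})

test_that("strand spectrum assigns pyrimidine-on-coding to untranscribed", {
  m <- spec_model()
  cpos <- which(m$bases == "C")[1] - 1L
  gpos <- which(m$bases == "G")[1] - 1L
  v <- tibble::tibble(pos = c(cpos, gpos), ref = c("C", "G"),
                      alt = c("T", "A"))
  s <- strand_spectrum(v, m)
  expect_equal(s$count[s$category == "C>T" &
                         s$strand == "untranscribed"], 1)
  expect_equal(s$count[s$category == "C>T" &
                         s$strand == "transcribed"], 1)
  expect_equal(sum(s$count), 2)
  empty <- strand_spectrum(v[0, ], m)
  expect_equal(sum(empty$count), 0)

  # a mutational process symmetric between strands leaves the two strand
  # bins balanced within binomial noise
  set.seed(6)
  idx <- sample(seq_len(m$length), 400, replace = TRUE)
  sym <- tibble::tibble(pos = idx - 1L, ref = m$bases[idx],
                        alt = vapply(m$bases[idx], function(b)
                          sample(setdiff(c("A", "C", "G", "T"), b), 1), ""))
  ss <- strand_spectrum(sym, m)
  tot <- tapply(ss$count, ss$strand, sum)
  p <- stats::binom.test(tot[["untranscribed"]], sum(tot))$p.value
  expect_gt(p, 0.001)
})

test_that("cosine similarity and its bootstrap reference behave", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")

  # reference concentrated in one category: every draw is identical
  conc <- c(50, 0, 0, 0, 0, 0)
  b <- bootstrap_cosine_reference(conc, n = 10, iterations = 100, seed = 1)
  expect_true(all(b$draws == 1))
  expect_length(b$draws, 100)

  # reproducible under a fixed seed, different otherwise
  ref <- c(30, 5, 40, 2, 15, 8)
  b1 <- bootstrap_cosine_reference(ref, n = 50, iterations = 200, seed = 7)
  b2 <- bootstrap_cosine_reference(ref, n = 50, iterations = 200, seed = 7)
  expect_identical(b1$draws, b2$draws)
  expect_false(identical(
    b1$draws,
    bootstrap_cosine_reference(ref, n = 50, iterations = 200,
                               seed = 8)$draws))

  # the reference distribution tightens toward 1 as n grows
  means <- vapply(c(10, 100, 1000), function(n) {
    mean(bootstrap_cosine_reference(ref, n = n, iterations = 300,
                                    seed = 3)$draws)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(means[3], 0.99)
  expect_error(bootstrap_cosine_reference(ref, n = 0), "n must be")

  cmp <- compare_spectra(c(10, 2, 20, 1, 5, 3), ref, iterations = 100,
                         seed = 2)
  expect_true(cmp$observed >= 0 && cmp$observed <= 1)
  expect_length(cmp$bootstrap$draws, 100)
})
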