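# Conversion-rate estimation, the exact binomial test, Holm adjustment,
# site calling and context/symmetry summaries.

test_that("conversion rates are pooled ratios over spike-in classes", {
  sp <- data.frame(state = c("5hmC", "unmodified"), NT = c(98L, 0L),
                   NC = c(2L, 50L))
  r <- estimate_conversion(sp)
  expect_equal(r$p_true, 0.98)
  expect_equal(r$p_bg, 0)

  sp2 <- data.frame(state = c("5hmC", "5hmC", "unmodified"),
                    NT = c(9L, 8L, 0L), NC = c(1L, 2L, 10L))
  expect_equal(estimate_conversion(sp2)$p_true, 17 / 20)

  expect_error(estimate_conversion(
    data.frame(state = c("5hmC", "unmodified"), NT = c(0L, 1L), NC = c(0L, 9L))),
    "coverage")
  expect_error(estimate_conversion(
    data.frame(state = c("5hmC", "unmodified"), NT = c(1L, 9L), NC = c(9L, 1L))),
    "chemistry")
})

test_that("read filtering keeps pairs with enough conversion evidence", {
  counts <- c(r1 = 0L, r2 = 5L, r3 = 1L)
  expect_equal(filter_reads(counts), c("r2", "r3"))
  expect_equal(filter_reads(counts, min_conversions = 2), "r2")
  expect_equal(filter_reads(counts, min_conversions = 0), names(counts))
  expect_error(filter_reads(c(r1 = -1L)), "non-negative")
})

test_that("binomial upper tail matches the summation oracle", {
  expect_equal(binom_site_pvalue(0, 10, 0.01), 1)
  expect_equal(binom_site_pvalue(10, 10, 0.5), 0.5^10)
  expect_equal(binom_site_pvalue(3, 10, 0.01), oracle_binom_upper(3, 10, 0.01),
               tolerance = 1e-12)
  expect_equal(binom_site_pvalue(3, 10, 0.01), 1.138e-4, tolerance = 1e-3)
  for (p in c(0.001, 0.01, 0.1, 0.5)) {
    n <- 30L
    nt <- 0:n
    expect_equal(binom_site_pvalue(nt, n, p),
                 vapply(nt, oracle_binom_upper, numeric(1), n = n, p = p),
                 tolerance = 1e-10)
  }
  expect_error(binom_site_pvalue(11, 10, 0.1), "exceed")
  expect_error(binom_site_pvalue(1, 10, 0), "p_bg")
})

test_that("Holm adjustment equals the step-down definition and dominates raw p", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  withr::with_seed(42, {
    for (i in 1:25) {
      p <- runif(sample(1:20, 1))
      expect_equal(holm_adjust(p), oracle_holm(p))
      expect_true(all(holm_adjust(p) >= p))
      m <- length(p) + sample(0:5, 1)
      expect_equal(holm_adjust(p, m = m), oracle_holm(p, m = m))
      expect_equal(bonferroni_adjust(p, m = m), oracle_bonferroni(p, m = m))
    }
  })
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("site calling applies coverage filters, Holm control and peak gating", {
  sites <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L), strand = "+",
    context = "CG", sample = "s1",
    NT = c(2L, 3L, 20L, 20L), NC = c(10L, 1L, 0L, 0L))
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 35L)
  rates <- list(p_true = 0.9, p_bg = 0.005)
  res <- call_sites(sites, rates, peaks)
  # NT=2: depth passes but never tested; N=4: out of the family entirely
  expect_false(res$tested[1]); expect_true(is.na(res$p_value[1]))
  expect_false(res$tested[2])
  # strong in-peak site is called, identical out-of-peak site is not
  expect_true(res$called[3])
  expect_true(res$tested[4] && res$p_holm[4] < 0.001 && !res$called[4])
  expect_true(all(res$p_holm >= res$p_value, na.rm = TRUE))
  expect_error(call_sites(sites, NULL, peaks), "rates")
})

test_that("the Holm family size counts untested depth-passing sites", {
  # 3 depth-passing sites, only one testable: its Holm factor must be 3
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), strand = "+",
                      context = "CG", sample = "s1",
                      NT = c(4L, 0L, 0L), NC = c(6L, 10L, 10L))
  res <- call_sites(sites, list(p_bg = 0.01),
                    data.frame(chrom = "chr1", start = 0L, end = 100L))
  expect_equal(res$p_holm[1], min(1, 3 * res$p_value[1]))
})

test_that("sequence contexts match hand-derived labels on both strands", {
  genome <- toy_context_genome()
  cases <- toy_context_cases()
  got <- classify_context(genome, rep("chr1", nrow(cases)), cases$pos,
                          cases$strand)
  expect_identical(got$context, cases$context)
  expect_identical(got$next_base, cases$next_base)

  expect_error(classify_context(genome, "chr1", 0, "+"), "not a cytosine")
  expect_error(classify_context(c(chr1 = "AAC"), "chr1", 2, "+"), "truncated")
  expect_error(classify_context(c(chr1 = "ACA"), "chr1", 1, "+"), "truncated")
  expect_error(classify_context(c(chr1 = "GACG"), "chr1", 0, "-"), "truncated")
})

test_that("symmetric CpG dyads classify identically on both strands", {
  # every CG dyad planted by the generator: + at x and - at x+1 both CG
  cfg <- sim_config(seed = 23, chrom_lengths = c(chr1 = 2e5))
  sc <- gen_site_counts(cfg, gen_genome(cfg)$genome, n_sites = 400,
                        modified_fraction = 0.5,
                        samples = data.frame(sample = "s1", tissue = "T1"))
  minus <- sc$truth[sc$truth$strand == "-", ]
  expect_gt(nrow(minus), 0)
  plus_cc <- classify_context(sc$genome, minus$chrom, minus$pos - 1L, "+")
  minus_cc <- classify_context(sc$genome, minus$chrom, minus$pos, "-")
  expect_true(all(plus_cc$context == "CG" & minus_cc$context == "CG"))
})

test_that("symmetry and CH fractions handle the degenerate cases", {
  one_dyad <- data.frame(chrom = "chr1", pos = c(10L, 11L), strand = c("+", "-"),
                         context = "CG", called = TRUE)
  expect_equal(symmetry_fraction(one_dyad), 1.0)
  expect_equal(symmetry_fraction(one_dyad[1, ]), 0.0)

  sites <- data.frame(context = c(rep("CG", 99), "CHH"), called = TRUE,
                      sample = "s1")
  expect_equal(ch_fraction(sites), 0.01)
  expect_equal(ch_fraction(data.frame(context = rep("CG", 5), called = TRUE)), 0)
  expect_message(v <- ch_fraction(data.frame(context = character(),
                                             called = logical())),
                 "undefined")
  expect_true(is.na(v))
})
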