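# Synthetic-data generator: determinism, containment and recovery of the
# configured generative parameters within sampling tolerance.

test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(p_bg = 0.5, p_true = 0.4), "p_bg")
  expect_error(sim_config(planted_fc = 1), "planted_fc")
  expect_error(sim_config(chrom_lengths = c(chr1 = 0)), "zero-length")
  expect_error(sim_config(link_r = 0), "link_r")
  expect_error(sim_config(base_lambda = -1), "base_lambda")
})

test_that("the same seed reproduces the genome and counts bit-for-bit", {
  cfg <- sim_config(seed = 7, chrom_lengths = c(chr1 = 60000))
  g1 <- gen_genome(cfg)
  g2 <- gen_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)
  s1 <- gen_site_counts(cfg, g1$genome, n_sites = 300,
                        samples = data.frame(sample = "s1", tissue = "T1"))
  s2 <- gen_site_counts(cfg, g2$genome, n_sites = 300,
                        samples = data.frame(sample = "s1", tissue = "T1"))
  expect_identical(s1$sites, s2$sites)
  expect_identical(gen_region_counts(cfg, n_regions = 30)$counts,
                   gen_region_counts(cfg, n_regions = 30)$counts)
})

test_that("gene models stay within chromosome bounds", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(chr1 = 10000))
  gg <- gen_genome(cfg, gene_spacing = 2000, gene_length_range = c(500, 1500))
  expect_true(all(gg$genes$start >= 0 & gg$genes$end <= 10000))
  expect_true(all(gg$genes$tss ==
                    ifelse(gg$genes$strand == "+", gg$genes$start,
                           gg$genes$end - 1L)))
})

test_that("genome base composition is uniform within binomial tolerance", {
  cfg <- sim_config(seed = 11, chrom_lengths = c(chr1 = 100000))
  s <- strsplit(as.character(gen_genome(cfg)$genome[[1]]), "")[[1]]
  freqs <- table(s) / length(s)
  expect_true(all(abs(freqs - 0.25) < 0.02))
})

test_that("site counts follow the configured conversion rates", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 1e6))
  gg <- gen_genome(cfg)
  sc <- gen_site_counts(cfg, gg$genome, n_sites = 12500,
                        modified_fraction = 0.8,
                        samples = data.frame(sample = "s1", tissue = "T1"))
  key <- paste(sc$sites$chrom, sc$sites$pos, sc$sites$strand)
  tkey <- paste(sc$truth$chrom, sc$truth$pos, sc$truth$strand)
  mod <- sc$truth$is_modified[match(key, tkey)]
  conv <- sc$sites$NT / (sc$sites$NT + sc$sites$NC)
  expect_gt(sum(mod), 10000)
  expect_lt(abs(mean(conv[mod]) - cfg$p_true), 0.01)
  expect_lt(abs(mean(conv[!mod]) - cfg$p_bg), 0.005)
  expect_true(all(sc$sites$NT + sc$sites$NC >= 1))  # truncated depth
})

test_that("a zero background rate yields zero converted reads at null sites", {
  cfg <- sim_config(seed = 2, p_bg = 0, chrom_lengths = c(chr1 = 2e5))
  sc <- gen_site_counts(cfg, gen_genome(cfg)$genome, n_sites = 500,
                        modified_fraction = 0.2,
                        samples = data.frame(sample = "s1", tissue = "T1"))
  key <- paste(sc$sites$chrom, sc$sites$pos)
  tkey <- paste(sc$truth$chrom, sc$truth$pos)
  mod <- sc$truth$is_modified[match(key, tkey)]
  expect_true(all(sc$sites$NT[!mod] == 0))
})

test_that("planted symmetric CpG fraction is recovered from the truth table", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(chr1 = 2e6))
  sc <- gen_site_counts(cfg, gen_genome(cfg)$genome, n_sites = 12500,
                        modified_fraction = 0.8,
                        samples = data.frame(sample = "s1", tissue = "T1"))
  truth <- sc$truth
  truth$called <- truth$is_modified
  expect_lt(abs(symmetry_fraction(truth) - 0.13), 0.02)
  # planted contexts agree with the emitted genome sequence
  cc <- classify_context(sc$genome, truth$chrom, truth$pos, truth$strand)
  expect_identical(cc$context, truth$context)
})

test_that("region counts plant an exact tissue-specific fraction with Poisson noise", {
  cfg <- sim_config(seed = 13)
  rc <- gen_region_counts(cfg, n_regions = 3000)
  expect_identical(sum(!is.na(rc$truth$specific_tissue)), 1000L)
  expect_true(all(rc$truth$fc[is.na(rc$truth$specific_tissue)] == 1))

  none <- gen_region_counts(sim_config(seed = 13, planted_ts_fraction = 0),
                            n_regions = 300)
  expect_true(all(none$truth$fc == 1))

  # size-factor-corrected null counts have mean base_lambda
  norm <- sweep(rc$counts, 2, rc$size_factors_true, "/")
  null_rows <- is.na(rc$truth$specific_tissue)
  vals <- norm[null_rows, ]
  tol <- 3 * sqrt(2 * cfg$base_lambda / length(vals))
  expect_lt(abs(mean(vals) - cfg$base_lambda), tol)
  expect_true(all(rc$size_factors_true >= 0.5 & rc$size_factors_true <= 2))
})

test_that("planted links reach the target correlation and noise genes do not", {
  cfg <- sim_config(seed = 17, n_tissues = 16, link_r = 0.95)
  gg <- gen_genome(cfg)
  rc <- gen_region_counts(cfg, n_regions = 600)
  ex <- gen_expression_and_links(cfg, rc, gg$genes)
  r <- mapply(function(reg, gene) {
    cor(ex$signal[reg, ], ex$tpm[gene, ])
  }, ex$links$region, ex$links$gene)
  expect_gt(mean(r >= 0.8 & r <= 1), 0.9)

  # zero-noise limit: exact affine dependence
  ex1 <- gen_expression_and_links(sim_config(seed = 17, n_tissues = 16,
                                             link_r = 1), rc, gg$genes)
  r1 <- mapply(function(reg, gene) cor(ex1$signal[reg, ], ex1$tpm[gene, ]),
               ex1$links$region, ex1$links$gene)
  expect_equal(unname(r1), rep(1, length(r1)), tolerance = 1e-12)

  # unlinked genes are independent of region signal
  noise_genes <- head(setdiff(rownames(ex$tpm), ex$links$gene), 100)
  reg <- ex$links$region[1]
  rn <- vapply(noise_genes, function(g) cor(ex$signal[reg, ], ex$tpm[g, ]),
               numeric(1))
  expect_lt(mean(abs(rn)), 0.5)
})

test_that("SNP catalogs respect bounds and the planted odds ratio", {
  cfg <- sim_config(seed = 19)
  rc <- gen_region_counts(cfg, n_regions = 3000)
  sn <- gen_snp_catalog(cfg, rc, n_snps = 10000, planted_or = 10)
  lens <- cfg$chrom_lengths
  expect_true(all(sn$snps$pos >= 0 & sn$snps$pos < lens[sn$snps$chrom]))

  target <- rc$regions[!is.na(rc$truth$specific_tissue) &
                         rc$truth$specific_tissue == sn$truth$tissue, ]
  inr <- overlap_snps(sn$snps, target, quiet = TRUE)
  fe <- fisher_enrichment(inr, sn$snps$phenotype)
  top <- fe[fe$phenotype == sn$truth$phenotype, ]
  expect_gt(top$odds_ratio, 5)
  expect_lt(top$odds_ratio, 20)

  flat <- gen_snp_catalog(cfg, rc, n_snps = 2000, planted_or = 1)
  expect_equal(flat$truth$prob_in_planted, flat$truth$prob_in_null)
})
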