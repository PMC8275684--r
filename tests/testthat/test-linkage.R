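# Tissue-specific expression lists, gene-body signal and windowed linkage.

test_that("tissue-specific genes obey the mean, rank and fold-change filters", {
  tpm <- rbind(marker = c(100, 1, 1),
               low = c(0.9, 0.2, 0.4),       # mean < 1: dropped first
               flat = c(10, 10, 10),          # FC 1: dropped by min_fc
               mild = c(12, 10, 10))          # FC 1.2: dropped by min_fc
  colnames(tpm) <- paste0("T", 1:3)
  res <- tissue_specific_genes(tpm)
  expect_equal(res$T1, "marker")
  expect_equal(res$T2, character(0))

  # lists may be shorter than top_n and never exceed it
  withr::with_seed(43, big <- matrix(rexp(2000, 0.1), ncol = 4,
                                     dimnames = list(sprintf("g%03d", 1:500),
                                                     paste0("T", 1:4))))
  res2 <- tissue_specific_genes(big, top_n = 20)
  expect_true(all(lengths(res2) <= 20))
  for (t in colnames(big)) {
    sel <- res2[[t]]
    other <- rowMeans(big[sel, setdiff(colnames(big), t), drop = FALSE])
    expect_true(all(big[sel, t] / other >= 2))
    expect_true(all(rowMeans(big[sel, , drop = FALSE]) >= 1))
  }
  expect_error(tissue_specific_genes(tpm[, 1, drop = FALSE]), "two tissues")
})

test_that("gene-body signal is a length- and depth-normalized density", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 0L, end = 10000L, tss = 0L,
                      biotype = "protein_coding",
                      exon_starts = "0", exon_ends = "10000")
  counts <- matrix(1000, 1, 1, dimnames = list("g1", "s1"))
  sig <- gene_body_signal(counts, genes, library_sizes = c(s1 = 1e6))
  expect_equal(sig[1, 1], 100)
  # doubling counts and library size together leaves the density unchanged
  expect_equal(gene_body_signal(counts * 2, genes, library_sizes = c(s1 = 2e6)),
               sig)
  expect_equal(gene_body_signal(counts * 0, genes,
                                library_sizes = c(s1 = 1e6))[1, 1], 0)
  genes$end <- 0L; genes$tss <- 0L
  expect_error(gene_body_signal(counts, genes), "zero-length")
})

test_that("site counts aggregate over gene bodies per sample", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                      start = c(0L, 500L), end = c(100L, 600L),
                      tss = c(0L, 500L), biotype = "protein_coding",
                      exon_starts = c("0", "500"), exon_ends = c("100", "600"))
  sites <- data.frame(chrom = "chr1", pos = c(10L, 50L, 550L, 900L),
                      strand = "+", context = "CG", sample = "s1",
                      NT = c(3L, 4L, 5L, 9L), NC = 0L)
  m <- gene_site_counts(sites, genes)
  expect_equal(m["g1", "s1"], 7)
  expect_equal(m["g2", "s1"], 5)   # the site at 900 hits no gene
})

test_that("signal-expression correlations recover monotone couplings", {
  sig <- matrix(1:5, 1, dimnames = list("g1", paste0("T", 1:5)))
  up <- matrix(c(2, 4, 9, 11, 30), 1, dimnames = dimnames(sig))
  expect_equal(unname(expression_correlation(sig, up)["g1"]), 1)
  lin <- matrix(2 * (1:5) + 3, 1, dimnames = dimnames(sig))
  expect_equal(unname(expression_correlation(sig, lin, method = "pearson")["g1"]), 1)
  down <- matrix(c(30, 11, 9, 4, 2), 1, dimnames = dimnames(sig))
  expect_equal(unname(expression_correlation(sig, down)["g1"]), -1)
  const <- matrix(5, 1, 5, dimnames = dimnames(sig))
  expect_true(is.na(expression_correlation(sig, const)["g1"]))
})

test_that("linkage respects the 500 kb window, t test and confidence rule", {
  regions <- data.frame(chrom = "chr1", start = 1000000L, end = 1001000L,
                        name = "regA")
  # TSS exactly 500,000 bp from the region's last base is still a candidate;
  # one base further is not
  genes <- data.frame(gene_id = c("gNear", "gEdge", "gFar"), chrom = "chr1",
                      strand = "+",
                      start = c(1100000L, 1500999L, 1501000L),
                      end = c(1110000L, 1510000L, 1510001L),
                      tss = c(1100000L, 1500999L, 1501000L),
                      biotype = "protein_coding",
                      exon_starts = "0", exon_ends = "1")
  genes$exon_starts <- as.character(genes$start)
  genes$exon_ends <- as.character(genes$end)
  tissues <- paste0("T", 1:16)
  x <- c(5, 3, 8, 2, 9, 4, 7, 1, 6, 10, 2.5, 3.5, 8.5, 4.5, 5.5, 7.5)
  sig <- matrix(x, 1, dimnames = list("regA", tissues))
  set.seed(47)
  make_y <- function(r) r * scale(x)[, 1] + sqrt(1 - r^2) * scale(rnorm(16))[, 1]
  tpm <- rbind(gNear = 50 + 10 * make_y(0.995), gEdge = 50 + 10 * make_y(0.2),
               gFar = 50 + 10 * make_y(0.9))
  colnames(tpm) <- tissues
  links <- link_tsdhmrs("regA", regions, genes, sig, tpm)
  expect_setequal(links$gene, c("gNear", "gEdge"))  # gFar: outside the window
  expect_equal(links$distance[links$gene == "gEdge"], 500000L)

  near <- links[links$gene == "gNear", ]
  expect_true(near$confident)
  # the p-value is the two-sided t transform of r on n - 2 df
  tstat <- near$pearson_r * sqrt(14) / sqrt(1 - near$pearson_r^2)
  expect_equal(near$p_value, 2 * stats::pt(-abs(tstat), df = 14),
               tolerance = 1e-12)
  expect_false(links$confident[links$gene == "gEdge"])

  # a perfect affine relationship stays confident with a floored p-value
  tpm2 <- rbind(gNear = 10 + 2 * x, gEdge = tpm["gEdge", ], gFar = tpm["gFar", ])
  colnames(tpm2) <- tissues
  links2 <- link_tsdhmrs("regA", regions, genes, sig, tpm2)
  perfect <- links2[links2$gene == "gNear", ]
  expect_equal(perfect$pearson_r, 1)
  expect_true(perfect$p_value >= 1e-300 && perfect$confident)

  # constant expression is skipped with a warning
  tpm3 <- tpm; tpm3["gEdge", ] <- 7
  expect_warning(links3 <- link_tsdhmrs("regA", regions, genes, sig, tpm3),
                 "constant")
  expect_false("gEdge" %in% links3$gene)
})
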