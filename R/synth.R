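# Synthetic hydroxymethylome generator with planted truth.
#
# Every generator is deterministic given the configuration seed: each one
# derives its own stream with a fixed offset from `seed`, so generators can be
# called in any order (or individually) and still reproduce bit-identical
# output.

#' Simulation configuration
#'
#' Bundles the generative parameters for the synthetic hydroxymethylome.
#' Defaults describe the study conditions the package is validated under:
#' high conversion (`p_true`) at genuine 5hmC sites against a low background
#' (`p_bg`), ~20x site coverage, Poisson region counts with mean
#' `base_lambda`, a third of regions hyperhydroxymethylated in exactly one
#' tissue at fold change `planted_fc`, 98% of modified cytosines in CpG
#' context with 13% of modified CpG dyads symmetric, and planted region-gene
#' links with generative Pearson correlation `link_r`.
#'
#' @param seed integer seed fixing all generator output bit-for-bit.
#' @param n_tissues,n_replicates_per_tissue sample layout.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param p_true C-to-T conversion rate at true 5hmC sites.
#' @param p_bg background conversion rate at unmodified cytosines.
#' @param depth_mean mean per-site sequencing depth (Poisson, truncated >= 1).
#' @param planted_ts_fraction fraction of regions planted as tissue-specific.
#' @param planted_fc signal fold change of planted regions (> 1).
#' @param base_lambda mean region count in non-specific tissues.
#' @param link_r target generative Pearson correlation for planted links.
#' @param cg_fraction fraction of modified sites in CG context.
#' @param symmetric_fraction fraction of modified CpG dyads modified on both
#'   strands.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_tissues = 8L,
                       n_replicates_per_tissue = 2L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                       p_true = 0.9,
                       p_bg = 0.005,
                       depth_mean = 20,
                       planted_ts_fraction = 1 / 3,
                       planted_fc = 5,
                       base_lambda = 50,
                       link_r = 0.95,
                       cg_fraction = 0.98,
                       symmetric_fraction = 0.13) {
  cfg <- list(seed = as.integer(seed), n_tissues = as.integer(n_tissues),
              n_replicates_per_tissue = as.integer(n_replicates_per_tissue),
              chrom_lengths = chrom_lengths, p_true = p_true, p_bg = p_bg,
              depth_mean = depth_mean, planted_ts_fraction = planted_ts_fraction,
              planted_fc = planted_fc, base_lambda = base_lambda,
              link_r = link_r, cg_fraction = cg_fraction,
              symmetric_fraction = symmetric_fraction)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  for (f in c("p_true", "p_bg", "planted_ts_fraction", "cg_fraction",
              "symmetric_fraction"))
    check_fraction(cfg[[f]], f)
  if (!length(cfg$chrom_lengths) || is.null(names(cfg$chrom_lengths)))
    stopf("chrom_lengths must be a non-empty named vector")
  if (any(cfg$chrom_lengths <= 0)) stopf("zero-length chromosome in chrom_lengths")
  if (cfg$p_bg >= cfg$p_true) stopf("p_bg must be < p_true")
  if (cfg$planted_fc <= 1) stopf("planted_fc must be > 1")
  if (cfg$depth_mean <= 0) stopf("depth_mean must be > 0")
  if (cfg$base_lambda <= 0) stopf("base_lambda must be > 0")
  if (cfg$link_r <= 0 || cfg$link_r > 1) stopf("link_r must be in (0, 1]")
  if (cfg$n_tissues < 1 || cfg$n_replicates_per_tissue < 1)
    stopf("n_tissues and n_replicates_per_tissue must be >= 1")
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` object.
#' @return `sim_samples()`: data.frame with columns `sample`, `tissue`,
#'   `replicate`, one row per (tissue, replicate).
#' @export
sim_samples <- function(config) {
  tissues <- sprintf("T%d", seq_len(config$n_tissues))
  reps <- seq_len(config$n_replicates_per_tissue)
  grid <- expand.grid(replicate = reps, tissue = tissues,
                      stringsAsFactors = FALSE)[, c("tissue", "replicate")]
  data.frame(sample = sprintf("%s.R%d", grid$tissue, grid$replicate),
             tissue = grid$tissue, replicate = grid$replicate,
             stringsAsFactors = FALSE)
}

#' Generate a random genome with toy gene models
#'
#' Each chromosome is an i.i.d. uniform A/C/G/T sequence. Non-overlapping
#' genes are placed along each chromosome with exonic block structure; the
#' TSS is the gene-body start on the + strand and `end - 1` on the - strand.
#'
#' @param config a [sim_config()] object.
#' @param gene_spacing approximate distance between consecutive gene starts (bp).
#' @param gene_length_range min/max gene-body length (bp).
#' @param n_exons_range min/max exon count per gene.
#' @return list with `genome` (a `DNAStringSet`) and `genes` (a gene-model
#'   data.frame in the [read_gene_models()] format).
#' @export
gen_genome <- function(config, gene_spacing = 15000,
                       gene_length_range = c(2000, 8000),
                       n_exons_range = c(1L, 4L)) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 11L, {
    seqs <- vapply(config$chrom_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    genes <- list(); gi <- 0L
    for (chrom in names(config$chrom_lengths)) {
      L <- config$chrom_lengths[[chrom]]
      pos <- 2000
      while (TRUE) {
        len <- round(runif(1, gene_length_range[1L], gene_length_range[2L]))
        if (pos + len + 2000 > L) break
        gi <- gi + 1L
        strand <- sample(c("+", "-"), 1L)
        n_ex <- sample(seq(n_exons_range[1L], n_exons_range[2L]), 1L)
        nseg <- 2L * n_ex - 1L
        widths <- as.vector(stats::rmultinom(1L, len - nseg, rep(1, nseg))) + 1L
        bounds <- pos + cumsum(c(0L, widths))
        ex_idx <- seq(1L, nseg, by = 2L)
        genes[[gi]] <- data.frame(
          gene_id = sprintf("gene_%04d", gi), chrom = chrom, strand = strand,
          start = as.integer(pos), end = as.integer(pos + len),
          tss = as.integer(if (strand == "+") pos else pos + len - 1L),
          biotype = "protein_coding",
          exon_starts = paste(bounds[ex_idx], collapse = ","),
          exon_ends = paste(bounds[ex_idx + 1L], collapse = ","),
          stringsAsFactors = FALSE)
        pos <- pos + len + round(runif(1, 0.4, 1.6) * gene_spacing)
      }
    }
    list(genome = Biostrings::DNAStringSet(seqs),
         genes = do.call(rbind, genes))
  })
}

#' Generate per-cytosine converted/unconverted counts with planted 5hmC sites
#'
#' Modified sites draw converted counts `NT ~ Binomial(depth, p_true)` in
#' every sample; unmodified cytosines draw `NT ~ Binomial(depth, p_bg)`;
#' depth is Poisson(`depth_mean`) truncated at 1. Sequence contexts are
#' planted into the genome (so [classify_context()] reproduces them):
#' CG with probability `cg_fraction` (after accounting for symmetric-partner
#' duplication), otherwise CHG/CHH. A fraction `symmetric_fraction` of
#' modified CpGs is modified on both strands. Modified sites are grouped into
#' enriched peak intervals; a fraction of unmodified sites is placed inside
#' peaks so that specificity is exercised where calls are possible.
#'
#' @param config a [sim_config()] object.
#' @param genome output of [gen_genome()] (the list, or its `genome` element).
#' @param n_sites total number of base cytosine sites to emit.
#' @param modified_fraction fraction of sites that carry 5hmC.
#' @param samples sample sheet data.frame (`sample`, `tissue`); defaults to
#'   the full layout from [sim_samples()].
#' @param inpeak_null_fraction fraction of unmodified sites placed inside peaks.
#' @param sites_per_peak modified sites grouped per peak interval.
#' @return list with `sites` (site count table), `truth` (per-site truth),
#'   `peaks` (BED-style intervals shared by all tissues), and `genome` (the
#'   edited `DNAStringSet` consistent with the planted contexts).
#' @export
gen_site_counts <- function(config, genome, n_sites = 10000,
                            modified_fraction = 0.2, samples = NULL,
                            inpeak_null_fraction = 0.3, sites_per_peak = 10L) {
  validate_sim_config(config)
  if (config$p_bg >= config$p_true) stopf("p_bg must be < p_true")
  if (is.list(genome) && !methods::is(genome, "DNAStringSet")) genome <- genome$genome
  if (is.null(samples)) samples <- sim_samples(config)
  chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1L]])
  lens <- chrom_lengths(genome)

  withr::with_seed(config$seed + 23L, {
    # candidate grid: positions spaced 8 bp so context edits never collide;
    # blocks of 50 grid points are potential peak windows (~400 bp)
    grid <- do.call(rbind, lapply(names(lens), function(chrom) {
      p <- seq(6L, lens[[chrom]] - 7L, by = 8L)
      data.frame(chrom = chrom, pos = p, stringsAsFactors = FALSE)
    }))
    block_size <- 50L
    n_blocks <- nrow(grid) %/% block_size
    grid <- grid[seq_len(n_blocks * block_size), , drop = FALSE]
    grid$block <- rep(seq_len(n_blocks), each = block_size)
    # a usable block never straddles chromosomes
    first_chrom <- grid$chrom[seq(1L, nrow(grid), by = block_size)]
    last_chrom <- grid$chrom[seq(block_size, nrow(grid), by = block_size)]
    usable <- which(first_chrom == last_chrom)

    n_mod <- round(n_sites * modified_fraction)
    n_null <- n_sites - n_mod
    n_null_in <- round(n_null * inpeak_null_fraction)
    n_null_out <- n_null - n_null_in
    n_peaks <- max(1L, ceiling(n_mod / sites_per_peak))
    if (n_peaks > length(usable))
      stopf("genome too small for %d peaks; enlarge chrom_lengths", n_peaks)
    peak_blocks <- sample(usable, n_peaks)

    mod_per_peak <- diff(round(seq(0, n_mod, length.out = n_peaks + 1L)))
    nullin_per_peak <- diff(round(seq(0, n_null_in, length.out = n_peaks + 1L)))
    site_rows <- vector("list", n_peaks + 1L)
    peak_rows <- vector("list", n_peaks)
    for (i in seq_len(n_peaks)) {
      g <- grid[grid$block == peak_blocks[i], , drop = FALSE]
      take <- mod_per_peak[i] + nullin_per_peak[i]
      if (take > nrow(g)) stopf("peak block too small; reduce sites_per_peak")
      sel <- g[sample(nrow(g), take), , drop = FALSE]
      site_rows[[i]] <- data.frame(
        chrom = sel$chrom, pos = sel$pos,
        is_modified = rep(c(TRUE, FALSE), c(mod_per_peak[i], nullin_per_peak[i])),
        in_peak = TRUE, stringsAsFactors = FALSE)
      peak_rows[[i]] <- data.frame(
        chrom = g$chrom[1L], start = min(g$pos) - 4L, end = max(g$pos) + 6L,
        stringsAsFactors = FALSE)
    }
    out_grid <- grid[!(grid$block %in% peak_blocks), , drop = FALSE]
    sel <- out_grid[sample(nrow(out_grid), n_null_out), , drop = FALSE]
    site_rows[[n_peaks + 1L]] <- data.frame(
      chrom = sel$chrom, pos = sel$pos, is_modified = FALSE, in_peak = FALSE,
      stringsAsFactors = FALSE)
    sites <- do.call(rbind, site_rows)
    sites$strand <- "+"

    # context assignment; base CH probability compensates for the symmetric
    # CpG partners added below so the emitted CH fraction matches the config
    ch_target <- 1 - config$cg_fraction
    s <- config$symmetric_fraction
    ch_base <- ch_target * (1 + s) / (1 + ch_target * s)
    u <- runif(nrow(sites))
    sites$context <- ifelse(u < ch_base,
                            ifelse(runif(nrow(sites)) < 0.5, "CHG", "CHH"),
                            "CG")

    # edit the genome so classify_context() agrees with the planted labels
    H <- c("A", "C", "T")
    for (chrom in unique(sites$chrom)) {
      idx <- which(sites$chrom == chrom)
      v <- chars[[chrom]]
      p1 <- sites$pos[idx] + 1L            # 1-based index of the cytosine
      v[p1] <- "C"
      is_cg <- sites$context[idx] == "CG"
      is_chg <- sites$context[idx] == "CHG"
      is_chh <- sites$context[idx] == "CHH"
      v[p1[is_cg] + 1L] <- "G"
      v[p1[is_chg] + 1L] <- sample(H, sum(is_chg), replace = TRUE)
      v[p1[is_chg] + 2L] <- "G"
      v[p1[is_chh] + 1L] <- sample(H, sum(is_chh), replace = TRUE)
      v[p1[is_chh] + 2L] <- sample(H, sum(is_chh), replace = TRUE)
      chars[[chrom]] <- v
    }

    # symmetric CpG partners: minus-strand cytosine one base downstream
    cand <- which(sites$is_modified & sites$context == "CG")
    sym <- cand[runif(length(cand)) < s]
    if (length(sym)) {
      partners <- data.frame(chrom = sites$chrom[sym], pos = sites$pos[sym] + 1L,
                             is_modified = TRUE, in_peak = TRUE, strand = "-",
                             context = "CG", stringsAsFactors = FALSE)
      sites <- rbind(sites, partners)
    }

    o <- order(sites$chrom, sites$pos, sites$strand)
    sites <- sites[o, , drop = FALSE]
    rownames(sites) <- NULL
    truth <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        strand = sites$strand, is_modified = sites$is_modified,
                        context = sites$context, in_peak = sites$in_peak,
                        tissue_set = "*", stringsAsFactors = FALSE)

    peaks <- do.call(rbind, peak_rows)
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    peaks$name <- sprintf("peak_%05d", seq_len(nrow(peaks)))
    peaks$score <- "."
    peaks$strand <- "."
    rownames(peaks) <- NULL

    ns <- nrow(sites); nsmp <- nrow(samples)
    depth <- rtpois(ns * nsmp, config$depth_mean)
    p <- rep(ifelse(sites$is_modified, config$p_true, config$p_bg), times = nsmp)
    nt <- rbinom(ns * nsmp, depth, p)
    counts <- data.frame(
      chrom = rep(sites$chrom, times = nsmp),
      pos = rep(sites$pos, times = nsmp),
      strand = rep(sites$strand, times = nsmp),
      context = rep(sites$context, times = nsmp),
      sample = rep(samples$sample, each = ns),
      NT = nt, NC = depth - nt, stringsAsFactors = FALSE)

    list(sites = counts, truth = truth, peaks = peaks,
         genome = Biostrings::DNAStringSet(vapply(chars, paste, character(1),
                                                  collapse = "")))
  })
}

#' Generate spike-in control counts
#'
#' Emulates a spiked-in model sequence carrying fully hydroxymethylated
#' cytosines (conversion rate `p_true`) alongside unmodified reference
#' cytosines (conversion rate `p_bg`), read at high depth. The output feeds
#' [estimate_conversion()].
#'
#' @param config a [sim_config()] object.
#' @param depth read depth per spike-in site.
#' @param n_modified,n_unmodified number of spike-in cytosines per class.
#' @return data.frame with columns `site_id`, `state`, `NT`, `NC`.
#' @export
gen_spikein_counts <- function(config, depth = 5000L, n_modified = 3L,
                               n_unmodified = 20L) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 31L, {
    n <- n_modified + n_unmodified
    state <- rep(c("5hmC", "unmodified"), c(n_modified, n_unmodified))
    p <- ifelse(state == "5hmC", config$p_true, config$p_bg)
    nt <- rbinom(n, depth, p)
    data.frame(site_id = sprintf("spike_%02d", seq_len(n)), state = state,
               NT = nt, NC = depth - nt, stringsAsFactors = FALSE)
  })
}

#' Generate a region-by-sample Poisson count matrix with planted
#' tissue-specific regions
#'
#' Regions are tiled across the genome. Exactly
#' `floor(n_regions * planted_ts_fraction)` regions are planted as specific to
#' one tissue each (assigned cyclically over tissues): their counts in that
#' tissue have mean `base_lambda * planted_fc * sf`, all other (region,
#' tissue) pairs have mean `base_lambda * sf`, with per-sample size factors
#' `sf` drawn log-uniformly from \[0.5, 2\] and independent Poisson replicates.
#'
#' @param config a [sim_config()] object.
#' @param n_regions number of regions to tile.
#' @param region_width,region_gap tiling geometry (bp).
#' @return list with `regions` (BED-style data.frame), `samples` (sample
#'   sheet), `counts` (integer matrix regions x samples), `size_factors_true`
#'   (the generative per-sample scale), and `truth` (per-region data.frame
#'   with `specific_tissue`, `NA` for non-specific, and generative `fc`).
#' @export
gen_region_counts <- function(config, n_regions = 3000, region_width = 800,
                              region_gap = 1000) {
  validate_sim_config(config)
  if (config$n_tissues < 2L) stopf("n_tissues must be >= 2")
  step <- region_width + region_gap
  tiles <- do.call(rbind, lapply(names(config$chrom_lengths), function(chrom) {
    L <- config$chrom_lengths[[chrom]]
    starts <- seq(1000, L - region_width - 1000, by = step)
    data.frame(chrom = chrom, start = as.integer(starts),
               end = as.integer(starts + region_width), stringsAsFactors = FALSE)
  }))
  if (nrow(tiles) < n_regions)
    stopf("genome too small for %d regions (capacity %d)", n_regions, nrow(tiles))
  regions <- tiles[seq_len(n_regions), , drop = FALSE]
  regions$name <- sprintf("region_%05d", seq_len(n_regions))
  regions$score <- "."
  regions$strand <- "."
  rownames(regions) <- NULL
  samples <- sim_samples(config)
  tissues <- unique(samples$tissue)

  withr::with_seed(config$seed + 41L, {
    n_planted <- floor(n_regions * config$planted_ts_fraction)
    planted_idx <- sort(sample(n_regions, n_planted))
    planted_tissue <- rep_len(tissues, n_planted)
    truth <- data.frame(region = regions$name, specific_tissue = NA_character_,
                        fc = 1, stringsAsFactors = FALSE)
    truth$specific_tissue[planted_idx] <- planted_tissue
    truth$fc[planted_idx] <- config$planted_fc

    sf <- exp(runif(nrow(samples), log(0.5), log(2)))
    fc_mat <- matrix(1, n_regions, length(tissues), dimnames = list(regions$name, tissues))
    fc_mat[cbind(planted_idx, match(planted_tissue, tissues))] <- config$planted_fc
    mu <- fc_mat[, samples$tissue, drop = FALSE] * config$base_lambda
    mu <- sweep(mu, 2L, sf, "*")
    counts <- matrix(rpois(length(mu), mu), nrow = n_regions,
                     dimnames = list(regions$name, samples$sample))
    list(regions = regions, samples = samples, counts = counts,
         size_factors_true = sf, truth = truth)
  })
}

#' Generate expression tables with planted region-gene links
#'
#' For each planted tissue-specific region, the nearest unused gene with a
#' TSS within `window` bp becomes its target: the gene's TPM across tissues
#' is an affine transform of the region's replicate-averaged normalized
#' signal plus Gaussian noise calibrated so the expected Pearson correlation
#' equals `link_r`. All other genes receive tissue-independent TPM.
#'
#' @param config a [sim_config()] object.
#' @param region_sim output of [gen_region_counts()].
#' @param genes gene-model data.frame (from [gen_genome()]).
#' @param window maximum TSS-to-region distance for a planted link (bp).
#' @return list with `tpm` (gene x tissue matrix), `links` (planted-link
#'   truth: region, gene, tissue, distance), and `signal` (region x tissue
#'   normalized signal used for the transform).
#' @export
gen_expression_and_links <- function(config, region_sim, genes, window = 500000) {
  validate_sim_config(config)
  if (config$link_r <= 0 || config$link_r > 1) stopf("link_r must be in (0, 1]")
  norm <- sweep(region_sim$counts, 2L, region_sim$size_factors_true, "/")
  tissues <- unique(region_sim$samples$tissue)
  signal <- vapply(tissues, function(t) {
    rowMeans(norm[, region_sim$samples$sample[region_sim$samples$tissue == t],
                  drop = FALSE])
  }, numeric(nrow(norm)))

  planted <- which(!is.na(region_sim$truth$specific_tissue))
  withr::with_seed(config$seed + 53L, {
    n_t <- length(tissues)
    tpm <- matrix(pmax(0, rnorm(nrow(genes) * n_t, 30, 8)), nrow(genes), n_t,
                  dimnames = list(genes$gene_id, tissues))
    used <- logical(nrow(genes))
    links <- list()
    noise_scale <- sqrt(1 / config$link_r^2 - 1)
    for (ri in planted) {
      reg <- region_sim$regions[ri, ]
      cand <- which(!used & genes$chrom == reg$chrom)
      if (!length(cand)) next
      d <- point_interval_distance(genes$tss[cand], reg$start, reg$end)
      cand <- cand[d <= window]; d <- d[d <= window]
      if (!length(cand)) next
      gi <- cand[which.min(d)]
      used[gi] <- TRUE
      x <- signal[ri, ]
      sdx <- stats::sd(x)
      tpm[gi, ] <- pmax(0, 60 + 0.5 * (x - mean(x)) +
                          rnorm(n_t, 0, 0.5 * sdx * noise_scale))
      links[[length(links) + 1L]] <- data.frame(
        region = region_sim$regions$name[ri], gene = genes$gene_id[gi],
        tissue = region_sim$truth$specific_tissue[ri], distance = min(d),
        stringsAsFactors = FALSE)
    }
    list(tpm = tpm,
         links = if (length(links)) do.call(rbind, links)
                 else data.frame(region = character(), gene = character(),
                                 tissue = character(), distance = integer()),
         signal = signal)
  })
}

#' Generate a SNP catalog with one phenotype enriched in planted regions
#'
#' Background phenotypes place SNPs uniformly over the genome. The planted
#' phenotype places each SNP inside the target tissue's planted regions with
#' probability `q1` chosen so the generative odds ratio against the uniform
#' in-region probability equals `planted_or`.
#'
#' @param config a [sim_config()] object.
#' @param region_sim output of [gen_region_counts()].
#' @param n_snps total SNPs in the catalog.
#' @param n_phenotypes number of phenotypes (equal SNP counts each).
#' @param planted_or generative odds ratio for the planted phenotype
#'   (1 = no enrichment).
#' @param target_tissue tissue whose planted regions receive the excess;
#'   defaults to the first tissue with planted regions.
#' @return list with `snps` (data.frame chrom/pos/rsid/phenotype) and `truth`
#'   (planted phenotype, tissue, odds ratio, and the two placement
#'   probabilities).
#' @export
gen_snp_catalog <- function(config, region_sim, n_snps = 10000,
                            n_phenotypes = 10L, planted_or = 10,
                            target_tissue = NULL) {
  validate_sim_config(config)
  if (planted_or < 0) stopf("planted_or must be >= 0")
  truth <- region_sim$truth
  if (is.null(target_tissue)) {
    tt <- truth$specific_tissue[!is.na(truth$specific_tissue)]
    if (!length(tt)) stopf("no planted regions to target")
    target_tissue <- tt[1L]
  }
  target <- region_sim$regions[!is.na(truth$specific_tissue) &
                                 truth$specific_tissue == target_tissue, ,
                               drop = FALSE]
  lens <- config$chrom_lengths
  genome_bp <- sum(lens)
  q0 <- sum(target$end - target$start) / genome_bp
  o0 <- q0 / (1 - q0)
  q1 <- planted_or * o0 / (1 + planted_or * o0)

  # positions are drawn without replacement from flattened coordinate
  # spaces, so (chrom, pos) is unique within each phenotype
  cum <- cumsum(as.numeric(lens))
  global_pos <- function(g) {
    ci <- findInterval(g - 1, c(0, cum), rightmost.closed = FALSE)
    data.frame(chrom = names(lens)[ci],
               pos = as.integer(g - 1 - c(0, cum)[ci]),
               stringsAsFactors = FALSE)
  }
  uniform_pos <- function(n) global_pos(sample.int(genome_bp, n))
  tw <- target$end - target$start
  cumw <- cumsum(as.numeric(tw))
  region_pos <- function(n) {
    g <- sample.int(sum(tw), n)
    ri <- findInterval(g - 1, c(0, cumw), rightmost.closed = FALSE)
    data.frame(chrom = target$chrom[ri],
               pos = as.integer(target$start[ri] + g - 1 - c(0, cumw)[ri]),
               stringsAsFactors = FALSE)
  }
  outside_pos <- function(n) {
    pool <- global_pos(sample.int(genome_bp, min(genome_bp, 4L * n + 1000L)))
    pool <- pool[!overlap_snps(pool, target, quiet = TRUE), , drop = FALSE]
    if (nrow(pool) < n) stopf("target regions cover too much of the genome")
    pool[seq_len(n), , drop = FALSE]
  }
  withr::with_seed(config$seed + 67L, {
    n_per <- n_snps %/% n_phenotypes
    phenos <- sprintf("phenotype_%02d", seq_len(n_phenotypes))
    parts <- lapply(seq_len(n_phenotypes), function(i) {
      if (i == 1L) {
        n_in <- sum(runif(n_per) < q1)
        p <- rbind(if (n_in) region_pos(n_in), outside_pos(n_per - n_in))
      } else {
        p <- uniform_pos(n_per)
      }
      p$phenotype <- phenos[i]
      p
    })
    snps <- do.call(rbind, parts)
    snps$rsid <- sprintf("rs%06d", seq_len(nrow(snps)))
    snps <- snps[, c("chrom", "pos", "rsid", "phenotype")]
    rownames(snps) <- NULL
    list(snps = snps,
         truth = list(phenotype = phenos[1L], tissue = target_tissue,
                      odds_ratio = planted_or, prob_in_null = q0,
                      prob_in_planted = q1))
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator and writes the full on-disk layout consumed by the
#' command-line pipeline: `genome.fa`, `genes.tsv`, `spikein.tsv`,
#' `samples.tsv`, `site_counts.tsv`, `site_truth.tsv`, per-tissue peak BEDs
#' under `peaks/`, `regions.bed`, `region_counts.tsv`, `region_truth.tsv`,
#' `tpm.tsv`, `link_truth.tsv`, `snps.tsv` and `snp_truth.yaml`.
#'
#' @param config a [sim_config()] object.
#' @param outdir output directory (created if needed).
#' @param n_sites,modified_fraction passed to [gen_site_counts()].
#' @param n_regions passed to [gen_region_counts()].
#' @param n_snps,n_phenotypes,planted_or passed to [gen_snp_catalog()].
#' @return invisibly, a list with all in-memory generator outputs.
#' @export
simulate_hmc_dataset <- function(config, outdir, n_sites = 10000,
                                 modified_fraction = 0.2, n_regions = 3000,
                                 n_snps = 10000, n_phenotypes = 10L,
                                 planted_or = 10) {
  validate_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  gg <- gen_genome(config)
  sc <- gen_site_counts(config, gg$genome, n_sites = n_sites,
                        modified_fraction = modified_fraction)
  rc <- gen_region_counts(config, n_regions = n_regions)
  ex <- gen_expression_and_links(config, rc, gg$genes)
  sn <- gen_snp_catalog(config, rc, n_snps = n_snps,
                        n_phenotypes = n_phenotypes, planted_or = planted_or)
  sp <- gen_spikein_counts(config)

  write_fasta(sc$genome, file.path(outdir, "genome.fa"))
  write_gene_models(gg$genes, file.path(outdir, "genes.tsv"))
  write_tsv_table(sp, file.path(outdir, "spikein.tsv"))
  write_tsv_table(rc$samples, file.path(outdir, "samples.tsv"))
  write_site_counts(sc$sites, file.path(outdir, "site_counts.tsv"))
  write_tsv_table(sc$truth, file.path(outdir, "site_truth.tsv"))
  for (t in unique(rc$samples$tissue))
    write_bed(sc$peaks, file.path(outdir, "peaks", paste0(t, ".bed")))
  write_bed(rc$regions, file.path(outdir, "regions.bed"))
  write_count_matrix(rc$counts, file.path(outdir, "region_counts.tsv"))
  write_tsv_table(rc$truth, file.path(outdir, "region_truth.tsv"))
  write_tpm(ex$tpm, file.path(outdir, "tpm.tsv"))
  write_tsv_table(ex$links, file.path(outdir, "link_truth.tsv"))
  write_snps(sn$snps, file.path(outdir, "snps.tsv"))
  yaml::write_yaml(sn$truth, file.path(outdir, "snp_truth.yaml"))
  invisible(list(genome = sc$genome, genes = gg$genes, spikein = sp,
                 sites = sc, regions = rc, expression = ex, snps = sn))
}
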