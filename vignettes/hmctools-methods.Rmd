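---
title: "Statistical methods behind hmctools"
author: "hmctools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind hmctools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmctools)
```

## Overview

hmctools implements the downstream statistics for base-resolution
5-hydroxymethylcytosine (5hmC) sequencing produced by bisulfite-free
chemistry in which 5hmC-derived bases read out as thymines. After alignment,
the data reduce to per-cytosine counts of converted (`NT`) and unconverted
(`NC`) reads per sample. Everything in this package operates on those counts
plus peak intervals, gene models, expression tables and SNP catalogs; it
does not perform alignment, deduplication or peak calling.

The pipeline has five statistical stages:

1. **conversion-rate calibration** from spike-in controls;
2. **single-base 5hmC site calling** with an exact binomial test, Holm
   family-wise error (FWER) control and peak gating, plus sequence-context
   and CpG-symmetry summaries;
3. **tissue-specific differentially hydroxymethylated region (tsDhMR)
   detection** on merged-peak count matrices with median-of-ratios
   normalization and a one-tailed Poisson test under Bonferroni control;
4. **region-to-gene linkage** by Pearson correlation of region signal with
   expression across tissues inside a 500 kb TSS window;
5. **SNP-catalog enrichment** with one-sided Fisher exact tests.

A seeded synthetic-data generator with planted truth accompanies every
stage, so the whole pipeline is validated by truth recovery rather than by
external data.

## Conversion calibration and the site-calling model

A spiked-in model sequence carries cytosines of known modification state.
The conversion rate of each class is the pooled ratio
$\hat p = \sum \mathrm{NT} / \sum(\mathrm{NT}+\mathrm{NC})$ over its sites:
$\hat p_{\mathrm{true}}$ over fully hydroxymethylated spike-in cytosines and
$\hat p_{\mathrm{bg}}$ over unmodified ones. The pooled ratio is the
maximum-likelihood estimate under a shared binomial rate, and the spike-in
is the only calibration substrate the protocol provides; estimation fails
loudly when either class lacks coverage or when
$\hat p_{\mathrm{bg}} \ge \hat p_{\mathrm{true}}$ (failed chemistry).

At a genomic cytosine with depth $N = \mathrm{NT}+\mathrm{NC}$, the null
hypothesis is that all conversions are background noise:
$\mathrm{NT} \sim \mathrm{Binomial}(N, p_{\mathrm{bg}})$. The site p-value
is the exact upper tail $P(X \ge \mathrm{NT})$, evaluated through the
regularized incomplete beta function so that the extreme tails used at
$\alpha = 10^{-3}$ are accurate; values below $10^{-300}$ underflow to zero
and are reported as such.

**Multiplicity and the family definition.** Sites with depth below
`min_depth` (default 5) or fewer than `min_nt` (default 3) converted reads
are discarded from calling, and Holm's step-down procedure controls the
FWER over the remaining tests at level `alpha` (default 0.001). One design
point deserves care: which sites constitute the Holm family. Depth is
ancillary under the null — it carries no information about modification —
so conditioning the family on `N >= min_depth` is valid. The converted
count is not: under a low background rate, conditioning the family on
`NT >= min_nt` selects exactly the sites that already look extreme, which
shrinks the family to a handful of members whose p-values are small by
construction and destroys FWER control. hmctools therefore defines the
family as **all depth-passing sites of a sample**; sites failing the
`min_nt` filter are never tested (their p-value is `NA` and they can never
be called) but still count toward the family size $m$. Untested sites
necessarily occupy the large-p end of the family, so the step-down
multipliers for tested sites are unchanged. With this definition the
pure-null simulation in the test suite (10^4 unmodified sites,
$p_{\mathrm{bg}} = 0.005$, depth $\sim$ 20, 200 replicates) keeps the
frequency of any false call at or below $\alpha$. The family scope is
exposed as `family = "per_sample"` (default) or `"per_tissue"`.

**Peak gating.** A called site must additionally fall inside a 5hmC
enriched peak of its tissue (the union of replicate peak sets). This
mirrors the enrichment step of the chemistry: regions pulled down are where
site-level evidence is interpretable.

**Contexts and symmetry.** Contexts are read off the genome on the site's
own strand: CG when the next base is G, else CHG when the base after next
is G, else CHH (H ∈ {A, C, T}); minus-strand contexts use the reverse
complement. A CpG dyad (plus-strand C at $x$, minus-strand C at $x{+}1$) is
*symmetric* when both strands are called; `symmetry_fraction()` reports the
fraction of symmetric dyads among dyads with at least one called strand,
and `ch_fraction()` the proportion of called sites in non-CG context.

## tsDhMR detection

Per-sample peaks are merged into a single region set (union of
overlapping-or-touching intervals), region read counts are collected into a
region × sample matrix, and sequencing depth is normalized with
median-of-ratios size factors: the reference for each region is the
geometric mean of its counts across samples (regions containing zeros are
excluded from the reference), and a sample's factor is the median ratio of
its counts to the reference. This estimator is implemented directly in the
package and cross-checked in the test suite against an independent
reference implementation. Replicates of a tissue are then merged; the
default aggregation is the **mean** of normalized counts, chosen over the
sum because it keeps the tissue signal on the per-sample scale regardless
of replicate count (the merge mode is a flag).

For each region and tissue, the null rate $\lambda$ is the mean of the
other tissues' merged signal and the p-value is the exact Poisson upper
tail $P(X \ge \mathrm{count})$. Two numerical choices: normalized merged
counts are not integers, so the observed count is **floored** before the
exact tail is evaluated (conservative — flooring can only enlarge the
upper-tail p-value); and $\lambda$ is floored at `lambda_min = 0.5` so that
regions absent from all other tissues cannot produce zero-rate artifacts.
P-values are Bonferroni-adjusted over the full regions × tissues family by
default (`family = "global"`; `"per_tissue"` is available), and a pair is a
tsDhMR when the adjusted p-value is below 0.05 **and** the fold change over
$\lambda$ exceeds 2. Fold change is computed on normalized counts. The
replicate-merged mean is underdispersed relative to a single Poisson draw,
which makes the test conservative on nulls; the fold-change requirement
further ensures that null regions essentially never qualify.

Batch correction is deliberately not applied to the region counts before
testing, and no negative-binomial dispersion is modelled: the test is a
Poisson test by design.

## Region-gene linkage and expression summaries

Candidate links pair a tsDhMR with every gene whose TSS lies within 500 kb
of the region interval. The distance is the base-pair separation between
the TSS and the nearest base of the region (0 inside), and the bound is
closed: a TSS exactly 500,000 bp away is still a candidate. For each pair,
the Pearson correlation $r$ between the region's replicate-merged
normalized signal and the gene's TPM across tissues is tested with the
two-sided t-statistic $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of
freedom (the classical normal-theory test; two-sided because that is the
conventional default, and the one-sided question is subsumed by the
confidence rule). A link is *confident* when $r > 0.8$ and $p < 0.05$.
Constant series are skipped with a warning; p-values are floored at
$10^{-300}$ so a perfect fit remains confident. The same tissue-level
matrix feeds both the Poisson test and the correlations.

Tissue-specific expression lists are computed by: dropping genes with mean
TPM below 1; ranking genes per tissue by fold change over the mean of the
other tissues; taking the top 300; then dropping entries with fold change
below 2. Ranking precedes the fold-change filter (rank-then-filter), so
lists may be shorter than 300. Gene-body 5hmC signal is an RPKM-like
density, `count / (gene length in kb × library size in millions)`, over the
full annotated gene span (a promoter-exclusion variant is a matter of
slicing the inputs; the span definition keeps the default simple), and
`expression_correlation()` compares it to expression with Spearman's rank
correlation by default.

## SNP enrichment

For each phenotype in a catalog, a 2 × 2 table partitions the SNP universe
(all SNPs in the supplied catalog — no external background is assumed) by
phenotype membership and tsDhMR overlap, using half-open interval
semantics. The one-sided (greater) Fisher exact p-value and the sample odds
ratio $(ad)/(bc)$ are reported, with Benjamini–Hochberg adjusted values as
a secondary column. Fisher p-values are discrete: under a fixed table they
are conservative rather than exactly uniform, so the calibration test in
the suite checks one-sided validity under label permutation and judges
two-sided uniformity only on pooled no-enrichment catalogs whose margins
vary. Linkage disequilibrium between SNPs is not modelled; enrichment
p-values should be read accordingly.

## Feature annotation

Gene models induce four genome-partitioning classes with precedence
promoter > exon > intron > intergenic; the promoter is TSS ± 2 kb (clipped
at chromosome ends). Intervals are classified by their midpoint, giving
each query a single label, and enrichment is
$\log_2(\mathrm{observed\ fraction}/\mathrm{genomic\ fraction})$ with
$-\infty$ for empty classes. The precedence order and midpoint rule are
package choices (common annotator behaviour); UTR and TTS classes are
folded into exon/intergenic.

## The synthetic-data generator

`sim_config()` fixes every generative parameter and a seed; all generators
derive independent streams from that seed, so outputs are bit-identical
across runs and generators can be invoked in any order. Defaults describe
the validation conditions used throughout the test suite:

| parameter | default | meaning |
|---|---|---|
| `p_true` | 0.9 | conversion at true 5hmC sites |
| `p_bg` | 0.005 | background conversion |
| `depth_mean` | 20 | per-site coverage, Poisson truncated ≥ 1 |
| `base_lambda` | 50 | region count mean in non-specific tissues |
| `planted_fc` | 5 | fold change of planted regions |
| `planted_ts_fraction` | 1/3 | fraction of regions planted tissue-specific |
| `n_tissues` × reps | 8 × 2 | sample layout |
| `link_r` | 0.95 | generative Pearson r of planted links |
| `cg_fraction` | 0.98 | modified sites in CG context |
| `symmetric_fraction` | 0.13 | modified CpG dyads modified on both strands |

Design notes, chosen once and not tuned:

* **Coverage** is truncated Poisson — the simplest model matching the
  caller's binomial assumption, with no overdispersion.
* **Size factors** are log-uniform on [0.5, 2], enough to exercise
  normalization without extreme imbalance.
* **Planted regions are specific to exactly one tissue**, matching the
  one-vs-rest test; the planted count is exact
  (`floor(n_regions × planted_ts_fraction)`) with tissues assigned
  cyclically.
* **Contexts are planted into the genome sequence** so that
  `classify_context()` reproduces the configured labels; the base-site CH
  probability is set to `ch(1+s)/(1+ch·s)` (with `ch = 1 − cg_fraction`,
  `s = symmetric_fraction`) so that after symmetric minus-strand partners
  are added, the *emitted* CH fraction has expectation `1 − cg_fraction`.
* **Planted links** transform the realized region signal affinely and add
  Gaussian noise with standard deviation
  $b\,\sigma_x\sqrt{1/r^2 - 1}$, making the expected Pearson correlation
  equal `link_r`; unlinked genes draw tissue-independent TPM.
* **SNP catalogs** draw positions without replacement from flattened
  coordinate spaces (so positions are unique within a phenotype); the
  planted phenotype's inside-region probability solves
  $\mathrm{odds}(q_1) = \mathrm{OR} \times \mathrm{odds}(q_0)$ for a known
  generative odds ratio.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: realistic base composition or CpG density, read-level
error profiles, overdispersed biological replicate variance,
linkage-disequilibrium structure among SNPs, and correlated co-regulation
beyond single planted links. Same-tissue planted regions share the same
tissue-indicator pattern by construction, so cross-correlations between a
planted region and another same-tissue region's target gene are genuine in
the generative model; spurious-link checks therefore count only
generator-independent pairs.

## Validation problem sizes

The test suite validates: exact tails against brute-force summation
(binomial N ≤ 50, Poisson λ ≤ 50 with counts to 200, Fisher totals ≤ 500,
all to 1e-10 relative error); Holm/Bonferroni against their literal
definitions on 1000 random vectors; FWER control over 200 pure-null
replicates for both callers; site-caller recovery on 10^4 sites (20%
modified); tsDhMR recovery over 20 seeds of 3000 regions × 16 samples;
linkage recovery over 20 seeds of a sparse 16-tissue layout plus a 10^4
permutation check of the correlation p-value at n = 8; SNP enrichment over
20 seeds of 10^4-SNP catalogs; and an end-to-end run of the command-line
pipeline on the default configuration. These sizes make the whole suite
run in a few minutes on a single CPU while keeping every sampling
tolerance well inside the asserted bounds.

## Known limitations

* The binomial site model assumes a single genome-wide background rate;
  sequence-dependent background variation is not modelled.
* Per-site stoichiometry (the hydroxymethylation *level*) is not
  estimated — the caller is a detector, not a quantifier.
* The Poisson region test ignores replicate overdispersion; with few,
  noisy replicates the Bonferroni + fold-change combination relies on the
  fold-change filter for practical specificity.
* Enrichment tests treat SNPs as exchangeable points; LD pruning and
  matched backgrounds are out of scope.
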