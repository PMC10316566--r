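---
title: "Methods: quantifying DEG recapitulation under cell and read downsampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DEG recapitulation under cell and read downsampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Single-cell RNA-seq clusters range from a few dozen to several thousand
cells, and it is not obvious when a cluster is large enough to identify
differentially expressed genes (DEGs) robustly. `degrecap` treats deep
bulk RNA-seq of purified populations as the reference and asks, on data
with known ground truth: what fraction of the bulk-reference DEG set is
recapitulated when the same comparison is run on single-cell data — as a
function of the number of cells, of sequencing depth, and of the DEGs'
own characteristics (p-value, fold change, transcript abundance)?

The package implements the whole chain as testable units: a paired
bulk/single-cell simulator with gene-level ground truth, preprocessing
(cell filtering, pseudo-bulk aggregation, TPM, log-normalization), two
DE procedures, the two down-sampling axes, and the evaluation grid.

# The generative model

The simulator (`simulation_config()`, `simulate_paired_experiment()`)
emulates a two-cell-type design in which each of 3 biological replicates
(differentiation rounds) is split into a single-cell library and a bulk
library per type. Its hierarchy:

* Gene relative abundances $r_g$ are log-normal (`meanlog = 1`,
  `sdlog = 2`), giving the heavy-tailed TPM distribution typical of
  transcriptomes. A fraction `frac_de` of genes (default 0.3) carries a
  true log2 fold change of type B over A, drawn from a random-sign
  mixture of modest (uniform 0.5–2) and large (uniform 2–6) effects —
  both regimes matter, because recapitulation behaves very differently
  for them.
* Each replicate $t$ has a shared, gene-wise log-normal perturbation
  (`replicate_noise_sd = 0.1`, natural-log scale, mean-corrected). It is
  shared by both cell types and both assays of the round: one harvest
  feeds all of them. This matters twice over — it makes bulk and
  single-cell data of a round genuinely paired, and it keeps the two
  pooled cell populations exchangeable for non-DE genes, so a global
  null simulation is actually null for the pooled-cell Wilcoxon test.
* Single-cell counts are negative binomial with
  $\mu_{gc} = L_c \, \pi_{gtr}$, where $L_c$ is the cell's expected
  total (log-normal, median 8,000 counts, `sdlog = 0.35`, a typical 10x
  3' v3.1 scale) and $\pi$ the perturbed relative abundance. Per-gene
  dispersions follow the decreasing trend
  $\alpha_g = (0.2 + 1/m_g)\,e_g$ with $m_g$ the expected per-cell
  count and $e_g$ mean-one log-normal scatter (`sdlog = 0.3`). Dropout
  is implicit in low NB means at shallow per-cell depth; no separate
  zero-inflation parameter is used, which is adequate for 10x-style UMI
  data.
* Bulk counts are NB at `bulk_depth` (default 1.1e8, so thinning to a
  1e8 reference is always feasible) around the same perturbed means,
  with a small technical dispersion (0.005); the biological
  replicate-to-replicate variance enters through the shared
  perturbation, not this dispersion.

`base_mean` in the ground-truth table is the expected type-A count per
bulk replicate at `bulk_depth` — the scale on which abundance-dependent
statements ("genes with base mean above 50") are meaningful.

Because sequencing measures relative abundance, fold changes act on
composition: with strongly asymmetric effect signs, median-of-ratios
normalization re-anchors on the median gene and all estimates shift by
the composition factor. This is faithful to real data (the same happens
in any DESeq2 analysis); simulations used for effect-size recovery
therefore use sign-balanced effects.

What the simulator does *not* emulate: ambient RNA, doublets, UMI
collisions, 3'-coverage bias, batch effects beyond the replicate
perturbation, and cell-type-specific library-size differences. Passing
tests demonstrate the pipeline's statistical behavior under the stated
NB hierarchy, not robustness to those artifacts.

# The two DE procedures

## NB Wald test on replicate counts (`nb_wald_test()`)

A self-contained DESeq2-style test for bulk and pseudo-bulk tables:

1. **Size factors** by median-of-ratios (`size_factors_median_of_ratios()`):
   reference = per-gene geometric mean over columns, computed on genes
   positive everywhere; factor = median ratio.
2. **Dispersion** per gene by method of moments on normalized counts,
   $\hat\alpha = (v - \bar{s^{-1}} m)/m^2$, floored at $10^{-8}$, with a
   parametric trend $\alpha(m) = a_0 + a_1/m$ fitted by an iterated
   Gamma GLM. The dispersion used is the **maximum** of the gene-wise
   estimate and the trend: with three replicates per group a gene-wise
   estimate *below* the trend is far more often an underestimate than a
   genuinely quiet gene, and underestimated dispersions inflate the Wald
   statistic's far tail badly enough to break BH control under a global
   null. Taking the maximum is the package's deliberately conservative
   substitute for full shrinkage machinery.
3. **Per-group NB rate MLE** with offset $\log s_j$, solved by a
   vectorized Newton iteration on $\eta = \log q$ (concave; exact for
   the saturated two-group design). A group whose counts are all zero
   receives half a count so the statistic stays finite.
4. **Wald test**: $\hat\beta = \eta_B - \eta_A$,
   $\mathrm{SE} = \sqrt{I_A^{-1} + I_B^{-1}}$ with
   $I = \sum_j \mu_j/(1+\alpha\mu_j)$, two-sided normal p;
   `log2fc` $= \hat\beta/\ln 2$. Genes with all-zero counts get `NA`
   and are excluded from the adjustment's $m$.

Omitted relative to the full DESeq2 procedure, deliberately and
documented: Cox–Reid adjusted-profile dispersion shrinkage, LFC
shrinkage, independent filtering, and Cook's-distance outlier handling.
Results are "NB Wald (DESeq2-style)", never "DESeq2".

## Wilcoxon rank-sum on log-normalized cells (`wilcoxon_rank_sum()`)

The marker-test path: per gene, a two-sided rank-sum test of
log-normalized expression (`log_normalize()`: natural
$\ln(1 + 10^4\,\mathrm{count}/\mathrm{total})$) between the pooled cells
of the two types, with midranks for ties and the normal approximation
with tie-corrected variance and continuity correction — the standard
large-sample path. The implementation exploits sparsity (zeros are one
tied block), matches `stats::wilcox.test(exact = FALSE)` to numerical
precision, and stays within 0.02 of exact enumeration when both groups
have at least 5 members (the worst case grows to about 0.04 for very
small groups at mid-range p; DEG calling at $\alpha = 0.05$ is
unaffected). The reported fold change is
$\log_2\frac{\mathrm{mean}(\mathrm{expm1}(x_B)) + 1}{\mathrm{mean}(\mathrm{expm1}(x_A)) + 1}$ —
pseudocount 1 on the depth-normalized scale, which downstream
fold-change quartiles depend on. The prefilters `logfc_threshold` and
`min_pct` default to 0 (every gene tested), matching the evaluation's
need to compare against bulk over the full gene universe.

Both tests report BH and Bonferroni adjustments; DEG calls use adjusted
$p \le \alpha$ (inclusive, default 0.05).

# Down-sampling axes

* **Cells** (`subsample_cells()`): without-replacement sampling of
  `round(fraction * n)` cells, stratified per replicate library,
  repeated (default 3 times) per level; default grid 100% down to 1%.
  Cell filtering (inclusive 200–5,000 detected genes,
  `filter_cells()`) is applied once, before subsampling.
* **Reads** (`thin_reads()`): count-level image of without-replacement
  read subsampling — per column a multivariate hypergeometric draw
  hitting the target total exactly (sequentially conditioned univariate
  hypergeometrics). Default grid 100M down to 5M read pairs, the first
  level acting as the reference of that axis.

All randomness derives from one root seed through a documented
string-hash stream split (`derive_seed()`), so extending a grid never
perturbs existing draws, and identical configuration plus seed yields
byte-identical reports.

# The evaluation grid

`run_full_evaluation()` fixes the reference as NB Wald + BH on the full
bulk data, then for every cell fraction and repeat runs (a) pseudo-bulk
(cell type × replicate library, i.e. 3 samples per type) through the NB
test with BH and (b) the Wilcoxon test with BH and, separately,
Bonferroni (the latter reported because it is the common default in
single-cell toolkits). Per combination it reports DEG counts, overlap,
recapitulation rate, test-unique DEGs, quartile-stratified rates (by
reference p ascending, |log2FC| descending, TPM descending; ties broken
by gene ID), the modest-DEG rate, and Spearman correlations of p-values
and abundance profiles.

Decisions worth knowing:

* The p-value correlation is computed over the *reference DEG set*, with
  missing/untested test-side p-values set to 1 — keeping the gene set
  fixed across fractions so correlations are comparable.
* Quartiles are computed on the reference DEG set only, not all genes.
* The modest-DEG subset uses inclusive interval bounds (defaults:
  unadjusted p in [3.1e-5, 0.025], BH p in [1e-4, 0.05], |log2FC| in
  [0.5, 2] — roughly 1.4- to 4-fold).
* TPM (`tpm()`) uses full gene lengths for both bulk and pseudo-bulk;
  3'-biased single-cell protocols violate the length assumption, so
  pseudo-bulk TPM is comparable across genes only approximately. The
  same length table is used on both sides so the comparison is at least
  internally consistent.
* Abundance correlations follow the rule that genes undetected in one
  profile enter at 0 TPM, and are Spearman on $\log_2(\mathrm{TPM}+1)$.

# Numerical choices and degenerate inputs

* Dispersion floor $10^{-8}$ (Poisson limit); trend fit falls back to
  the median gene-wise estimate when fewer than 10 stable genes exist.
* Newton steps are clamped to ±5 on the log scale; convergence tolerance
  $10^{-10}$.
* Constant genes get p = 1 in the Wilcoxon test; all-zero genes get
  `NA` in the NB test and are excluded from $m$.
* TPM errors on all-zero columns; log-normalization errors on zero-total
  cells; quartiles require at least 4 reference DEGs; recapitulation
  errors on an empty reference set.
* Quartile membership uses `ceiling(rank * 4 / n)`, which splits
  non-divisible sizes as evenly as possible with the earlier quartiles
  never smaller than later ones by more than one gene.

# Problem sizes used by the shipped checks

The package's own acceptance checks run at the study's conditions where
that is meaningful: the monotonicity check uses 10,000 genes and 5,000
cells per type with 30% DE genes at mixed effect sizes, fractions
{100%, 20%, 4%, 1%} with 3 repeats; null calibration uses 2,000 genes
and 500 cells per type over 5 seeds; effect-size recovery uses 3,000
genes at bulk depth $10^7$. The standalone summary script
(`scripts/acceptance.R`) uses 6,000 genes and 3,000 cells per type with
a 20-fold bulk-depth thinning range — a size chosen to exercise every
stage at realistic sparsity while remaining quick on one CPU.

# Known limitations

* The NB test's normal Wald reference with 3 + 3 samples is kept honest
  by the conservative dispersion rule; power is somewhat below what
  full shrinkage machinery would give, so absolute recapitulation rates
  are conservative, while orderings across fractions and quartiles —
  the quantities of interest — are unaffected.
* The pooled-cell Wilcoxon treats cells as independent; with real
  replicate structure it is anticonservative for genes with strong
  between-replicate variation that is *not* shared across types. The
  simulator's shared-round design does not probe that failure mode.
* Recapitulation measures agreement with bulk, not truth: test-unique
  DEGs are counted and reported but not adjudicated.
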