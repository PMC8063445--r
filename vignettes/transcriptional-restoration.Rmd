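---
title: "Scoring transcriptional restoration toward a healthy baseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring transcriptional restoration toward a healthy baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txrestore)
```

## The question the package answers

Given bulk expression profiles from a healthy baseline group (e.g. wild-type
littermates), a disease group (e.g. a TNF-transgenic arthritis model), and
one or more treatment arms, `txrestore` quantifies *restoration*: how far
each treatment moves the transcriptome back toward the healthy state, which
co-regulated gene clusters it restores, and which functional categories it
fixes without disturbing the healthy program. The package takes normalized
log2 intensities as given — array or pseudo-bulk normalization is upstream
and out of scope — and treats gene identifiers as opaque strings.

## The statistical model

### Differential expression

For a contrast of groups $A$ vs $B$ the effect per gene $g$ is
$\mathrm{logFC}_g = \bar{x}_{gA} - \bar{x}_{gB}$ (log2 units; the second
argument is always the reference). Two statistics are offered:

* **ordinary**: pooled-variance two-sample $t$ on
  $d = n_A + n_B - 2$ degrees of freedom;
* **moderated** (default): empirical-Bayes variance shrinkage. With sample
  variances $s_g^2$ on $d$ df, the prior $(d_0, s_0^2)$ is estimated by
  matching the mean and variance of $\log s_g^2$ to a scaled-F model:
  $\operatorname{Var}[\log s_g^2] - \psi'(d/2)$ is inverted through the
  trigamma function (Newton iteration, tolerance $10^{-10}$) to give
  $d_0$, and the mean equation gives $s_0^2$. The posterior variance
  $\tilde{s}_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ yields
  $\tilde{t}_g = \mathrm{logFC}_g / (\tilde{s}_g \sqrt{1/n_A + 1/n_B})$ on
  $d_0 + d$ df.

The moderated statistic is the field default for $n = 3$ arrays per group:
with 4 residual df, per-gene variances are too unstable for the ordinary
$t$. When the excess variance of $\log s_g^2$ is non-positive (e.g. truly
homoscedastic data) the fit degenerates gracefully to $d_0 = \infty$,
i.e. one shared variance — the limiting closed form
$\tilde{t} = \mathrm{logFC}/(s_0\sqrt{1/n_A + 1/n_B})$. The test suite
cross-checks the whole fit against `limma::eBayes` on heteroscedastic
simulations; the implementation itself is self-contained.

Degenerate genes: in ordinary mode a gene with zero pooled variance gets
$t = 0, p = 1$ when its logFC is also 0 (identical groups); when its logFC
is non-zero the ordinary statistic is undefined and the gene falls back to
the moderated one, with a classed warning counting how many genes were
affected. Genes with $s_g^2 = 0$ never enter the prior fit but do receive
the moderated variance.

Multiple testing uses Benjamini–Hochberg step-up FDR (`stats::p.adjust`),
applied **per contrast**: whether the original analyses adjusted per contrast
or globally is not derivable from the inputs, and per-contrast adjustment
keeps every contrast self-contained. "Adjusted p" throughout means BH FDR —
the convention for array differential expression.

### Signature selection

The disease signature is $\{g : |\mathrm{logFC}_g| \ge 1,\;
\mathrm{adj\_p}_g \le 0.05\}$ on the disease-vs-baseline contrast; both
boundaries are **inclusive**, and both thresholds are exposed as parameters.
The extended altered set is the union of the same filter across the disease
and every treatment contrast vs baseline. Which contrast list to union over
(vs-WT only, or also vs-disease) is a genuinely open choice; the function
takes an explicit contrast list so either reading can be expressed, and the
pipeline default uses the vs-WT contrasts.

### Ward clustering

Signature genes are clustered on their raw logFC-vs-WT row vectors across all
conditions, Euclidean geometry, Ward objective (minimum increase in
within-cluster sum of squares), via `stats::hclust(method = "ward.D2")` —
heights on the distance scale, i.e. the square root of the merged criterion.
The convention matters only for heights; the partition at fixed $k$ is
convention-independent, which is what the pipeline consumes. Defaults
$k = 6$ for genes and $k = 3$ for categories are analysis choices, not
data-driven estimates, and are plain parameters. Labels are canonicalized
(1..k by decreasing size, ties by smallest member row index) so partitions
are invariant to input row order; the test suite checks the partitions
against a brute-force agglomerator that recomputes the Ward criterion from
scratch at every merge. Rows are *not* standardized before clustering by
default — logFC values are already on a common scale, and standardizing a
row would erase the magnitude information that distinguishes strongly from
weakly perturbed genes — but a `standardize` flag is provided.

### Distance from health and efficiency scores

A gene group's distance from health under a condition is the mean of
$|\mathrm{logFC}|$ vs baseline over its members — absolute values, because
up- and down-regulated genes must not cancel. The "all" row is exactly the
size-weighted mean of the cluster rows (tested to $10^{-12}$).

For a functional category $C$ and treatment $T$:

$$\mathrm{score}(C, T) = \log_{10}
  \frac{\max(\mathrm{mean}_{g \in C}\,|\mathrm{logFC}_{T\,vs\,disease}(g)|,\ \varepsilon)}
       {\max(\mathrm{mean}_{g \in C}\,|\mathrm{logFC}_{T\,vs\,WT}(g)|,\ \varepsilon)}$$

Both "mean logFC" quantities are means of **absolute** values: with signed
means, categories containing both up- and down-regulated genes would score
near zero regardless of restoration, making "effective recovery without
disrupting the healthy state" unreadable from the score; the distance
analysis above already fixes the absolute-value convention. The floor
$\varepsilon = 0.01$ log2 units (configurable) keeps the ratio defined when a
treatment coincides exactly with a baseline, bounds scores to
$\pm\log_{10}(\text{max displacement}/\varepsilon)$, and is flagged per cell
when it fires. Contrasts vs disease are computed directly as
treatment-vs-disease group contrasts, not as differences of vs-WT logFCs:
the direct contrast has the correct replicate variance, and the two agree in
expectation. Categories are intersected with a **shared** gene universe (the
extended altered set by default) and dropped below `min_set_size = 5`
surviving members, since a mean over fewer genes is dominated by single-gene
noise. A category "passes" when its score exceeds 1 (a 10-fold displacement
ratio) for at least one treatment; passing categories are Ward-clustered on
their score vectors.

Useful identities (all tested): multiplying every vs-disease logFC by 10
raises unfloored scores by exactly 1; swapping the two contrast sets negates
unfloored scores; the filter is monotone in scores.

## The synthetic-data generator

`simulate_expression()` emulates the structure of a small-n expression study
so the whole pipeline is testable with known ground truth:

* gene baselines $b_g \sim N(7, 2^2)$ log2 units — typical array intensity
  spread;
* a fraction (default 0.1) of genes are disease-perturbed with
  $|\delta_g| \sim U(1, 3)$ log2 units, upward with probability 0.5 —
  magnitudes at or above the signature threshold, as a disease signature is
  defined to be;
* each treatment restores each disease gene **all-or-none** with its
  restoration fraction (defaults 0.4 / 0.6 / 0.9, a weak and a moderate
  monotherapy plus a strong combination); all-or-none keeps cluster-level
  ground truth crisp, and a `restored_residual` multiplier (off by default)
  expresses partial restoration when wanted;
* off-target effects (default 2% of non-disease genes at ±1.5 log2 units per
  treatment) reproduce the phenomenon that treatments also alter genes
  outside the disease signature — with them on, the extended altered set is
  strictly larger than the disease signature;
* replicate noise is Gaussian on the log2 scale, sd 0.25 by default,
  homoscedastic; a scaled inverse-chi-square option (`noise_df`) makes
  per-gene variances heterogeneous to exercise variance moderation;
* $n = 3$ replicates per group, matching the usual design of such studies;
* one integer seed drives all draws in a fixed documented order (baselines,
  disease assignment, effects, per-treatment flags in treatment order,
  noise), so output is byte-reproducible.

What it does **not** emulate: probe-level structure, batch or hybridization
effects, intensity-dependent variance, correlated gene modules beyond the
shared disease effect, and count-based (RNA-seq) sampling noise. Passing
tests therefore demonstrate correctness of the algorithms under the stated
model, not robustness to those artifacts; on real data the usual upstream QC
and normalization still matter.

`simulate_gene_sets()` draws categories by weighted sampling without
replacement, disease genes upweighted by a configurable odds multiplier, so
category-level scoring has real enriched categories to find; with multiplier
1 the per-set disease fraction matches the global fraction (binomially
tested).

## Numerical and engineering choices

* Missing values in the expression matrix are a hard error, never imputed:
  downstream statistics stay deterministic functions of the input file.
* All result tables are TSV with headers, written at full float precision
  (round-trip well under $10^{-9}$).
* p-values are clamped to $(0, 1]$ at the double-precision floor so BH input
  invariants hold exactly.
* The pipeline draws no random numbers; its manifest records a SHA-256
  checksum per output, so determinism is checkable byte-for-byte. On any
  stage failure, partial outputs are removed and the error names the stage.
* Agglomeration tie-breaks follow `stats::hclust`; labels are canonicalized
  afterward, and the brute-force oracle comparisons run on continuous random
  data where ties have probability zero.

## Problem sizes in the tests

The test suite validates calibration and recovery at sizes chosen to give
stable averages while keeping a full run fast: the null calibration uses
20 studies of 10,000 genes ($3+3$ replicates); signature recovery uses 10
studies of 2,000 genes at noise sd 0.25 and effects $\ge 1.5$; restoration
monotonicity averages 20 studies of 800 genes with restoration fractions
0 / 0.5 / 1; oracle equivalence uses 200 random Ward instances
($n \le 15$) and 1,000 random BH vectors. The same computations, seeded from
the command line, are what `scripts/acceptance.R` reports.

## Known limitations

* Two published headline counts (an 867-gene disease signature and a
  3733-gene extended set) depend on the original study's deposited
  differential-expression tables, which are too large to redistribute here;
  the counting rule is implemented and fully tested on synthetic data, and
  the corresponding checks run only where a user supplies the deposited
  tables under `inst/extdata/published_de_vs_wt/`.
* Single-factor contrasts only: no batch covariates or multi-factor linear
  models.
* No enrichment statistics (hypergeometric/GSEA) — the efficiency score is a
  displacement ratio, not a significance test — and no redundancy reduction
  over overlapping categories.
* $k$ is user-chosen; no gap/silhouette selection is attempted.
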