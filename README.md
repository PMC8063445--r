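# txrestore

Quantifying how well drug treatments restore a diseased transcriptome to the
healthy state.

## The problem

In preclinical disease models — the motivating case is TNF-driven arthritis in
transgenic mice, with wild-type (WT) littermates as the healthy baseline and
one or more drug arms (two monotherapies and a combination) — a natural
question is not just *which genes does a treatment change*, but *how far does
each treatment move the diseased transcriptome back toward health, and which
biological functions does it fix without disturbing*. `txrestore` implements
that analysis as a deterministic, tested pipeline over a normalized log2
expression matrix, a sample sheet, and (optionally) gene sets in GMT format.

The method, for groups WT (healthy), TG (disease) and treatments T:

1. **Differential expression.** For any contrast A vs B, per gene:
   `logFC = mean(A) − mean(B)` (log2 units) with an ordinary pooled t or an
   empirical-Bayes **moderated t** — the posterior variance
   `s̃²_g = (d₀s₀² + d·s²_g)/(d₀ + d)` with `(d₀, s₀²)` fitted by matching the
   first two moments of `log s²_g` to a scaled-F prior — and
   Benjamini–Hochberg adjusted p-values. The moderated t is the standard
   choice at n = 3 replicates per group.
2. **Disease signature.** Genes with `|logFC| ≥ 1` and `adj_p ≤ 0.05`
   (inclusive boundaries) in the TG-vs-WT contrast; the **extended altered
   set** is the union of that filter over disease and all treatment
   contrasts vs WT.
3. **Restoration clustering.** Signature genes are clustered on their
   logFC-vs-WT profiles across all conditions with **Ward agglomerative
   clustering** (ward.D2 convention, k = 6 by default), and each cluster's
   **distance from health** is its mean |logFC| vs WT per condition —
   0 means indistinguishable from the healthy state.
4. **Treatment-efficiency scores.** Each gene-set category C (GO/KEGG/TF
   targets, intersected with the extended set) gets, per treatment T,

   `score(C, T) = log10( mean_C |logFC(T vs TG)| / mean_C |logFC(T vs WT)| )`

   with both means floored at ε = 0.01: positive when the treatment moves
   category genes away from the disease state further than it leaves them
   displaced from health. Categories with score > 1 for at least one
   treatment are kept and Ward-clustered (k = 3) into treatment-specific
   groups.

A seeded synthetic-data generator (`simulate_expression()`,
`simulate_gene_sets()`) produces studies with known ground truth — disease
effect sizes, per-treatment restoration fractions, off-target perturbations —
so every stage is testable without any external download.

## Worked example

```r
library(txrestore)

sim <- simulate_expression(sim_config(n_genes = 1000, seed = 42))
de  <- compute_contrast(sim$expression, sim$design, "TG", "WT")
glance(de)
#> # A tibble: 1 × 6
#>   contrast_id moderation n_genes n_sig_05 df_prior s2_prior
#> 1 TG_vs_WT    moderated     1000      104      Inf   0.0628

sig <- select_signature(de)           # |logFC| >= 1 & adj_p <= 0.05
#> <signature 'TG_vs_WT'> 94 genes (|logFC| >= 1, adj_p <= 0.05) from: TG_vs_WT

vs_wt <- lapply(setNames(nm = c("TG", treatment_groups(sim$design))),
                function(g) compute_contrast(sim$expression, sim$design, g, "WT"))
prof <- build_profile(unname(vs_wt), sig)
cl   <- ward_cluster(prof, k = 6)
#> <ward clustering> 94 items in 6 clusters (sizes: 26, 21, 16, 14, 12, 5)

distance_report(prof, cl)   # overall row, conditions as columns:
#>   TG_vs_WT DRUG_A_vs_WT DRUG_B_vs_WT COMBO_vs_WT
#> 1     2.11         1.10        0.787       0.429
```

The untreated disease group sits 2.11 log2 units (mean |logFC|) from healthy;
the monotherapies close roughly half of that distance and the combination
(restoration fraction 0.9 in the simulated ground truth) comes within 0.43 —
the noise floor plus its unrestored residue. `plot_profile_heatmap(prof, cl)`,
`autoplot(cl)` and `autoplot(distance_report(prof, cl))` draw the
corresponding heatmap, dendrogram and distance profile, and
`efficiency_scores()` then ranks functional categories per treatment (in the
same run, the top combination-therapy categories score ≈ 1.2, i.e. a 15-fold
displacement ratio, e.g. SET0004: 1.97 log2 units from disease vs 0.13 from
healthy).

The whole analysis runs from one config:

```r
run_pipeline(pipeline_config("expression.tsv", "design.tsv", out_dir = "out",
                             baseline_group = "WT", disease_group = "TG",
                             gmt = "sets.gmt"))
```

writing the DE tables, signature and extended set, profile, clusters,
distances, efficiency table, overlap counts and a `manifest.json` with a
SHA-256 checksum per output (two runs with the same inputs are
byte-identical). A thin command-line wrapper with `simulate` and `run`
subcommands is installed at `inst/scripts/txrestore.R`.

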