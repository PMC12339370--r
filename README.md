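# trfam

Family-level analysis of serum tRNA fragments (tRFs) for prenatal-stress
cohort studies.

## What it does, and for whom

tRFs are 16–50 nt cleavage products of nuclear- and mitochondrially encoded
tRNAs. In serum small-RNA sequencing of mother–newborn cohorts, individual
tRFs are weak, noisy markers — but fragments sharing a **genome origin**
(Nuc/MT), a **parental tRNA amino acid**, and a **cleavage type** (5′-tRF,
5′-half, i-tRF, 3′-half, 3′-tRF) are co-produced by the same nucleases and
tend to shift together. `trfam` is for analysts who want to test that
*family-level* coherence directly.

The core statistic: within a family, count the members whose stress-vs-control
log2 fold change is negative, `k` out of `n` informative members, and test
`k ~ Binomial(n, 1/2)` with the exact two-sided binomial test,

    p = min(1, 2 * min(P(X <= k), P(X >= k))),

Benjamini–Hochberg-corrected across families. A family is called *down*
(or *up*) when FDR ≤ 0.05 and more than (less than) half its members
decrease. The same machinery runs at coarser grouping (all-MT, per
cleavage type, per amino acid).

Around that core, the package provides the full pipeline:

* prefiltering, median-of-ratios size factors, and a simplified
  negative-binomial Wald DE stage (vectorised IRLS; externally produced DE
  tables can be slotted in via `read_de_table()`);
* fragment-length profiles per group and Kruskal–Wallis tests of
  expression-weighted family length across the four stress-by-sex groups;
* weighted cholinergic target scoring over prediction tables (core genes
  weigh 5, peripheral 1; an RNA is a "CholinotRF"/"CholinomiR" iff it has
  ≥ 1 core or ≥ 5 peripheral qualifying targets), with Fisher and
  hypergeometric enrichment;
* SVM classification of stress status from marker sets with leave-one-out
  cross-validation, ROC/AUC, and permutation-calibrated p-values;
* Ellman-assay cholinesterase kinetics: OLS slopes of 21-cycle absorbance
  traces under selective inhibitors (iso-OMPA → AChE, BW284c51 → BChE),
  IQR outlier handling, Mann–Whitney / Wilcoxon group and dyad statistics;
* a seeded synthetic-cohort generator reproducing the study design
  (groups 6/8/11/10, 45 families / 565 fragments, planted family trends,
  prediction tables, kinetic traces) with truth tables for validation.

## Worked example

```r
library(trfam)

catalog <- simulate_catalog(n_families = 45, n_trfs = 565, seed = 7)
index   <- build_family_index(catalog)
index
#> family_index: 565 fragments in 45 families (42 testable, min_size = 2)

# plant a down-trend (90% of members, |log2FC| = 1) in one large family
big <- index$families$family[index$families$size >= 40][1]   # "Nuc-Lys-3p-tRF"
sim <- simulate_counts(catalog, cohort_design(),
                       effect_spec(big, fraction_down = 0.9, log2fc = 1),
                       seed = 8)

keep  <- prefilter(sim$counts, smallest_group_size = 6)
de    <- nb_wald_de(sim$counts[keep, ], sim$metadata, subgroup = "all")
trend <- family_trend_table(de, build_family_index(catalog[catalog$id %in% keep, ]))
head(trend[order(trend$padj), c("family", "n", "k_down", "prop_down",
                                "pvalue", "padj", "direction")], 3)
#>            family  n k_down prop_down   pvalue     padj direction
#> 16 Nuc-Lys-3p-tRF 60     57    0.9500 6.25e-14 2.63e-12      down
#> 42  MT-Ser-5p-tRF 46     12    0.2609 1.64e-03 3.45e-02        up
#> 21 Nuc-Thr-3p-tRF 19      3    0.1579 4.43e-03 6.20e-02      none
```

The planted family is recovered decisively: 57 of its 60 informative
members move down (FDR 2.6e-12). The weak "up" call in the second row is a
side effect worth knowing about: the planted family is ~11% of the whole
matrix, and median-of-ratios normalisation redistributes part of such a
dense shift onto the remaining features. Planted effects in a small
fraction of features do not show this.

The full pipeline — DE in all three contrasts, family and super-family
trends, length analysis, cholinergic scoring, classification, kinetics —
runs from one YAML config:

```r
paths <- simulate_study("study_dir", seed = 1)
cfg <- load_config(overrides = list(
  seed = 1,
  inputs = paths[c("counts", "metadata", "annotations",
                   "predictions", "gene_list", "kinetics")],
  classifier = list(B = 199L),
  output_dir = "study_out"))
run_pipeline(cfg)
```

which writes per-stage TSVs plus a `manifest.json` echoing every threshold
and seed; reruns with the same config and seed are byte-identical. A thin
command-line wrapper (`inst/cli/trfam.R`) exposes `simulate`, `validate`
and `run` subcommands.

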