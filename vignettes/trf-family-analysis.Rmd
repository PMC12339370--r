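---
title: "Family-level analysis of serum tRNA fragments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-level analysis of serum tRNA fragments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfam)
```

## The problem

Serum short-RNA sequencing of mother–newborn dyads can reveal molecular
correlates of maternal prenatal stress, but individual tRNA fragments (tRFs)
are noisy, sparse markers in cohorts of a few dozen samples. tRFs are 16–50
nt cleavage products of nuclear- and mitochondrially encoded tRNAs, and
fragments sharing a genome origin, a parental amino acid, and a cleavage
type are produced by the same nucleases from near-identical substrates. They
therefore tend to move together. `trfam` analyses such data at the *family*
level — the (origin, amino acid, cleavage type) triple — where a coherent
directional shift across many weak members is detectable even when almost no
single member passes a differential-expression threshold.

The package implements the full analysis chain: catalog and family indexing,
a simplified negative-binomial Wald differential-expression (DE) stage,
the exact binomial family-trend test, fragment-length profiling, weighted
cholinergic target scoring ("CholinotRF"/"CholinomiR" designation), SVM
classification of stress status with leave-one-out cross-validation (LOOCV)
and permutation-calibrated significance, and Ellman-assay cholinesterase
kinetics. A seeded synthetic-cohort generator reproduces the statistical
structure of the study design so that every stage is testable end to end.

## The family trend statistic

For one contrast (stress vs. control), the DE stage gives each fragment a
log2 fold change. Within a family, let $n$ be the number of members with a
finite, nonzero log2 fold change and $k$ the number moving down. Under the
null hypothesis that member directions are independent fair coin flips,
$k \sim \mathrm{Binomial}(n, 1/2)$. The two-sided p-value uses the central
method,

$$p = \min\{1,\; 2\min(P(X \le k),\, P(X \ge k))\},$$

which for the symmetric null coincides with the minimum-likelihood method
and is trivial to validate against a full $2^n$ enumeration. Families are
tested only when they have at least `min_size` informative members
(default 2 — a sign test over one member is uninformative; the minimum is
configurable because the appropriate cutoff is a judgment call), and
Benjamini–Hochberg FDR is applied across testable families within a
contrast. A family is called *down* when FDR ≤ 0.05 and more than half its
members decrease, *up* in the mirror case.

Zero log2 fold changes are excluded from $n$: a sign test cannot assign
them a direction. Members are treated as independent; in reality fragments
of one family are co-produced and positively correlated, which makes the
binomial p-values optimistic on strongly correlated families. This is a
deliberate simplification — the test is a descriptive screen, and the
synthetic-cohort null simulations (below) show the FDR is controlled when
members are conditionally independent given the design.

The same statistic applies at coarser granularity (all mitochondrial
fragments, all 3′-tRFs, all fragments of one amino acid) via
`superfamily_trend_table()`; grouping granularity is just a parameter.

### Sidedness

The two-sided test is the default. The directional phrasing of the
scientific question ("a tendency for decreased expression under stress")
suggests a one-sided test, but significant up-trends are equally
interpretable and are reported in practice; both sidednesses are exposed
via `alternative`.

## The differential-expression stage

The family trend needs only fold-change *signs* and the screen's
significance calls, so the DE stage is a deliberately simplified
negative-binomial Wald pipeline rather than a re-implementation of a full
DE framework:

* **Prefilter**: keep a fragment iff at least `smallest_group_size` samples
  have a count of at least 10 (the smallest design group sets the default).
* **Normalisation**: median-of-ratios size factors over fragments with
  all-positive counts.
* **Dispersion**: per-feature method of moments on group-wise residual
  variances, then shrunk halfway (in log space) toward a fitted
  mean–dispersion trend $\phi(\mu) = a_0 + a_1/\mu$. The halfway weight is
  a fixed, simple stand-in for a full empirical-Bayes posterior; with
  21–35 samples it stabilises small-sample estimates without flattening
  genuine dispersion differences.
* **Fit**: per-feature NB GLM with log link and log size factors as
  offsets, fitted by IRLS. All features share one two-level design, so the
  2×2 weighted normal equations are solved vectorised across the whole
  matrix (50 iterations maximum, convergence tolerance $10^{-8}$ on the
  coefficients).
* **Test**: Wald statistic on the group coefficient referred to a
  *t* distribution with $n - 2$ degrees of freedom. With the normal
  reference the null rejection rate at $p \le 0.05$ runs slightly hot at
  these sample sizes; the *t* reference brings the null simulation into
  the 0.03–0.07 band.
* **Degeneracies**: a group with all-zero counts causes separation; such
  features fall back to a moderated log2 fold change from group means with
  a 0.5 pseudo-mean, are flagged, and are excluded from the FDR step
  (`p = NA`).

The stage is swappable: `read_de_table()` accepts any externally produced
DE table in the same schema (id, baseMean, log2FC, stat, pvalue, padj), so
real-data runs can use a full DE framework and feed its output to the
family-trend stage unchanged. Exact numerical replication of any specific
DE tool is a non-goal.

One known property of median-of-ratios normalisation matters for
interpretation: when a large fraction of features shifts in one direction,
the size factors absorb part of the shift and fold-change estimates
attenuate toward zero. The parameter-recovery tests therefore plant
effects in a small fraction of features, which is also the biologically
realistic regime.

## The synthetic cohort generator

`simulate_catalog()`, `simulate_counts()`, `simulate_prediction_table()`
and `simulate_ellman_traces()` are first-class, tested code, and their
defaults encode the study conditions the analysis is designed for:

* **Design**: four groups crossing newborn sex with maternal stress
  status, sized 6 (female stress), 8 (male stress), 11 (female control),
  10 (male control); PSS-10 scores drawn uniformly in [0, 10] for control
  and [19, 40] for stress mothers (integer scores; only the group label is
  used downstream).
* **Catalog scale**: 45 families over 565 fragments, the scale of the
  newborn serum catalog after prefiltering. Family sizes follow a
  heavy-tailed split (a few families dominate, as in real catalogs).
* **Lengths**: cleavage-type-specific normal modes rounded and clamped to
  16–50 nt — 18–19 nt for 5′-tRFs, 23–24 nt for i-tRFs and 3′-tRFs,
  31–32 nt for 5′-halves, 36 nt for 3′-halves — reproducing the observed
  serum length landscape: a dominant 23–24 nt mode, smaller 18–19 and
  31–32 nt modes, and a 36 nt peak.
* **Counts**: negative binomial with log-uniform base means on [5, 2000]
  and dispersion $\phi(\mu) = 0.1 + 1/\mu$, a decreasing mean–dispersion
  trend typical of serum small-RNA data (neither per-feature dispersions
  nor library sizes are published for such cohorts, so these are
  conventional rather than fitted values); library-size factors are
  log-normal with $\sigma = 0.2$.
* **Planted effects**: per family, a fraction of members shifts down by a
  chosen log2 fold change in the stress group (the remainder shifts up),
  optionally restricted to one sex. The default study emulation sends
  mitochondrial families down with fraction 0.99 in females and 0.90 in
  males and one nuclear Asp i-tRF family up — the qualitative pattern the
  family statistic is designed to detect. Every planted effect is emitted
  in a truth table; recovery tests consume only generator outputs.
* **Prediction tables**: each RNA draws a Poisson(30) number of gene
  targets from a 2000-gene universe with scores uniform on [50, 100];
  planted cholinergic RNAs are guaranteed at least one core-gene target
  with score ≥ 80. The weighted gene list has 15 core + 87 peripheral =
  102 genes, the scale of curated cholinergic panels.
* **Kinetics**: per sample, three 21-cycle traces (uninhibited, iso-OMPA,
  BW284c51) with additive Gaussian absorbance noise, clamped at zero.

What the generator does *not* emulate: within-family member correlation
beyond the shared planted direction, sequence-level realism, batch and
plate effects, zero inflation beyond what the NB produces, and the
compositional coupling between miR and tRF fractions. Passing tests
therefore demonstrate that the statistics behave as designed under the
stated generative model — not that any particular biological dataset
satisfies that model.

## Cholinergic scoring

Candidate RNAs must be 17–28 nt long (the microRNA-like targeting window)
and predictions must score at least 80. Duplicate (RNA, gene) predictions
collapse to their maximum score *before* the score filter, so a
low-scoring duplicate cannot mask a qualifying one. Qualifying targets in
the weighted list contribute 5 (core genes, e.g. ACHE, CHAT) or 1
(peripheral genes, e.g. IL6, CHKB) to the RNA's cholinergic score, and the
RNA is designated cholinergic iff it targets at least one core gene or at
least five peripheral genes. The rule is deterministic, so recovery on
planted tables is exact; the score is additive and the designation
monotone in added targets.

The 102-gene list shipped in `inst/extdata/cholinergic_genes_example.csv`
is a *documented example assembled for demonstration, not an authoritative
curated panel*; real analyses should supply their own list in the same
CSV schema. Enrichment of the designation in mitochondrial vs. nuclear
fragments uses Fisher's exact test; enrichment of cholinergic genes among
predicted targets uses the hypergeometric upper tail.

## Classification

Marker-set expression is summarised as $\log_2(\text{normalised count}+1)$
and standardised *inside* each cross-validation fold using training-fold
statistics only. The classifier is a soft-margin SVM (RBF kernel by
default, cost 1, kernel width by the median heuristic on the training
fold; the exact SVM variant behind published serum-tRF classifiers is not
reported, so these defaults are documented assumptions, and a linear
kernel is available). With 17–35 samples, nested hyperparameter tuning is
unstable and is off by default.

Two LOOCV-specific choices matter:

* **Score centering.** Each leave-one-out training fold is short exactly
  one sample of the held-out class. When the fit is weak, the decision
  function collapses toward a constant determined by that composition,
  which systematically anti-predicts the held-out label: on pure-noise
  features the naive LOOCV AUC averages ≈ 0.28, not 0.5. Re-weighting
  classes repairs the mean but leaks the held-out label through the
  weighted prior whenever the SVM underfits. `trfam` instead reports
  $f(x_i) - f(0)$ — the decision value relative to the standardised
  training-data origin — which removes the composition-dependent offset
  while preserving informative score differences. Pure-noise AUC then
  averages ≈ 0.5, separable data still give AUC 1, and permutation nulls
  behave. Disable via `svm_config(center_scores = FALSE)`.
* **Pooled ROC.** All out-of-fold scores are pooled into a single ROC
  (the convention of common ROC-from-CV tooling), rather than averaging
  per-fold curves; with LOOCV each fold holds one sample, so pooling is
  the only option that yields a curve at all.

AUC uses the rank (Mann–Whitney) formulation with half credit for ties,
which equals trapezoidal ROC integration on tie-free scores. Significance
comes from label permutations preserving class sizes, with the full LOOCV
re-run per permutation and the add-one estimate
$p = (1 + \#\{\mathrm{AUC}_b \ge \mathrm{AUC}\})/(1 + B)$; BH FDR is
applied across the evaluated marker sets. The default $B$ is 10,000 for
real analyses; the bundled pipeline configuration and the package's own
validation use $B = 199$, which is ample to rank marker sets while keeping
a desk-scale run in minutes.

## Cholinesterase kinetics

Catalytic rates come from ordinary-least-squares slopes over the 21
one-minute absorbance readings (a sub-window is configurable; all 21
cycles is the default since the traces are linear by construction),
reported in mOD/min and scaled by the sample dilution factor. The
uninhibited slope estimates total activity, the iso-OMPA condition (BChE
inhibited) estimates AChE, and the BW284c51 condition (AChE inhibited)
estimates BChE; $|\,\text{total} - (\text{AChE}+\text{BChE})\,|/\text{total}$
is reported as an additivity diagnostic and the fit $R^2$ as a linearity
diagnostic ($R^2$ is defined as 1 for an exactly constant trace). Negative
rates are reported but flagged rather than clamped — blank-corrected
slopes can legitimately dip below zero under noise. No blank subtraction
is applied by default (per-plate blank handling is upstream of this
package's inputs); unit conversion to nmol/min/mL is available through a
user-supplied extinction coefficient, with no default asserted.

Outlier removal uses the 1.5 × IQR fence with quartiles by linear
interpolation between order statistics (`stats::quantile` type 7); on the
worked example {2, 4, 6, 8, 100} the quartiles are 4 and 8, the upper
fence 14, and the outlier 100 is removed. Group comparisons use the
Mann–Whitney U test (unpaired) and the Wilcoxon signed-rank test (paired
dyads, or log-ratios against zero for ratio-vs-unity tests), exact for
small tie-free samples. Newborn/mother ratios exclude dyads with a
non-positive rate on either side, with reasons reported.

## Numerical and design notes

* Every generator is a pure function of (parameters, seed); the RNG state
  is saved and restored around each call.
* Family ordering is total (origin, then amino acid alphabetically, then
  cleavage type 5′→3′), so all outputs are byte-reproducible.
* Fragment length always comes from the sequence or an explicit length
  column, never from identifier coordinate arithmetic: tDR-style names use
  structural tRNA numbering, in which end − start + 1 need not equal the
  fragment length.
* Fragments mapping to parental tRNAs of different origins or amino acids
  are assigned by the annotation table's primary record (a warning is the
  appropriate channel for the rare ambiguous case; the name grammar
  carries a single origin/amino acid).
* The Fisher odds ratio is the sample odds ratio, with a Haldane 0.5
  correction when a cell is zero; a zero margin yields p = 1 and an
  undefined (NA) odds ratio.
* Expression-weighted mean fragment length (the per-sample family summary
  fed to the Kruskal–Wallis test) uses size-factor-normalised counts as
  weights; the choice of per-sample summary is not canonical and is
  documented here. Families whose summaries tie across all samples get
  H = 0, p = 1 rather than an error.
* Validation problem sizes were chosen to exercise the study design at
  full scale while keeping a complete run desk-scale: 200 replicate
  cohorts for the family-trend null and power studies, 5,000 features for
  DE calibration, 100–200 datasets with B = 199 permutations for
  classifier calibration, 50 samples for kinetic recovery.

## Known limitations

* The binomial treats family members as independent; correlated
  co-production inflates significance on tightly co-regulated families.
  Interpret family FDRs as a screen, not as a literal error rate.
* The simplified DE stage does not implement Cox–Reid-adjusted dispersion
  estimation or fold-change shrinkage estimators; it matches a full DE
  framework in sign and calibration, not numerically.
* LOOCV AUC on a handful of samples has high variance; permutation
  p-values, not raw AUCs, are the interpretable quantity.
* With dense planted effects (a large fraction of all features moving one
  way), median-of-ratios normalisation attenuates fold changes; this is a
  property of the normalisation, shared with standard DE tools.
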