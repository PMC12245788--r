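---
title: "Inverse docking fingerprints: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse docking fingerprints: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockfp)
options(dockfp.quiet = TRUE)
```

## The problem

Inverse molecular docking ("target fishing") docks one small molecule
against a large library of protein binding sites and asks which proteins
score unusually well. Two statistical obstacles stand between raw docking
output and that answer. First, structure libraries are redundant: one
protein is typically represented by several PDB entries and chains (in
realistic libraries a long-tailed distribution — a handful of structures
for most proteins, dozens for the famous ones). Second, docking scores
are in arbitrary units whose location and spread differ between ligands,
so absolute values are not comparable across ligands or meaningful in
isolation.

`dockfp` addresses both. Structures are collapsed to unique proteins by
UniProt accession, keeping the best (minimum) score per (ligand, target);
then each ligand's best-score profile is standardized to Z-scores using
the ligand's own mean and sample standard deviation over the common
target set. The Z vector is the ligand's *inverse docking fingerprint*: a
binding-pattern signature that supports three analyses —

1. **hit tables**: targets where several ligands score in the strongest
   tail of their distributions;
2. **fingerprint comparison**: an all-against-all RMSD matrix over the
   full common target set, clustered by Ward linkage to reveal groups of
   ligands with similar predicted binding patterns;
3. **retrospective validation**: per-ligand target rankings scored
   against known actives with ROC AUC and early-recognition metrics.

## Model assumptions

The Z-score presentation assumes each ligand's best scores across targets
are approximately normal; the −2.58 cutoff is then the 99.5th percentile
of the reference distribution. `normality_diagnostic()` reports sample
skewness, excess kurtosis and the Kolmogorov–Smirnov distance so users
can check this on their own data; it is advisory and never gates the
pipeline, because moderate departures shift the percentile interpretation
without invalidating the ranking (Z is a monotone transform of the raw
scores for each ligand).

The fingerprint RMSD

$$R_{l,k} = \sqrt{\tfrac{1}{N_t}\sum_{i=1}^{N_t}\bigl(Z_l(i)-Z_k(i)\bigr)^2}$$

is the Euclidean distance between fingerprints scaled by $1/\sqrt{N_t}$,
hence a proper metric; it is computed over **all** common targets rather
than a curated top subset, which makes it robust to curation choices.
Because the entries are Euclidean, Ward clustering applies the standard
Lance–Williams recurrence on squared distances, and heights are reported
on the distance scale so a dendrogram height reads directly as a
fingerprint RMSD.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `z_cut` | −2.58 | strict hit cutoff; the 99.5th percentile of N(0,1). Strict (`Z < z_cut`): the boundary itself does not count. |
| `min_ligands` | 3 | ligands that must pass `z_cut` for a target to be listed; guards against single-ligand artifacts. |
| `top_k` | 10 | per-ligand top targets pooled (de-duplicated) into the heatmap shortlist. |
| `alpha` | 20 | early-recognition exponent of RIE/BEDROC; weight $e^{-\alpha r/N}$ concentrates ~80% of the mass in the top 8% of the ranking. |
| `ef` fraction | 0.10 | EF prefix as a fraction of the library; prefix size is `ceil(f*N)`, never empty. |
| `pchembl_min` | 4 | strict lower bound (−log10 molar activity) for a ligand–target pair to count as active. |
| `tg_bins` | 10 | equal-count bins estimating the predictiveness curve for total gain. |

## Numerical and design choices

- **Sample SD** (denominator $N_t-1$) standardizes fingerprints — the
  ordinary finite-sample convention; at $N_t$ in the hundreds the
  difference from the population SD is negligible but the choice is fixed
  for reproducibility.
- **Intersection policy**: statistics are computed after restricting to
  targets scored for *every* ligand, so the single $N_t$ in the RMSD is
  well defined; dropped targets are counted and logged. At least 3 common
  targets and nonzero per-ligand variance are required (fatal otherwise,
  naming the ligand).
- **Best score** means minimum, fixed polarity: lower (more negative) =
  stronger predicted binding. There is no per-file polarity flag —
  mixed-polarity inputs must be converted before ingestion.
- **Duplicate records** of the same (ligand, pdb, chain) keep the
  minimum and are counted; **unmapped chains** are dropped with a
  warning rather than an error, since a binding-site library rarely
  covers every chain in a score dump.
- **Curated heatmaps carry over** the full-matrix Z values rather than
  re-standardizing on the subset: the displayed scale stays anchored to
  each ligand's whole-library distribution. Re-standardizing on the
  subset would inflate contrasts within the shortlist and is deliberately
  not offered.
- **Tie-breaking** is deterministic everywhere: ranking ties break by
  accession; equal-height Ward merge candidates break by the
  lexicographically smallest pair of cluster creation indices; dendrogram
  display order puts the smaller subtree first, ties by alphabetically
  first leaf. AUC alone is computed tie-aware from the raw scores
  (Mann–Whitney with ties counted ½), because crediting an arbitrary
  tie-break order would inflate it; the rank-based metrics (EF, RIE,
  BEDROC) need integer ranks and use the deterministic order.
- **Total gain binning**: the predictiveness curve is estimated by the
  active fraction in `tg_bins` equal-count bins (sizes differing by at
  most one). Published TG implementations do not document their binning,
  so small numerical differences from other tools are expected by
  construction; TG and BEDROC are clipped to [0, 1] against
  floating-point overshoot.
- **Newick export** writes ultrametric branch lengths (child branch =
  parent height − child height), so the most recent common ancestor of
  two leaves sits at their cophenetic distance and round-tripping through
  a phylogenetics parser recovers the merge heights.

## The synthetic-data generator

`generate_synthetic()` emulates the statistical shape of an inverse
docking campaign, not its physics:

- **Scale**: 14 ligands in two classes of 7 — mirroring a study design
  where half the ligands share a rigid scaffold and half a flexible one —
  over 500 unique targets by default (any size via `n_targets`).
- **Redundancy**: structures per target follow 1 + Geometric(p) with
  p = 0.17, giving a median of 4 structures per target and a heavy right
  tail, the qualitative signature of real structure libraries. Matching
  real libraries' larger *mean* (driven by extreme outliers such as
  kinases with hundreds of structures) is intentionally not attempted at
  desk scale.
- **Scores**: ligand l's structure-level score for target t is
  $\mathcal N(\mu_l - \Delta\sigma_l[\text{block}] -
  \delta\sigma_l[\text{active}],\ \sigma_l)$, decomposed into a
  target-level mean (SD $\sigma_l\sqrt{1-w^2}$) plus structure-level
  noise (SD $\sigma_l w$, default w = 0.25). The decomposition keeps
  structures of one protein correlated — as redundant structures of the
  same binding site are in practice — so the best-of-structures aggregate
  stays near-normal and preserves planted shifts at the target level,
  while the marginal per-structure distribution is exactly the stated
  normal.
- **Planted signal**: each class has a disjoint affinity block (10% of
  targets) whose target-level means drop by $\Delta\sigma_l$ (default
  Δ = 2); actives (25 per ligand, default shift δ = 1) are planted on
  block-free targets so enrichment tests are independent of the cluster
  structure. μ_l is drawn from −60..−40 and σ_l from 4..7 arbitrary
  units, spanning realistic between-ligand variation.

What the generator does **not** emulate: correlated binding-site
families (targets are independent given the class block), systematic
scoring-function bias toward particular folds, missing cells, and any
real chemistry. Passing the planted-recovery tests therefore shows the
*statistical machinery* is correct — it does not certify performance on
real docking output, where between-target correlation and bias can only
weaken class separation.

## Problem sizes used in the test suite

The suite exercises the defaults end to end: 20 independent seeds of the
default 14 × 500 design for planted-class recovery (expected adjusted
Rand index 1, with a Δ = 0 control near 0), 100 random screens of
N = 200 with 20 actives for the metric oracles, 1,000 random screens for
range invariants, a 5,000-target run for the normality property of the
generator (where the skewness statistic's own sampling noise, SD
≈ √(6/N), is small enough for a 0.15 bound to be informative), and one
library-scale run at 14 × 3,888 targets through the command-line driver.
Cross-implementation anchors: Ward trees are checked against
`hclust(method = "ward.D2")` cophenetic distances, AUC against `pROC`,
Newick output against `ape` parse-back, and RIE/BEDROC against frozen
reference values from an independent cheminformatics implementation.

## Known limitations

- The intersection completeness policy discards targets missing for any
  ligand; with very sparse matrices this can shrink $N_t$ drastically.
  An imputation-based policy is out of scope.
- Ward is the only linkage offered through the main API; the RMSD matrix
  is exported so any `hclust` linkage can be applied externally.
- Per-ligand validation only: metrics are not pooled across ligands,
  since prevalence differs per ligand and pooling would mix scales.
- Manual curation (which shortlist targets are "non-drug" artifacts) is
  consumed as a user-supplied exclude list, never decided in code.
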