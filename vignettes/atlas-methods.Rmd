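---
title: "Methods: droplet single-cell atlas analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet single-cell atlas analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropatlas)
```

## Scope and model

`dropatlas` implements the analysis chain used to build droplet
single-cell (Drop-seq) atlases of the *Drosophila* midbrain, starting from a
digital gene expression (DGE) matrix of UMI counts — genes in rows, cell
barcodes in columns — and ending with annotated, transmitter-typed cell
clusters. The package deliberately begins *after* read alignment and barcode
collapse: its inputs are integer UMI counts in the Drop-seq tools
tab-delimited dialect or Matrix-Market triplets.

The pipeline stages, in fixed order:

1. **QC filtering.** Cells are kept when they show at least `min_genes`
   detected genes (default 200) and a total UMI count inside
   `[umi_lower, umi_upper]` (defaults 800 and 10,000). Both tests are applied
   jointly in one pass, so the filter is idempotent and insensitive to the
   order in which thresholds are quoted. The defaults are the published
   whole-brain settings; the lower UMI bound is the dominant filter in
   practice, and relaxing it to 200 recovers the larger, noisier cell set.
2. **Log-normalization.** `x(g,c) = ln(1 + S * count(g,c) / n_umi(c))` with
   scale factor `S = 10,000` — the droplet-toolkit default invoked by the
   study's "default options". Zeros are preserved, and every cell satisfies
   `sum(expm1(x)) = S` exactly, which the tests assert as an algebraic
   identity. Multiplying a cell's counts by any constant leaves its profile
   unchanged: this is pure library-size removal, not variance stabilization.
3. **Covariate regression and scaling.** Per gene, an ordinary-least-squares
   fit of the normalized values on a batch indicator design; the residuals
   are standardized to unit variance and clipped at ±10. The clip guards the
   PCA against single outlier cells; the value is conventional and the
   results here are insensitive to it because planted signals are broad.
   Only batch is regressed by default (matching the source analysis), but the
   interface accepts arbitrary covariate data frames. Constant genes are set
   to zero and flagged rather than erroring, since they carry no information
   either way.
4. **PCA.** Scores are the centered cells-by-genes data projected onto the
   top eigenvectors of the gene covariance; 50 components by default. Signs
   are fixed by making the largest-magnitude loading entry positive, so
   results are reproducible across SVD backends. Small problems use an exact
   SVD; larger ones a truncated iterative SVD seeded deterministically.
5. **Jack Straw (optional).** In each of `n_reps` replicates a random 1% of
   genes is permuted across cells and the PCA is re-fitted; the permuted
   genes' absolute gene–PC correlations form the null. A PC is significant
   when the fraction of genes beating the null at the 0.05 level exceeds
   0.05 by a one-sided binomial test. An earlier shortcut that scored
   permuted genes against the *fixed* scores proved anti-conservative on
   pure noise — observed genes take part in the fit while permuted ones do
   not — so the full re-fit is used even though it costs `n_reps` PCAs. The
   test is a diagnostic for choosing `n_pcs` and is off by default in the
   pipeline.
6. **Clustering.** A shared-nearest-neighbor graph is built from the k = 20
   nearest neighbors (Euclidean, PC space; each cell's neighbor set includes
   itself), edges weighted by Jaccard overlap of neighbor sets and pruned at
   1/15. Communities are found by Louvain modularity optimisation with a
   resolution parameter; k-means with k-means++ seeding is available as the
   alternative used for the published 29-cluster segregation. Pruning is
   strict (`weight > prune`), so a pruning threshold of 1 empties the graph.
7. **t-SNE.** Two-dimensional embedding of the PC scores (perplexity 30,
   fixed seed recorded in the manifest). The embedding is display-only; no
   downstream statistic reads it.
8. **Markers and annotation.** One-vs-rest Wilcoxon rank-sum tests per gene
   and cluster with Bonferroni correction; reporting thresholds log2 FC ≥ 1
   and adjusted p < 0.01 (the published rule). Log2 fold changes are
   computed on `expm1` of the normalized means with pseudocount 1, the
   convention of the toolkit the study used. The Bonferroni denominator is
   the number of genes tested after the expressed-fraction gate (default:
   expressed in ≥ 10% of either group), again matching that toolkit.
   Pairwise presets mirror the figure legends: >50% / log2 FC 1.5 for the
   Kenyon-cell panels, >75% / 2 for glia, >50% / 1 for monoamines.
9. **Co-expression statistics.** Per-cell transmitter calls (`VAChT`,
   `VGlut`, `Gad1` above a normalized threshold τ = 2), category overlap
   fractions, neuropeptide radar tables, receptor-combination histograms,
   neuropeptide burden, and Pearson correlation heatmaps with Fisher
   Z-scores.
10. **QC estimators.** Species-mixing doublet classification and rate
    estimation, and bimodal sex assignment from a male-specific gene.

## The rank-sum test

The Mann–Whitney U statistic is computed from mid-ranks. When both groups
have at most 8 observations the two-sided p-value is obtained by exhaustive
enumeration of all `choose(n1 + n2, n1)` group assignments — exact under
ties. Larger groups use the normal approximation with tie-corrected variance
and a continuity correction. The matrix path used by marker discovery shares
ranks across all one-vs-rest comparisons of a clustering, since the pooled
ranking of each gene does not depend on which cluster is tested; the suite
asserts the matrix and scalar paths agree to machine precision, and that the
exact path equals an independent pair-counting enumeration oracle over a
thousand random tied instances.

## Transmitter calls and "expressing"

Two detection conventions coexist and are recorded in every output:

* **raw UMI ≥ 1** — used for co-expression *counting* (radar tables,
  combination histograms, neuropeptide burden), matching the source's
  language about "cells expressing";
* **normalized value > τ = 2** — used for transmitter *calls*, the threshold
  quoted for the transmitter display panels.

The source does not state which convention produced its headline overlap
percentages, so both are computable here and the default assignment above is
a package decision. Radar tables report both the conditional fraction per
category (`#(NP⁺ ∧ category) / #(category)`, the primary quantity: the
description "normalized to the total number of cells expressing each
neurotransmitter" pins the denominator) and the sum-normalized variant used
to draw relative radar shapes.

The correlation "Z-score" is likewise undefined in the source; the default
here is the Fisher transform `z = atanh(r) * sqrt(n - 3)`, with
within-matrix standardization of r available behind a flag.

## Doublet estimation

With species proportions `p` and `q = 1 - p`, only a fraction `2pq` of
two-cell droplets are cross-species and hence observable in a barnyard
experiment. The corrected rate is `(n_mixed / 2pq) / n_total`. The published
counts (764 barcodes; 368 and 384 pure; 12 mixed) give 24/764 = 3.14% with
this all-barcode denominator and 24/752 = 3.19% with the singlet denominator
— the latter rounds to the printed 3.2%, so both denominators are
implemented and the all-barcode form (which follows the phrase "of all
sequenced transcriptomes") is the default.

## Sex assignment

The per-cell UMI counts of a male-specific gene (roX1 in the fly midbrain)
are histogrammed at integer resolution; the two highest local maxima
separated by a valley define the cutoff at their midpoint (peaks at 0 and 9
give 4.5). Cells above the cutoff are called male. The positive fraction is
a drop-out diagnostic: below the expected male share it indicates transcript
drop-out. Note a structural property of the midpoint rule: if male counts
are Poisson with mean 9, a cutoff near 4.5 calls only
`P(Pois(9) ≥ 5) ≈ 94.5%` of males positive, so the expected positive
fraction in a perfectly balanced mixture is ≈ 47.3%, not 50%. Smoothing is
off by default (integer bins are already discrete); a width-3 moving average
is available for noisy genes. Cluster exclusions (the source excluded
non-neuronal tissue and one hybrid cluster) are the caller's responsibility
via the cell subset argument.

## The synthetic atlas generator

The generator exists so that every downstream stage is testable without
external downloads, and its defaults are fixed to the study design rather
than tuned per test:

* counts are negative binomial with mean
  `(cluster profile) × (cell library size) × (batch effect)` and shared
  dispersion φ = 0.3 (`var = μ + φμ²`), a typical droplet overdispersion;
* library sizes are lognormal(log 2000, 0.4), placing most cells inside the
  800–10,000 UMI window;
* 8 equal batches with lognormal multiplicative gene-level effects
  (sd 0.15), mirroring eight replicates that "contributed equally";
  per-replicate cell numbers are unpublished, so equal batch sizes are the
  default;
* each of the 8 default clusters carries 50 disjoint marker genes elevated
  by 2^`marker_log2fc`. The marker-program size matters: with an order of
  magnitude fewer markers the planted between-cluster eigenvalues sit at the
  Marchenko–Pastur noise edge of a 2000 × 3000 z-scored matrix and no
  method can recover the partition, which contradicts both the intended
  recovery property and the biology (real neuronal types differ in hundreds
  of genes; common simulators plant differential expression in ~10% of
  genes). 50/2000 = 2.5% is deliberately conservative;
* a 50/50 male/female mix with the sex gene at Poisson(9) in males and zero
  (with a 1% single-count leak) in females, reproducing the biphasic 0/9
  histogram;
* per-cluster Bernoulli programs for the three transmitter markers (one
  dominant class per cluster at 0.85, others at 0.05) and the 16-gene
  neuropeptide panel (0.5 in one preferred cluster, 0.02 elsewhere);
* doublets (3% of barcodes by default, the published barnyard estimate) are
  the sum of two independently drawn cell profiles, the second cluster
  uniform; ground truth records both components' totals so conservation is
  testable.

The barnyard generator draws each barcode's cell(s) independently from the
species proportions, so only ~`2pq` of doublets are cross-species — exactly
the situation the estimator corrects for — and adds a 1% cross-species
contamination fraction to singlets.

What the generator does *not* emulate: ambient RNA beyond that single
contamination fraction, cell-cycle or continuous trajectories,
gene–gene correlation within a cluster beyond the shared programs, variable
capture efficiency per batch, or read-level noise. Passing tests therefore
demonstrate the correctness and calibration of the *analysis machinery*
under the stated generative model, not performance on real tissue.

## Numerical and design choices

* **Resolution.** The pipeline default is 2.5, the published whole-brain
  setting for ~45 types among ~10,000 cells. The synthetic recovery checks
  use 1.0, the standard community-detection default, because eight
  well-separated planted types is a different regime; using 2.5 there
  measures over-splitting of the Louvain objective, not pipeline
  correctness.
* **Problem sizes.** The bundled checks run the full pipeline at 3000 cells
  × 2000 genes (about half a minute) and the estimator recoveries at
  n = 2000; these sizes give recovery noise well below the asserted margins
  while keeping the suite quick to iterate.
* **Determinism.** Every stochastic step (SVD initialisation, Louvain visit
  order, t-SNE, k-means++, generators) runs under an explicitly recorded
  seed through an RNG-state-preserving wrapper, so identical configs
  reproduce byte-identical outputs and the user's RNG stream is untouched.
* **Tie-breaks.** Cluster labels are relabelled contiguously from 0 in order
  of first appearance; annotation ties break alphabetically by panel name so
  results cannot depend on panel listing order; SNN neighbor sets include
  the cell itself (the convention of the toolkit ecosystem).
* **Degenerate inputs.** Zero-UMI cells are an error at normalization (with
  a pointer to QC); constant genes are flagged, not fatal; unimodal sex-gene
  distributions yield a diagnostic instead of calls; empty QC results are
  allowed; a doublet rate of zero is honored exactly.
* **Cluster-count reporting.** The source variously reports 28, 29 and 30
  clusters depending on method and manual curation; the package treats the
  cluster count as data-dependent output and hard-codes none of these.
  Manual curation is supported only as explicit label editing by the caller,
  not as an algorithm.

## Known limitations

* Marker discovery materializes the normalized matrix densely per
  clustering; at the bundled sizes this is a few tens of MB, but atlases two
  orders of magnitude larger would need a blocked implementation.
* The Jack Straw re-fits the PCA per replicate; at default replicates this
  is the most expensive diagnostic in the package and is therefore off by
  default in the pipeline.
* The annotation score (fraction expressing × mean normalized expression,
  negative markers gated at half the positive score) is a simple heuristic
  adequate for well-separated panels; probabilistic annotation is out of
  scope.
* Expression-profile doublet detection without species mixing is
  deliberately out of scope, as is any inference about synaptic release
  (expression of a transmitter pathway is necessary, not sufficient).
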