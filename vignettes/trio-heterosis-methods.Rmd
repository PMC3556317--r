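---
title: "Methods: trio RNA-seq analysis of expression heterosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio RNA-seq analysis of expression heterosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteroseq)
```

## The problem

Heterosis — the superiority of an F1 hybrid over its inbred parents — has
a transcriptional counterpart: genes whose expression in the hybrid
departs from the mid-parent expectation. Given replicated RNA-seq counts
for the two parents (P1, P2) and the hybrid (F1), possibly at several
developmental stages, `heteroseq` asks three questions per gene: is the
hybrid's expression different from each parent's (differential
expression)? is the departure additive, dominant or over-dominant
(dominance-ratio classification)? and do the candidate genes fall in
genomic intervals already linked to the traits that show phenotypic
heterosis (QTL overlap)? Alongside, replicated trait measurements yield
mid-parent heterosis (MPH) and high-parent heterosis (HPH) percentages
with significance tests.

## Quantification scale

Counts are normalized to RPKM, `count · 10⁹ / (L · N)`, where `L` is the
gene's summed exon length and `N` the per-sample total. The per-sample
denominator is the column sum of the gene-level matrix. External mapped-read
totals (which also count reads outside annotated genes) can be supplied,
but a self-contained column-sum default keeps the pipeline closed over its
inputs and is monotone-equivalent for comparisons within a sample.

Downstream model fitting and clustering use `log2(RPKM + 1)`. The
pseudocount of 1 is a convention (one RPKM ≈ one transcript-scale unit);
it compresses genes below ~1 RPKM toward zero, which is the desired
behaviour for distance computations dominated by well-measured genes.

## Differential expression: conditional NB exact test

The two-group test re-implements the exact-test idea for negative-binomial
counts rather than wrapping an existing package, so that its behaviour is
fully specified here:

1. **Library-size equalization.** Counts are scaled to the geometric mean
   of the library sizes and rounded to integers ("pseudo-counts"). The
   rounding keeps the conditional law well defined on integer support. A
   quantile-matching adjustment would be slightly more faithful to the
   marginal NB shape; the simple scaling was chosen as self-contained and
   adequate at the replicate numbers this design targets (2 per group).
2. **Dispersion.** With variance `μ + φμ²`, the gene-wise
   method-of-moments estimate `φ̂ = max(0, (s² − μ̄)/μ̄²)` (pooled
   within-group variance, mean of group means) is unusable alone at two
   replicates, so it is shrunk toward a 10%-trimmed mean of the gene-wise
   values with a fixed prior weight of 20 df-equivalents:
   `φ = (df·φ̂ + 20·φ̄)/(df + 20)`. All-zero genes take the common value.
3. **Conditional test.** Under H0 (equal means), the group sums are NB
   with sizes `n_A/φ` and `n_B/φ` and a shared probability parameter;
   conditioning on the total `t` leaves a negative hypergeometric law in
   the group-A sum that is free of the mean. The two-sided p-value sums
   the probabilities of all splits `a = 0..t` whose probability does not
   exceed the observed one (with a `1e-9` log-scale tolerance so that
   ties, e.g. the mirror split, are included rather than lost to rounding).
   At `φ = 0` the law reduces to binomial(`t`, `n_A/(n_A+n_B)`).
4. **Calling.** Benjamini–Hochberg step-up FDR (re-implemented;
   `q_(i) = min_{j≥i} m·p_(j)/j`), then the inclusive conjunction
   FDR ≤ 0.05 and |log₂FC| ≥ 1. Fold changes use normalized group means
   with a pseudo-mean of 0.5 per group so zero-count groups stay finite.
   For the hybrid/parent contrasts the orientation is hybrid over parent.

The test is *statistically analogous* to, not bit-compatible with, the
edgeR exact test whose role it fills; its correctness is checked against
brute-force enumeration of the conditional law (independent `dnbinom`
products) for all genes with conditional totals ≤ 50.

DEGs from the two hybrid/parent contrasts (labels R/F and X/F, after the
parental line initials) are united into DG_HP; the parent/parent contrast
(R/X) gives DG_PP.

## Additive/dominance decomposition and h_p classification

Per gene and stage, the model `y = u + (GA) + (GD) + (SR) + e` is fitted
by least squares on log₂ expression with design P1 → `u + a`,
P2 → `u − a`, F1 → `u + d`, plus a sum-to-zero replicate block column per
batch. `u` is then the mid-parent mean, the composite additive effect is
`[a] = |a|`, and `[d] = d` is the hybrid's deviation from the mid-parent
(positive = above). With 3 genotypes × 2 replicates the residual df is 2.
The replicate effect is fitted per gene: the block term exists to absorb
batch shifts between replicate pairs, and a per-gene fit is the direct
reading of the model (a global fit would leak gene-specific batch response
into the residuals).

The dominance ratio `h_p = [d]/[a]` has awkward sampling properties, so
classification works on the linear combinations `[d] − [a]` (when
`[d] > 0`) and `[d] + [a]` (when `[d] < 0`) instead: a two-sided t
confidence interval at level 0.998 (α = 0.002 split evenly) is built for
the combination, and

* `[d] > 0`: CI ∋ 0 → **HPL** (`h_p = 1`); CI > 0 → **AHP** (`h_p > 1`);
  CI < 0 → **MPL** (`0 < h_p < 1`, partial dominance);
* `[d] < 0`: CI ∋ 0 → **LPL** (`h_p = −1`); CI < 0 → **BLP**
  (`h_p < −1`); CI > 0 → **MPL**;
* `[d] = 0` exactly → "none".

Two choices here were genuinely open:

* **Variance mode.** Per-gene residual variance at df = 2 makes a 99.8%
  t-interval enormous (t quantile ≈ 22), absorbing nearly every gene into
  HPL/LPL. The default therefore moderates each gene's variance toward
  the median across genes with 20 pseudo-df
  (`s²_mod = (20·median(s²) + 2·s²)/22`, effective df 22) — the same
  borrowing-strength logic moderated-t methods use. A `per_gene` mode
  retains the raw variances for fidelity.
* **The MPL class.** The CI procedure has a third outcome on each side
  (interval on the "wrong" side of zero) that four-class summaries omit.
  It is emitted explicitly as MPL rather than silently dropped, so class
  counts always partition the classified genes.

Pattern summaries over DG_HP report up-regulated (AHP + HPL) and
down-regulated (LPL + BLP) fractions over classified genes
(class ≠ "none").

## Phenotype heterosis

For replicate trait values, `MPH = 100·(F1 − MP)/MP` with
`MP = (P̄1 + P̄2)/2`, and `HPH = 100·(F1 − HP)/HP` with HP the best
parental mean — the larger one by default, with a flag for
smaller-is-better traits. Significance: the MPH test uses the composite
variance `s²_F1/n_F1 + (s²_P1/n_P1 + s²_P2/n_P2)/4` with Satterthwaite
df (the paper-style t test does not specify a construction; this is the
standard one for a linear combination of independent group means); the
HPH test is a Welch two-sample t of F1 against the best parent. Zero
variance throughout is resolved by convention: p = 1 when the difference
is zero, p = 0 otherwise.

## Enrichment, clustering, QTL overlap

* **Enrichment** is the one-sided hypergeometric upper tail
  `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)`, per term, BH-corrected within
  each namespace. The default background universe is the detected-gene
  set (≥ 1 read), since an undetectable gene can never enter a DEG set;
  both raw-p and FDR flags are reported. The annotation is user-supplied —
  no GO/KEGG databases are bundled.
* **Clustering** is average-linkage agglomeration on 1 − Pearson
  correlation across genes (uncentered correlation, the Cluster 3.0
  default, and Euclidean distance are options). Trees serialize to Newick
  with branch lengths equal to merge-height differences.
* **QTL overlap** places genes into marker-delimited intervals supplied
  with bp coordinates (marker names are metadata; no genetic map is
  bundled). The default membership rule is full containment — "located
  in an interval" is read strictly — with an any-overlap rule available;
  containment results are always a subset of overlap results.

## The synthetic generator's stated world

`simulate_trio_counts()` draws, per gene: baseline log₂ expression
`u ~ N(5, 2)` (log₂ RPKM units — a realistic bulk RNA-seq spread), and
with probability 0.3 a non-null effect pair `a ~ N(0, 1)`,
`d ~ N(0, 0.8)` (log₂ units; `frac_null = 0.7`). Genotype means on the
log₂ scale are `u + a`, `u − a`, `u + d`, plus a per-(stage, replicate)
block effect `N(0, 0.05)`. Expected counts are
`2^η · (L/1000) · (lib/10⁶)` — the baseline acts as a true RPKM — and
counts are NB with dispersion 0.1 by default (gene-wise gamma
dispersions and the Poisson limit are options). Gene lengths are uniform
on 200–10,000 bp; the trio design is 3 genotypes × 2 replicates × 2
stages, matching the motivating experiment; trait phenotypes default to
the published Xieyou 9308 root-trait means and sds with 10 replicates.

What it deliberately does **not** emulate: read-level artifacts
(alignment, positional/GC bias), isoforms, correlated effect structure
across genes, and outlier samples. A green test on synthetic data
therefore establishes that the estimators recover the model they assume —
not that the model captures every property of real libraries.

Determinism: one seed governs the whole draw; identical configs give
bitwise-identical counts and fixture files.

## Numerical choices

* Exact-test tie tolerance `1e-9` on the log-probability scale.
* Library equalization rounds to integers; totals of zero give p = 1.
* Dispersion clipped at 0; common value is a 10%-trimmed mean.
* BH implemented as a reverse cumulative minimum; errors on NA input.
* CI boundaries are inclusive (a CI endpoint exactly at 0 counts as
  covering), matching the inclusive ≤/≥ DEG thresholds.
* The pipeline config is JSON (schema-checked key-value text); unknown
  keys are rejected rather than ignored.

## Known limitations

* The exact test's equalization-by-rounding perturbs very small counts;
  its p-values are conservative at low totals (checked by stochastic
  dominance against uniform on null simulations).
* The replicate block effect assumes replicates form batches across
  genotypes within a stage; fully crossed batch structures are out of
  scope.
* Published paper-scale results that depend on the real sequencing data
  (global DEG counts, class fractions, detection and mapping rates) are
  not reproducible from this package and are not claimed; the package
  reproduces the published trait MPH/HPH arithmetic exactly and the
  qualitative stage-switching parent affinity of the hybrid on seeded
  fixtures.
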