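---
title: "Methods: SVR-based immune cell deconvolution and its benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SVR-based immune cell deconvolution and its benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrdecon)
```

## The mixture model

A bulk expression profile is modelled as a linear combination of cell-type
specific profiles on the **linear intensity scale**:

$$ B_g = \sum_c A_{gc}\, x_c + \varepsilon_g $$

with $B$ the mixture over the signature genes, $A$ the signature matrix
(mean linear-scale expression of gene $g$ in cell type $c$) and $x \ge 0$
the mixing weights. The linearity assumption holds for transcript
abundances, not for their logarithms, which is why log2 inputs are
anti-logged at ingestion (`as_linear()`, $2^x - 1$) and all mixing
arithmetic — simulation included — happens on the linear scale.

The model is deliberately *relative*: fractions are renormalized mixing
weights and say nothing about absolute cell counts or per-cell mRNA
content. Cell types absent from the signature fold into the residual.

## Fitting: ν-SVR on a standardized basis

`deconvolve_sample()` proceeds in four steps.

1. **Gene alignment.** Signature and mixture are restricted to their
   shared genes, in the signature's order; the overlap must be at least
   the number of cell types, otherwise the basis is underdetermined and
   the call errors.
2. **Standardization.** Every column (each signature column and the
   mixture) is scaled to zero mean and unit variance over the shared
   genes. This makes the fit invariant to the overall scale of the
   mixture and puts the regularization on a comparable footing across
   cell types.
3. **ν-SVR grid.** One linear-kernel ν-SVR (via `e1071::svm`, i.e.
   libsvm) is fitted per ν in the grid (default $\{0.25, 0.5, 0.75\}$,
   cost $C = 1$). ν jointly bounds the fraction of margin errors and the
   fraction of support vectors, so the grid spans sparse-to-dense use of
   the signature genes. The fit minimising the reconstruction RMSE
   $\lVert A_{std} w - B_{std}\rVert_2 / \sqrt{G}$ wins; ties break
   toward the smaller ν (sparser support, deterministic).
4. **Weights to fractions.** Standardizing each signature column divides
   it by its own standard deviation, so the fitted weight of column $c$
   absorbs a factor $\sigma_c$: $w_c = x_c\,\sigma_c/\sigma_B$. The
   winning weights are therefore divided by the per-column signature
   standard deviations before negative clipping and renormalization;
   without this back-scaling the recovered fractions would be biased
   toward high-variance columns and exact recovery of noiseless in-basis
   mixtures would be impossible. If every back-scaled weight is
   non-positive the result is returned as an all-zero vector with an
   `all_zero` flag rather than renormalized.

RMSE and the reconstruction correlation are reported in standardized
space — the space the regression actually operates in — and are
comparable across samples for that reason.

### Quantile normalization

`quantile_normalize()` forces all sample columns onto the across-sample
mean of the order statistics, preserving within-column ranks; tied values
receive the mean of the target quantiles they jointly occupy (a
deterministic convention; note that `limma::normalizeQuantiles` instead
interpolates at the mean tied rank, so the two agree exactly only on
tie-free data). A single column is returned unchanged with a warning —
there is nothing to normalize against.

In `deconvolve()` the mixture columns are quantile-normalized *among
themselves* (default on). This removes technical distribution differences
between real samples before they are compared against a common basis. It
is intentionally **not** a normalization onto the signature's
distribution: forcing a mixture's values onto the pooled signature
distribution destroys the linear mixture structure (a blend of
block-structured columns does not share their distribution), and in our
prototyping raised the fraction error on noiseless mixtures from ~1e-4 to
~0.9. For the same reason the in-silico benchmarks deconvolve each
simulated column individually: cross-sample quantile normalization of
heterogeneous exact linear blends is a distortion, not a correction.
Quantile normalization is a tool for technical harmonization of real
arrays.

## Signature construction

`build_signature()` runs a fixed pipeline; every exclusion is logged and
the three exclusion sets (non-significant, non-hematopoietic,
tumor-expressed) are disjoint by construction.

1. **Marker ranking** (`rank_marker_genes`). Each cell type is contrasted
   one-vs-rest on the log2 scale. The default statistic is limma's
   empirical-Bayes moderated t, which shrinks per-gene variances toward
   the across-gene prior — the right choice for the small per-type
   replicate counts typical of curated reference panels; a plain
   pooled-variance t is available (`method = "t"`). P-values are BH
   adjusted across genes within each contrast. Only genes with adjusted
   p < 0.05 **and positive log2 fold change** qualify: signature entries
   are mean expression levels of genes that characterise a type, and a
   "marker" that is low in its own type would corrupt the basis. Markers
   are ordered by decreasing fold change (signed, not absolute — the
   ordering criterion and the retention criterion are the same quantity).
   Genes constant across the panel get p = 1.
2. **Enrichment-score filter** (`compute_enrichment_scores`,
   `hematopoietic_gene_set`). Every tissue group of a broad tissue panel
   is contrasted against each other group individually with a plain
   two-group linear model per gene (the coefficient is the group mean
   difference on log2 scale); q-values are BH adjusted *within each
   pairwise contrast* across genes. ES(gene, group) is the sum of that
   group's significant (q < 0.05, strict) coefficients. A gene's
   non-hematopoietic fraction is the share of its **positive** ES mass
   carried by non-hematopoietic groups; genes above 0.05 are removed, as
   are genes with no positive enrichment anywhere (no evidence of
   hematopoietic expression). The mass-fraction reading (rather than a
   count-of-groups fraction) weights each group by its effect size and
   is the more direct operationalization of "fraction of
   non-hematopoietic enrichment". Plain rather than moderated fits are
   used here so the statistic is exactly reproducible by per-gene `lm()`
   — the tissue panel has many samples per group, where shrinkage buys
   little.
3. **Tumor filter** (`filter_tumor_expressed`). Candidates with mean
   log2 expression > 7 across a tumor panel are removed, so tumor
   content cannot impersonate immune signal. Candidates absent from the
   tumor panel are kept but logged: absence of evidence is not treated
   as tumor expression.
4. **Top-n merge and condition-number scan** (`assemble_signature`,
   `optimize_signature`). For each n in 1…44 the union of per-type top-n
   markers (shared genes enter once) forms a candidate basis whose
   entries are mean linear-scale expression per type; the n minimising
   the 2-norm condition number $\sigma_{max}/\sigma_{min}$ wins, ties
   toward smaller n (parsimony). The 2-norm (SVD) condition number is
   the natural choice for a least-squares-type system. A candidate with
   no more genes than cell types cannot constitute a basis and that n is
   skipped with a warning — for disjoint top-1 lists the union size
   equals the number of types, so n = 1 is structurally infeasible
   whenever any top marker is shared.

## The synthetic panel and what it does (not) emulate

`generate_synthetic_panel()` builds a block-structured signature: each of
25 cell types (the default panel with its seven-major-lineage hierarchy)
carries 20 dedicated marker genes; 10% of each type's markers are also
elevated in the neighbouring sibling type, emulating markers shared
between closely related subtypes. Defaults, chosen once for realism:

| parameter | default | rationale |
|---|---|---|
| markers per type | 20 | ~500 signature genes for 25 types, the density of real microarray-derived immune signatures |
| background level | 50 (median) | ≈ 2^5.6, typical array background |
| background jitter | log-normal, sdlog 0.2 | constitutive expression differs per gene; a perfectly flat background is not only unrealistic but degenerate — with equal-size blocks exactly tiling the gene set, the standardized signature columns sum to zero and the regression solution is defined only up to a constant weight shift |
| marker fold change | 100 | definitive lineage markers (Cd19-, Cd3e-class genes) are essentially off outside their lineage: two orders of magnitude |
| replicate noise | log-normal, sdlog 0.1 | multiplicative intensity error, the error structure of array data |
| reference replicates | 3 per type | small curated panels |

The three benchmark designs are exact linear blends over this basis:
**pure profiles** (one noisy single-type profile per type), **spike-in
series** (one type swept 0–100% in 10% steps against a fixed
Dirichlet(1)-random background of the other types; Dirichlet(1) is the
uniform distribution on the simplex), and the **tumor-dilution series**
(a random immune mixture blended with a tumor profile at 0–90% in 10%
steps plus 91–99% in 1% steps, 19 points). The synthetic tumor profile
expresses the signature genes at background level with a broad log-normal
spread (sdlog 0.5): signature genes survive the tumor-expression filter
by construction, so a real tumor expresses them near background. The
tumor-robustness check is evaluated on **major-type aggregated**
fractions, which is the granularity at which the composition is expected
to survive extreme dilution.

What the generator does *not* emulate: probe saturation, batch effects,
platform-specific intensity distributions, correlated marker programs
across unrelated types, and cell types missing from the signature.
Passing benchmarks therefore demonstrate the correctness and conditioning
of the estimator, not its field accuracy on real arrays — that depends on
the quality of the real signature matrix used.

## Numerical choices and degenerate inputs

- Condition number returns `Inf` when the smallest singular value is
  below `max(dim) * eps * σ_max` (standard rank tolerance); an empty
  matrix errors.
- RMSE ties across the ν grid break toward smaller ν; condition-number
  ties across n break toward smaller n. Both rules are deterministic.
- A constant mixture column cannot be standardized and fails that sample
  (collected, not fatal, in `deconvolve()`); a constant signature column
  is rejected at construction.
- Duplicate gene symbols are collapsed at ingestion by `max` (the
  convention for probe-to-symbol collapsed arrays; `mean` available).
- Fractions must sum to 1 within 1e-9 unless flagged `all_zero`.
- All table output is written atomically (temp file + rename).

## Problem sizes in the shipped tests

The test suite exercises the default 25-type, 500-gene panel for the
end-to-end recovery checks (25 pure profiles; 100 noiseless random
compositions; 25 spike series × 11 points; one 19-point tumor series)
and a 6-type, 30-gene panel for unit-level checks — sizes chosen so the
whole suite completes in about two minutes on one core while still
running every design at the full default panel.

## Known limitations

- Fractions are relative to the signature's universe of cell types;
  unmodelled populations bias all fractions upward.
- Closely related subtypes with many shared markers (e.g. CD4/CD8
  subsets) are mutually confusable at the fine-grained level; the
  hierarchy exists precisely so users can report major-type aggregates
  where this matters.
- The moderated one-vs-rest contrast treats "all other types" as one
  group; a type that is intermediate between two others can lose markers
  to the pooled variance of the rest.
- No empirical significance measure for a deconvolution is provided; the
  reconstruction RMSE and correlation are goodness-of-fit diagnostics,
  not p-values.
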