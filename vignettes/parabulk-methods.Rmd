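---
title: "Pseudobulk double-difference analysis of heterochronic parabiosis cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudobulk double-difference analysis of heterochronic parabiosis cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parabulk)
```

## The experimental design

Heterochronic parabiosis surgically joins a young and an old animal so that
they share circulation. A six-arm design separates the effects of age,
surgery and heterochronicity:

| arm | description |
|-----|-------------|
| YX / OX | unpaired young / old |
| YY / OO | isochronic pairs (young–young, old–old) |
| YO | young heterochronic (joined to an old partner) |
| OY | old heterochronic (joined to a young partner) |

Write the expected log2 expression of a gene in each arm as a sum of an
aging effect $a$, surgery effects $s_Y$ and $s_O$ (entering both members of
a pairing), a rejuvenation shift $r$ (old heterochronic only) and an
acceleration shift $q$ (young heterochronic only):

$$\mathrm{YX}: 0,\quad \mathrm{YY}: s_Y,\quad \mathrm{YO}: s_Y + q,\quad
  \mathrm{OX}: a,\quad \mathrm{OO}: a + s_O,\quad \mathrm{OY}: a + s_O + r.$$

Two double-difference contrasts isolate the heterochronic shifts while the
surgery terms cancel exactly:

* **RJV** (rejuvenation): $(\mathrm{OY}-\mathrm{OX})-(\mathrm{OO}-\mathrm{YX})
  = r - a$, with design weights OY $+1$, OO $-1$, OX $-1$, YX $+1$;
* **AGA** (aging acceleration): $(\mathrm{YO}-\mathrm{YX})-(\mathrm{YY}-\mathrm{OX})
  = q + a$, weights YO $+1$, YY $-1$, YX $-1$, OX $+1$.

A gene "rejuvenated" by parabiosis therefore shows an RJV estimate opposite
in sign to its aging change, and a *bidirectional* gene is significant in
both RJV and AGA with opposite fold-change signs. Seven pairwise
comparisons (OXvYX — the aging comparison — OYvOX, OYvOO, OOvOX, YOvYX,
YOvYY, YYvYX) complete the catalogue.

## The statistical model

Cell-level counts are too correlated within an animal to be treated as
replicates, so all testing is **pseudobulk**: within each cell type, UMI
counts are summed per animal, and animals are the experimental units. Per
gene the model is a negative-binomial GLM with log link, a one-hot
animal-type design (no intercept) and offset $\log(\text{effective library
size})$, where effective library sizes are raw pseudobulk totals times TMM
normalization factors (trimmed mean of M-values: 30% two-sided trim on
log-ratios, 5% on average abundance, inverse-variance weights, factors
rescaled to geometric mean 1).

Dispersion is estimated in two steps: a common value maximizing the summed
Cox–Reid adjusted profile likelihood (APL) on a log-spaced grid
($10^{-4}$–4, 21 points), then a gene-wise value maximizing the gene's own
APL plus 10 "prior genes" worth of the average APL — shrinking gene-wise
dispersions toward the common value. Contrasts are tested with a
quasi-likelihood F statistic: the per-gene QL dispersion (residual deviance
/ residual df) is moderated by empirical-Bayes squeezing toward a common
value with a moment-estimated prior df, and
$F = (\text{deviance drop under the contrast constraint}) / s^2_{\text{moderated}}$
is referred to $F(1, \text{df}_{\text{resid}} + \text{df}_{\text{prior}})$.
The constrained fit reparameterizes the design onto the null space of the
contrast and iterates IRLS with deviance-guarded step halving; genes that
do not converge are excluded from testing and logged.

Reported fold-changes are estimated with a small library-proportional prior
count (0.125 per average animal) so that genes with an empty arm keep
finite log2FC; tests and deviances always use the unaugmented fit.
Contrasts are estimated on the natural-log GLM scale and reported in log2
units. BH-adjusted q-values are computed per (cell type, contrast) table
(`p_adj.loc`, used for all thresholding at FDR 0.05) and across all tested
cell types (`p_adj.glb`). Per-animal TPM is counts $\times 10^6$ / library
size; the per-animal-type TPM is the unweighted mean over that type's
animals (a pooled-count variant is available via `pooled_tpm`), and heatmap
matrices are per-gene z-scores of $\log_2(\mathrm{TPM}+1)$ across animals
(sample SD; zero-variance rows map to zero).

## Quality control and doublet flagging

The two-round QC mirrors standard droplet practice: cells are kept with
percent-mitochondrial reads in [0, 5], detected genes in [250, 6000] and
total UMI in [200, 30000]; genes must be detected in at least 5 cells.
Clusters are flagged when mean percent-mito exceeds 8%, or the cluster
summary nCount falls below 1,000 or nFeature below 500 — the summary is the
cluster *median* by default (robust to outlier cells; configurable to the
mean, since either reading of "min nCount" is defensible). Animals are
excluded when their average number of detected genes (over cells with any)
is below 700, their mean percent-mito exceeds 1.5, or they contribute no
cells to some cluster. Stored nCount/nFeature covariates are treated as
fixed cell annotations, which makes `filter_cells()` idempotent.

Cluster markers are two-sided Wilcoxon rank-sum tests of log-normalized
expression (counts scaled to 10,000 per cell, then log1p), with midranks
for ties; the null distribution is enumerated exactly up to 20 cells and
approximated normally (tie-corrected variance, 0.5 continuity correction)
above. A cluster is flagged as a probable doublet when more than 40% of its
cells express (raw count $\ge 1$) at least 7 of the top-10 markers of a
foreign cell type whose *class* differs from the cluster's own; the
type-to-class map (e.g. oligodendrocyte lineage, astroependymal, neuronal,
vascular, immune) is supplied by the user rather than hard-coded. The
"foreign type outside the cluster's class" reading resolves an ambiguity in
how the rule is usually phrased; it is a documented choice, not an assertion
about intent. Cell-count differences between animal types are tested per
cell type by one-way ANOVA on per-animal counts with no multiplicity
correction; animals with zero cells of a type enter as zeros.

## Preranked permutation enrichment

Genes are ranked by $-\log_{10}(p) \times \mathrm{sign}(\log_2\mathrm{FC})$
(p-values of exactly zero are capped at the smallest positive normalized
double; ties keep input order so runs are reproducible). The enrichment
score is the classic weighted Kolmogorov–Smirnov running sum (weight 1 on
absolute scores). Significance uses a gene-label permutation null: random
same-size sets drawn from the ranked universe, one-sided tail p with +1
smoothing among same-sign null scores, and NES = ES / mean(|null ES| of
matching sign). Sets are filtered to 15–500 members after intersection with
the ranked list, 1,000 permutations per set, and BH-adjusted significance
at $q \le 0.25$. The senescence scan applies the same machinery to a single
curated senescence gene set per (cell type, paradigm) with no size filter,
reporting NES and BH-adjusted p across the scan grid. Sample-permutation
nulls are out of scope. Ortholog mapping is applied from a user-supplied
two-column table: set members keep all targets (deduplicated); ranked lists
keep the first occurrence when sources collapse.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes, with known
ground truth: six arms with the study's unbalanced animal counts (8 YX, 7
YY, 9 YO, 8 OX, 7 OO, 11 OY), ~40 cells per animal per cell type by
default, gamma(0.5) baseline relative abundances (a realistically skewed
transcriptome), NB counts with global dispersion 0.4 (variance
$\mu + \phi\mu^2$, typical for UMI data), log-normal per-cell library sizes
with median 2,800 UMI, and a per-(animal, gene) normal random intercept
with SD 0.15 log2 — the between-animal variance that makes
quasi-likelihood testing meaningful; as no published value exists for it,
this is a calibration choice exposed in the config. A small set of genes is
labelled mitochondrial (prefix `mt-`) and rescaled to a 1% expression share
so QC paths are exercised while simulated animals stay below the 1.5%
animal-level threshold. Batch labels are assigned round-robin with no batch
effect (clusters in the motivating data were represented by all batches).
Affected genes per effect are the first $\lfloor\text{fraction}\times
G\rfloor$ of a seeded shuffle, so tests can re-derive the selection.

Counts are drawn by inverse CDF (`qnbinom` on seeded uniforms) rather than
`rnbinom`: two configs differing only in planted effect sizes then share
their entire uniform stream, so cohorts are *coupled* — the
surgery-cancellation check compares RJV estimates between a cohort with and
without $s_O$ as a property of the estimator rather than of independent
Monte-Carlo noise. Sub-seeds for effects, random intercepts, cell counts
and count draws all derive deterministically from one global seed.

The generator does not emulate UMAP geometry, batch effects, ambient RNA or
doublet transcriptomes (doublet-rule tests construct mixtures explicitly),
so passing tests demonstrate correctness of the statistical machinery under
the stated generative model, not robustness to those artifacts in real
data.

## Verification strategy and problem sizes

The test suite checks every stage against independent oracles at small
sizes: brute-force predicate evaluation for QC filters, exact enumeration
for rank-sum p-values, a textbook step-up oracle for BH, a hand-written
running-sum loop for enrichment scores, exhaustive same-size-set
enumeration for permutation p-values, and a truth table for the
bidirectional classifier. Stage-level recovery uses the default cohort
(2,000 genes, 50 animals, ~40 cells/animal, ~2,000 cells per run): planted
RJV effects are recovered with mean bias well inside ±0.15 log2 and the
null fraction of $p \le 0.05$ sits near 0.045 with KS-uniformity
non-rejections in 20/20 replicates. Null calibration uses 20 such
replicates; the senescence reversal uses 20 replicates of a 1,000-gene
cohort with a 50-gene senescence panel planted at $a = +1$, $r = -2a$ —
effect sizes chosen once as "adequately powered" study conditions.

Three documented limits of the study conditions (not of the implementation)
are worth stating plainly. First, rank recovery: at ~40 cells per animal
the lowest abundance tertile of genes carries per-gene log2FC noise of
~0.8, so the Spearman correlation between planted and estimated RJV effects
sits at 0.87–0.92 depending on seed; the reference pseudobulk QLF
implementation produces the same values to three decimals on identical
cohorts, so this is the information floor of the design, not estimator
slack. Second, for the same reason, planted reversal genes below median
abundance rarely reach AGA significance at FDR 0.05, capping end-to-end
bidirectional sensitivity near 0.65 when effects are planted blindly with
respect to abundance. Third, the surgery-cancellation property is an
expectation statement: per-gene estimate differences between coupled
cohorts are dominated by integer-count coupling noise in low-abundance
genes (median |Δ| ≈ 0.016, but mean |Δ| ≈ 0.08), while the mean shift —
the quantity the cancellation claim concerns — is below 0.01 log2.

## Numerical choices

* Newton/IRLS convergence tolerance $10^{-8}$, at most 100 iterations for
  unconstrained fits (1-D per group, since the one-hot design decouples
  coefficients) and 200 for constrained fits with step halving.
* Coefficients of empty arms are floored at $-50$ on the natural-log scale;
  constrained-fit initialization floors them at $-25$ before projection.
* Dispersion grid $10^{-4}$–4 with quadratic interpolation in $\log\phi$
  around the grid maximum.
* The prior df of the QL moderation comes from moment matching on
  $\log s^2$ with a Newton inverse-trigamma; infinite prior df degenerates
  to the common value.
* Zero log2FC is "same direction" for the signed-absolute-difference
  reversal statistic (sign 0), and exact-zero fold-changes of significant
  gene pairs are classified concordant, not bidirectional.
* DGE frequencies per 100 cells are reported at full precision and printed
  to 4 decimals.
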