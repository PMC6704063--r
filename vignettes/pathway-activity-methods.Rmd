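---
title: "Methods: cell-type pathway activity and metabolic heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type pathway activity and metabolic heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMetPath)
```

## The pathway activity model

`scMetPath` scores the activity of a gene program (typically a KEGG
metabolic pathway) in each cell type of a single-cell RNA-seq dataset.
All computations run on log2(TPM + 1) values. The chain is:

1. **Cell-type means.** `celltype_means()` averages each gene over the
   cells of each annotated cell type, giving a gene × type matrix $E$.
2. **Relative expression.** `relative_expression()` divides each gene's
   row by its across-type mean: $r_{ij} = E_{ij} / \bar E_{i\cdot}$.
   Values above 1 mean the gene is expressed above its own cross-type
   average in that type; by construction each valid gene's $r$ averages
   to exactly 1 across types (checked to 1e-12 in the tests). Genes with
   an all-zero row have no defined ratio and are flagged invalid rather
   than propagated as NaN.
3. **Weighted pathway score.** `pathway_scores()` averages $r_{ij}$ over
   the pathway's member genes with weights $w_i = 1/(\text{number of
   pathways containing gene } i)$, so genes shared by many programs are
   down-weighted. Before averaging, a pathway-level outlier rule drops
   genes whose relative expression strays beyond `outlier_hi` (default 3)
   times the 75th percentile or below `outlier_lo` (default 1/3) times
   the 25th percentile of the pathway's pooled $r$ values. The percentile
   pool is the pathway's member-gene $r$ values **across all cell
   types**, and an outlier gene is removed from that pathway in *every*
   cell type: removing it type-by-type would make scores incomparable
   across types, which defeats the purpose of a relative score. A
   pathway with no surviving genes gets an `NA` score and is flagged —
   a zero would masquerade as "strong down-regulation".

### The permutation test

`permutation_test()` shuffles the cell-type labels across all cells
(`n_perm` times, default 5000 for single-cell data; `bulk_group_activity()`
defaults to 1000 for bulk cohorts) and recomputes the *entire* chain —
means, ratios, outlier exclusion, weighted score — per shuffle. The
directional tail for a pathway/type pair counts null scores above the
observed score when it exceeds 1, below it when it is under 1.

Two presentational decisions matter here:

- **Two-sided default.** The direction of the tail is chosen by the data,
  which makes the raw directional fraction anti-conservative: under a
  true null it concentrates on (0, 0.5) and rejects at roughly twice the
  nominal rate. The default `p_type = "two_sided"` therefore doubles the
  directional tail (capped at 1), which our null simulations show is
  calibrated (type-I error ≈ 0.04–0.05 at α = 0.05, p-values passing a KS
  uniformity test). `p_type = "directional"` reports the raw one-sided
  tail for users who want the uncorrected convention.
- **Add-one smoothing.** p is computed as $(1+b)/(1+n)$ so a permutation
  p-value is never exactly 0; `smooth = FALSE` recovers the plain
  fraction $b/n$. A score exactly equal to 1 gets p = 1 (no deviation in
  either direction).

Shuffling is global across all cells rather than stratified within
tumors; with patient-specific malignant programs a stratified shuffle
would test a subtly different null, and the global shuffle matches the
score's definition (deviation of a cell type from the all-cell average).

## Normalization evaluation

Size factors (`size_factors()`) are computed on (pseudo-)counts by four
standard methods — median-of-ratios RLE, TMM, upper quartile, and
cell-type-aware pooling deconvolution — through their reference
implementations in DESeq2, edgeR and scran respectively; pseudo-counts
are obtained from TPM by multiplying gene length (`tpm_counts_convert()`),
and all methods accept non-integer counts. Only *reference genes* with
dropout rate < 0.75 enter the computation: factors driven by rarely
detected genes mostly measure dropout, not depth. The reference-gene
filter is applied uniformly to all four methods so their comparison is
apples-to-apples.

`evaluate_normalizations()` ranks the methods by how well they align the
distributions of log relative expression across cell types, using the
mean two-sample Kolmogorov–Smirnov statistic over all type pairs. The KS
statistic was chosen because it is distribution-free, symmetric, and
insensitive to the heavy tails of expression ratios; the method with the
smallest mean statistic is selected. On data with cell-type-specific
composition bias the deconvolution method wins this comparison (a frozen
simulation in the test suite), which is why it is the recommended choice
for annotated single-cell data.

## Heterogeneity ranking and GSEA

`pca_gene_scores()` quantifies each gene's contribution to cell-to-cell
variance within a group (e.g. the malignant cells of one tumor): a PCA is
run on centered, **unscaled** log2(TPM + 1) values (scaling would erase
exactly the variance differences being measured), the smallest leading
set of PCs whose cumulative variance fraction reaches
`variance_threshold` (default 0.80) is kept, and the gene's score is the
sum of absolute loadings over those PCs. Variance fractions use the PC
eigenvalues over their total, i.e. variance of centered data. The sign of
a loading is arbitrary, so absolute values make the score well defined.
CV and SD are provided as simpler alternatives; as expected, CV inflates
low-abundance genes (a rank-correlation property asserted in the tests),
which is the main reason the PCA score is the default.

`enrichment_score()` implements the weighted running-sum GSEA statistic:
walking the descending ranking, hits add $|s|^{p}$ (normalized over the
set, exponent default 1), misses subtract $1/(N - n_{set})$, and the ES
is the extremum of the walk. Zero-score genes contribute zero hit weight,
the continuous limit of the formula. The implementation is verified to
1e-12 against a brute-force walk and against an established external
implementation of the same statistic. `preranked_gsea()` builds the null
from random gene sets of matched size drawn from the ranked universe
(gene-set permutation — the same null is used in the two-class mode,
where genes are ranked by the difference of class means on log2 values).
NES divides the ES by the mean magnitude of same-signed null scores, and
p is the add-one-smoothed fraction of same-signed null scores at least as
extreme. Ranking ties are broken lexicographically by gene id so runs are
bit-reproducible.

## Subtype rules

T cells: CD4 > 1 with CD8A < 1 is CD4+; the converse is CD8+; both above
1 is excluded (ambiguous/doublet); everything else — including values
exactly at the threshold — is explicitly `unassigned` rather than
silently dropped, so downstream enrichment inputs are auditable. Among
CD4+ cells, FOXP3 + CD25 > 2 defines Tregs and exact double-zero defines
Ths; CD25 is accepted under either the protein name or the gene symbol
IL2RA, whichever the matrix uses. Fibroblasts are k-means clustered
(k = 2, 10 restarts, fixed seed) on a marker panel after excluding cells
with FOS and VIM both < 1; the cluster with the higher mean expression of
the designated CAF markers is named CAF, making the labeling invariant to
arbitrary cluster indices. The packaged marker panel is a synthetic
curation of canonical CAF (matrix/activation: FAP, THY1, PDPN, PDGFRA,
collagens, DCN, MMP2) versus myofibroblast (contractile: ACTA2, MYL9,
MYLK, TAGLN, MCAM) markers and is fully user-overridable.

## Signature scores and agreement statistics

`cell_set_score()` is the unweighted mean log2(TPM + 1) of a set's genes
per cell, computed on the same scale as the pathway definition of
expression and deliberately *not* re-normalized per cell.
`relative_mutual_information()` normalizes mutual information by the
minimum of the two label entropies (natural logs); min-entropy
normalization was chosen so that a partition that refines another —
carrying all of its information — scores exactly 1; `max`, `mean` and
`sqrt` normalizations are available for users who prefer a stricter
notion of agreement. The degenerate both-sides-single-cluster case is
defined as 1 and flagged.

## What the synthetic generator emulates

`generate()` draws per-gene LogNormal baseline expression with i.i.d.
log2 noise, then layers the structures the pipeline is designed to
detect: planted pathway fold-changes in chosen cell types;
patient-specific Gaussian shifts on a random 20% of genes confined to
malignant cells (`tumor_effect_sd`, default 0.5 log2 units); a shared
standard-normal latent factor loading on named sets (the hypoxia-like
axis coupling glycolysis and OXPHOS programs); optional per-set noise
inflation (`set_noise_mult`) for planting high-variance programs;
per-cell log-normal library scaling (sd 0.3); and expression-dependent
dropout on a logistic curve (midpoint 1, slope 1 on log2 expression), so
low-expressed genes drop out more — the confound that motivates
restricting imputation to high-dropout genes. Columns are renormalized to
a TPM sum of 1e6 before logging. Defaults (1000 genes, 20 disjoint
25-gene sets, 250 malignant cells over 2 tumors plus 150 T cells, 100 B
cells, 100 macrophages) are sized to a realistic desk-scale
microenvironment with every group comfortably above the 50-cell filter.

The generator does **not** emulate: count-level sampling noise (it works
on the TPM scale directly; NB count simulation would duplicate what the
TPM↔pseudo-count conversion already exercises), doublets, batch effects,
ambient RNA, or realistic gene-gene co-expression beyond the planted
factors. Passing tests therefore demonstrate correctness of the
statistical machinery under known ground truth, not performance on any
particular real tissue.

## Numerical choices and degenerate inputs

- Quantiles use R's default type-7 definition everywhere.
- Imputation (`impute_dropouts()`, default neighbor-mean with k = 10)
  only ever touches zeros of genes with dropout above the threshold;
  the contract (low-dropout genes bit-identical, nonzero entries never
  modified, imputed values non-negative) is enforced on the output of
  *any* pluggable backend.
- Pseudo-bulk pooling un-logs to TPM, averages, and re-logs: the mean of
  TPM is the natural "pool" (a sum would only rescale TPM), and pooling
  a single cell is the identity.
- Constant matrices are an error for PCA (no variance to decompose);
  constant genes are excluded with a warning from correlation analyses;
  zero-variance signature scores make correlations flagged-undefined
  rather than errors.
- Every stochastic function takes an explicit seed and is bit-reproducible.

## Problem sizes used in the validation suite

The packaged checks run at desk scale, chosen to finish in minutes while
keeping binomial noise well inside the asserted margins: null calibration
on 500 genes × 200 cells (4 types, 100 pathways, 200 shuffles); planted
+1 log2 effect recovery over 50 generator replicates at 500 shuffles;
deconvolution factor recovery on 500 genes × 200 cells against
LogNormal(0, 0.25) truth; GSEA/PCA oracle equivalence on 100 random
instances; heterogeneity power over 20 replicates of a √5-noise-inflated
set. `scripts/acceptance.R` re-runs the same workflows end-to-end and
writes every measured number as JSON.

## Known limitations

Pathway scores are relative across the cell types present in the
dataset: adding or removing a cell type shifts every gene's reference
mean, so scores are comparable within an analysis, not across datasets.
The permutation null assumes exchangeable cells under label shuffling and
ignores within-tumor correlation of malignant cells. GSEA uses gene-set
permutation, which tests enrichment against random gene sets rather than
phenotype permutation's sample-label null. The imputation default is a
deliberately simple neighbor-mean; it satisfies the stated contract but
is not a model-based imputer, and the backend is pluggable for users who
need one.
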