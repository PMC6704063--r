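# scMetPath

Metabolic pathway activity and heterogeneity analysis for tumor
single-cell RNA-seq.

Single-cell RNA-seq of tumors mixes malignant cells with the immune and
stromal cells of the microenvironment, and each of these populations runs
its metabolism differently. `scMetPath` is for researchers who want to ask,
from a gene × cell expression matrix: which metabolic pathways are more or
less active in each cell type, is that difference statistically meaningful,
which pathways drive cell-to-cell variability within a tumor, and how do
classic programs such as glycolysis, oxidative phosphorylation (OXPHOS) and
the hypoxia response co-vary across single cells?

## The model

Expression is analyzed as log2(TPM + 1). For gene *i* and cell type *j*,
the cell-type mean is

    E_ij = (1 / n_j) Σ_k g_ik          (mean over the n_j cells of type j)

and the **relative expression** compares it with the gene's average over
all *N* cell types:

    r_ij = E_ij / ((1/N) Σ_j E_ij)

so r > 1 marks above-average expression in that cell type, and every
gene's r averages to exactly 1 across cell types. The **pathway activity
score** of pathway *t* in cell type *j* is the weighted average over its
member genes

    p_tj = Σ_i w_i r_ij / Σ_i w_i ,   w_i = 1 / (# pathways containing gene i),

after excluding outlier genes whose relative expression exceeds 3× the
pathway's 75th percentile or falls below 1/3 of its 25th percentile.
Significance comes from a label-permutation test: cell-type labels are
reshuffled, the whole chain is recomputed per shuffle, and the observed
score is compared with the null scores on the side it deviates (doubled to
a calibrated two-sided p-value by default; the raw directional tail is
available via `p_type = "directional"`).

Around this core the package provides:

- **Normalization evaluation** — RLE, TMM, upper-quartile and pooling
  deconvolution size factors (via DESeq2, edgeR and scran), restricted to
  reference genes with dropout < 0.75, ranked by how well each method
  aligns relative-expression distributions across cell types.
- **Heterogeneity ranking** — per-gene PCA score (sum of absolute
  loadings over the top principal components covering ≥ 80% of variance),
  plus CV and SD alternatives, fed into a from-scratch pre-ranked GSEA
  with a gene-set permutation null.
- **Subtype classification** — threshold rules for CD4+/CD8+ T cells and
  Treg/Th subsets, and k-means CAF/myofibroblast separation of
  fibroblasts.
- **Signature analysis** — per-cell gene-set scores, score–score and
  gene–gene correlations, and relative mutual information between
  clusterings.
- **Synthetic data** — `generate()` draws tumor-microenvironment data
  with known planted effects (pathway up-regulation, patient-specific
  malignant shifts, a shared latent "hypoxia" axis, expression-dependent
  dropout) so every claim the package makes can be tested against ground
  truth.

## Worked example

Simulate a microenvironment in which T cells up-regulate one pathway by
+1 log2 unit, then score and test all pathways:

```r
library(scMetPath)

sim <- generate(simulation_spec(
  planted_effects = data.frame(pathway = "PATHWAY_01",
                               cell_type = "Tcell", log2fc = 1),
  seed = 7))
act <- permutation_test(sim$matrix, sim$annotation, sim$gene_sets,
                        n_perm = 1000, seed = 7)
subset(act, pathway == "PATHWAY_01")
#>     pathway      group     score     p_value n_genes_used n_outliers
#>  PATHWAY_01      Bcell 0.8976986 0.001998002           24          1
#>  PATHWAY_01 Macrophage 0.8845000 0.001998002           24          1
#>  PATHWAY_01  malignant 0.9220749 0.001998002           24          1
#>  PATHWAY_01      Tcell 1.2957265 0.001998002           24          1
```

The planted pathway scores 1.30 in T cells (significantly above the
cross-type average, p ≈ 0.002 at 1000 permutations) and correspondingly
below 1 in the other cell types — the score is relative, so up-regulation
in one type necessarily depresses the others. One member gene was removed
by the outlier rule (`n_genes_used` 24 of 25). Per-cell signature scores
of two unperturbed pathways stay uncorrelated:

```r
s1 <- cell_set_score(sim$matrix, sim$gene_sets$PATHWAY_02)
s2 <- cell_set_score(sim$matrix, sim$gene_sets$PATHWAY_03)
score_correlation(s1, s2)$estimate
#> -0.074
```

A command-line wrapper with subcommands (`simulate`, `preprocess`,
`normalize-eval`, `pathway-activity`, `heterogeneity`, `gsea`,
`subtypes`, `correlate`, `run-all`) is installed at
`inst/scripts/scmetpath`:

```sh
Rscript inst/scripts/scmetpath simulate --out demo --seed 2 --planted PATHWAY_01:Tcell:1
Rscript inst/scripts/scmetpath pathway-activity --matrix demo/matrix.tsv \
  --annotation demo/annotation.tsv --gmt demo/gene_sets.gmt \
  --n-perm 1000 --seed 2 --out demo/activity.tsv
```

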