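# cogex

Clusters-of-gene-expression (CoGE) analysis for stepwise tumor-progression
cell-line series.

## The problem

Some tumor models come as an *ordered* series of cell lines with increasing
malignant potential — for example an oral tongue squamous-cell-carcinoma
parental line and successive generations re-isolated from lymph-node
metastases. Bulk RNA-seq of each line (FPKM per gene, several replicates per
line) then asks three questions that generic one-contrast DE tools do not
answer directly:

1. Which genes change between each parental line and its *derived* line, and
   in which direction?
2. What regulatory *pattern* does each gene follow across two successive
   comparisons — e.g. "down-regulated in both steps", "up in the first step
   only", "expressed at a constant level yet reproducibly shifted"?
3. Which cancer hallmarks do those changes serve, and which genes shift
   consistently along the whole series (candidate progression biomarkers)?

`cogex` implements this workflow for anyone with an FPKM matrix, a sample
sheet giving the line order, and (optionally) pathway gene sets annotated to
the hallmarks of cancer.

## The model

**Differential expression.** For each successive pair (parental *P*, derived
*D*) and each gene, a two-sided pooled-variance Student t-test on the
replicate FPKM values gives *p*; Benjamini–Hochberg correction within the
pair gives *q* (step-up: with p-values sorted ascending,
`q_(i) = min_{j>=i} p_(j) * m / j`, capped at 1). A gene is a DEG when
*p* < α (mode `"p"`) or *q* < α (mode `"q"`), α = 0.05.

**Direction labels.** With mean FPKM `mP`, `mD` and ratio `r = mD / mP`, a
DEG is labeled

| condition                | label               |
|--------------------------|---------------------|
| `mP > 0, mD = 0`         | `EXCLUSIVE_PARENTAL`|
| `mP = 0, mD > 0`         | `EXCLUSIVE_DERIVED` |
| `r < 0.8`                | `DOWN`              |
| `0.8 <= r <= 1.2`        | `CONTINUUM`         |
| `r > 1.2`                | `UP`                |

Non-significant genes are `NOT_DEG`. `CONTINUUM` genes are statistically
detectable changes with negligible fold change (±0.2 around 1).

**CoGE.** Crossing a gene's label in a predecessor comparison with its label
in the focal comparison assigns one of 11 clusters of gene expression
(exclusive parental/derived, continuum, exclusive parental/derived
down/up-regulated, common down, common up, and the two discordant
down-up/up-down patterns). See `?assign_coge` for the precedence rules.

**Hallmark contributions.** Pathway gene sets (GMT) plus a pathway-to-hallmark
map (a pathway may serve several of the 8 + 2 hallmarks) give per-hallmark
gene sets `G(h)`. Against a reference hallmark (invasion and metastasis by
default), the *absolute* contribution of hallmark *h* is the shared pathway
and gene counts `|P(h) ∩ P(ref)|`, `|G(h) ∩ G(ref)|`; the *relative*
contribution in CoGE cluster *c* is
`pct(h, c) = 100 · |G(h) ∩ G(ref) ∩ C(c)| / |G(h) ∩ C(c)|` (0 when the
denominator is empty). Per comparison, a hallmark's total is the plain mean
of its 11 cluster percentages; overall, the mean of the per-comparison
totals, ranked descending.

**Progression-consistent genes.** Genes that are DEGs in *every* successive
comparison with the identical direction label.

## Worked example

The package ships the published 26-gene progression table (mean FPKM for the
ZsG → LN1 → LN2 → LN3 series) as a checksummed fixture:

```r
library(cogex)
cons <- find_consistent_genes(comparisons_from_means(table3_means()))
table(cons$label)
#> CONTINUUM      DOWN        UP
#>        10        15         1
cons[cons$label == "UP", ]
#>   gene_id label  ratio_1  ratio_2  ratio_3
#> 6   ENPP1    UP 1.288369 1.441438 2.519559
```

All 26 genes keep one label across the three transitions — 15 down, 10
continuum, 1 up (ENPP1, whose FPKM ratio grows 1.29 → 1.44 → 2.52).

On synthetic data with known ground truth:

```r
cfg <- simulation_config(seed = 42)          # 5 lines x 7 replicates, cv 0.10
sim <- generate_expression(cfg)
ann <- generate_annotation(cfg, sim$truth)
res <- run_pipeline(sim$expr, ann)

res$comparisons[["line2 vs line3"]][1:3, c("gene_id", "ratio", "p_value", "label")]
#>        gene_id     ratio      p_value label
#> g00001  g00001 0.4014875 1.116745e-12  DOWN
#> g00002  g00002 0.2177785 1.953525e-12  DOWN
#> g00003  g00003 0.3932950 8.115005e-08  DOWN

table(factor(res$coge[["line2 vs line3"]]$cluster, levels = coge_clusters()))
#> EXCLUSIVE_PARENTAL  EXCLUSIVE_DERIVED          CONTINUUM ... COMMON_DOWN COMMON_UP
#>                  4                  7                 69 ...          60        60

nrow(res$consistent)
#> [1] 177     # 60 DOWN + 60 UP + 57 of 60 planted CONTINUUM genes recovered
```

`write_results(res, "out/")` writes `deg_table.tsv`, `coge_table.tsv`,
`consistent_genes.tsv`, the three contribution CSVs and a `summary.json`.

## Command line

```sh
Rscript inst/scripts/cogex simulate --seed 1 --outdir sim/
Rscript inst/scripts/cogex run --expr sim/expression.tsv --samples sim/samples.tsv \
    --gmt sim/pathways.gmt --hallmarks sim/hallmark_map.tsv --outdir out/
Rscript inst/scripts/cogex fixtures --name table3 --outdir fixtures/
```

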