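# scgap

Rare cell type detection for single-cell RNA-seq, built on the geometry of
per-cell nearest-neighbour distance curves.

## The problem and the idea

Global clustering loses minor populations: a handful of cells — down to a
pair of doublet-scale outliers in tens of thousands — contribute almost
nothing to any global objective. But a tight rare cluster of size *n*
leaves a sharp local signature. For each of its members *m*, the first
*n − 1* nearest neighbours are the other members, and the *n*-th neighbour
sits across the inter-cluster *gap*, so the distance curve
*D*⟨*m*,*k*⟩ (distance from cell *m* to its *k*-th nearest neighbour in
50-dimensional PCA space) jumps at exactly *k* = *n*.

`scgap` locates that jump with discrete derivatives along *k*:

    ΔD⟨m,k⟩  = D⟨m,k⟩ − D⟨m,k−1⟩            (D⟨m,0⟩ := 0)
    ΔΔD⟨m,k⟩ = 2·ΔD⟨m,k⟩ − ΔD⟨m,k−1⟩ − ΔD⟨m,k+1⟩

For every candidate size *k* it measures the right-skew of the
neighbour-smoothed ΔΔD distribution after Tukey-fencing the background and
appending two copies of the candidate cluster's mean value; skewness > 2
flags *k* as a candidate. A candidate is confirmed only if the top cell
and its *k* − 1 nearest neighbours end up as exactly *k* cells carrying
that tag (the count-equals-*k* rule), which is what keeps the false-positive
rate low on homogeneous data. See `vignettes/rare-cell-detection.Rmd` for
the full model, parameter rationale and limitations.

The package also ships a minimal Splat-style gamma-Poisson simulator with
group-wise differential expression and logistic dropout (the benchmarking
world for the method), evaluation metrics (F1, sensitivity/specificity,
rank AUC, Wilcoxon + BH differential expression), Matrix Market / dense
text IO, and a CLI.

## Worked example

Simulate a 1200-cell three-group population (ratio 10:45:45, 5000 genes,
`de_prob = 0.6`), subsample 7 rare + 500 + 500 cells, and run the
detector:

```r
library(scgap)

p   <- sim_params(n_genes = 5000, group_sizes = c(120, 540, 540),
                  de_prob = 0.6, seed = 42)
d   <- plant_rare_group(p, rare_size = 7, major_sizes = c(500, 500), seed = 42)
res <- detect_rare_cells(d$counts, seed = 1)
print(res)
#> <rare_cell_result> 1 confirmed rare cluster(s)
#>   R1: size 7, skewness 21.96, top cell cell0025

pred <- names(res$per_cell_label)[!is.na(res$per_cell_label)]
cc   <- confusion_counts(pred, d$rare_cells, names(res$per_cell_label))
f1_score(cc)                               #> 1
sensitivity_specificity(cc)                #> sensitivity 1, specificity 1
rank_auc(res$per_cell_score, d$rare_cells) #> 1
```

The detector found one cluster whose size (7), membership and skewness
(21.96, far above the threshold of 2) identify the planted rare group
exactly: F1 = 1 against ground truth, and the continuous per-cell score
ranks all 7 planted cells above every abundant cell (AUC = 1).

Key knobs (all exposed in `run_config()` / the CLI): gene/cell filters
(3 cells, 200 genes), normalization (`median` or `none`), number of PCs
(50), neighbourhood size `k_max` (defaults to
`min(max(50, ceil(0.05·N)) + 10, N−1)`), metric (`euclidean` or
`manhattan`), skewness threshold (2), fence convention, seed.

## Command line

```sh
Rscript inst/cli/scgap.R simulate --out sim/ --n-genes 5000 \
    --group-sizes 120,540,540 --de-prob 0.6 --rare-size 7 \
    --major-sizes 500,500 --seed 42
Rscript inst/cli/scgap.R run --input sim/matrix.mtx --out out/ --seed 1
Rscript inst/cli/scgap.R evaluate --cells out/cells.tsv --truth sim/labels.tsv
Rscript inst/cli/scgap.R iterate --input sim/matrix.mtx --out out/ --rounds 3
```

`run` writes `cells.tsv` (cell, label, score), `clusters.json` (members,
sizes, skewness, parameters) and `config.json` (the resolved
configuration); re-running with the same inputs reproduces them
byte-for-byte.

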