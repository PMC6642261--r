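# DIselect

Discriminative-Index gene selection for expression data.

## What it does and who it is for

Given a normalized gene-expression matrix (bulk or single-cell RNA-seq;
samples × genes, nonnegative values such as RSEM-normalized counts) and a
class label per sample, DIselect ranks every gene by its power to
discriminate the classes, so that a compact biomarker panel can be read
off the top of the list. It is aimed at transcriptomics analysts who have
more differentially expressed genes than they can act on and need a
principled ordering rather than another p-value list.

## The method

A one-layer softmax regression is trained on the expression matrix:

    P(class k | x) = exp(θₖᵀx + bₖ) / Σₗ exp(θₗᵀx + bₗ)

by full-batch gradient descent (seeded, gradient-norm-clipped). With
X̂ᵏ the class-k average expression profile and WXᵏⱼ = θᵏⱼ · X̂ᵏⱼ, the
**Discriminative Index** of gene j sums over all unordered class pairs:

    DIⱼ = Σ_{k₁<k₂} | WXᵏ¹ⱼ − WXᵏ²ⱼ |

(K(K−1)/2 terms per gene; a single absolute difference when K = 2).
Because trained weights depend on their random initialization, the
ranking is averaged over many re-initialized runs (reference setting
10,000 iterations; 50–100 suffice at desk scale). The package also
implements the surrounding evaluation workflow: class-ratio-preserving
splits, gradient-boosted-tree / softmax classification of reduced gene
sets, leave-one-out cross-validation, top-k accuracy curves, ranked-list
overlap, and a synthetic-cohort generator with planted discriminative
genes.

## Worked example

```r
library(DIselect)

# a 90/10-imbalanced cohort of 100 samples x 200 genes with 4 planted
# discriminative genes (+500 expression units on the cancer class)
sim <- simulateExpression(nPerClass = c(cancer = 90, normal = 10),
                          nGenes = 200, plantedGenes = 1:4,
                          plantedShift = 500, seed = 42)
sim$dataset
#> DIDataSet: 100 samples x 200 genes
#> classes (2): cancer (90), normal (10)

ranking <- rankGenes(sim$dataset, trainControl(), nIter = 50, seed = 42)
head(rankingTable(ranking))
#>   rank gene_id  mean_di
#> 1    1 gene001 36.90785
#> 2    2 gene004 35.75348
#> 3    3 gene003 31.27083
#> 4    4 gene002 28.94490
#> 5    5 gene012 13.05374
#> 6    6 gene009 11.76804

recoveryRate(ranking, sim$truth, 4)
#> [1] 1
```

All four planted genes occupy the top four ranks, with a clear mean-DI
gap to the first noise gene — `recoveryRate` of 1 means the panel
read off the top of the list is exactly the planted truth. A
stratified 50/50 split then scores a classifier on the 4-gene panel:

```r
parts <- stratifiedSplit(sim$dataset, c(0.5, 0.5), seed = 42)
genes <- topGenes(ranking, 4)
res <- trainAndScore(reduceFeatures(sim$dataset[, parts[[1]]], genes),
                     reduceFeatures(sim$dataset[, parts[[2]]], genes),
                     seed = 42)
res$accuracy
#> [1] 0.96
res$confusion
#>         predicted
#> observed cancer normal
#>   cancer     45      0
#>   normal      2      3
```

0.96 is the plain fraction of the 50 held-out samples classified
correctly; the confusion table shows the errors fall in the minority
class, the usual caveat of plain accuracy under 9:1 imbalance.

The same workflow is available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "diselect.R", package = "DIselect"))')
Rscript $CLI simulate --out-prefix cohort --seed 42
Rscript $CLI rank --expression cohort_expression.tsv --labels cohort_labels.tsv \
                  --output ranking.tsv --n-iter 100 --top-c 14 --seed 42
Rscript $CLI overlap --ranking-a ranking.tsv --ranking-b other_ranking.tsv \
                     --depths 100,500 --output overlap.tsv
```

## Documentation

The methods vignette (`vignettes/discriminative-index.Rmd`) describes
the model and its assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate,
and the package's numerical and design choices.
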