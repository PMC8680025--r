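# mdlgene

Multi-label prediction of aging-related disease genes from heterogeneous
biological data, combining diffusion-based network embedding with a
two-stage modular neural classifier, plus the surrounding evaluation and
candidate-gene recommendation machinery.

## Who this is for

Computational biologists who have, for one set of genes:

* one or more weighted gene–gene networks (protein interactions, annotation
  similarity, ...),
* several gene × feature tables of very different dimensionality (boolean
  pathway/annotation memberships, continuous expression summaries),
* a sparse, hierarchical gene × disease annotation matrix,

and who want calibrated per-disease scores for every gene — in particular
for the *unannotated* genes, whose "negative" labels often just mean nobody
has looked yet.

## The method

**Network embedding.** Each network with adjacency `A` is summarised by
random walk with restart. With the column-stochastic transition matrix
`B[i,j] = A[i,j] / Σ_i A[i,j]`, the diffusion state of gene `i` is the fixed
point of

```
s_i = (1 − p_r) · B · s_i + p_r · e_i
```

where `p_r` is the restart probability and `e_i` the indicator vector of
gene `i`. The log-transformed diffusion-state matrices of all networks are
stacked and factorised by a truncated SVD (the Mashup approach), so every
gene gets one shared `d`-dimensional latent vector across all networks —
e.g. 800 dimensions instead of a ~15,000-dimensional diffusion profile, a
~95% reduction.

**Modular deep classifier.** Each feature dataset (the embedding included)
is compressed by its own four-hidden-layer encoder (64/32/32/16 units, ReLU,
dropout 0.5, tanh output head over the disease labels). The 16-unit
bottleneck activations of all encoders are concatenated and fused by a
second encoder (32/24/16) that produces the final per-label scores in
[0, 1]. Per-dataset encoders let an 800-column embedding and a 300-column
pathway table contribute on an equal footing instead of sharing one encoder.

**Evaluation and recommendation.** Per-label AUROC under k-fold
cross-validation (fold-averaged), naive "research-level" and L2-logistic
baselines, Welch t and Mann–Whitney U seed-replicated method comparisons,
and a consensus recommendation step: across repeated runs, the top-k scored
negative genes per disease are recorded, genes recurring in at least a
threshold number of runs are recommended (with Ave./Hig./Low. P summaries),
and a one-sided rank test checks that the recommended block genuinely
separates from the genes ranked just below it.

A synthetic-data generator with planted community structure, community-
linked labels, and "hidden positives" (true associations released as
negatives) makes the whole pipeline testable end to end without external
data.

## Worked example

```r
library(mdlgene)

study <- generate_benchmark_suite("tiny")   # 60 genes, 3 communities, 6 labels
cfg <- benchmark_config(seeds = 1:3, n_folds = 5, embedding_dim = 8,
                        top_k = 5, min_frequency = 2)
res <- run_pipeline(study, cfg)
print(res)
#> Pipeline result over 3 seed(s)
#>   mean per-fold macro AUROC by method:
#>     MDL    0.7994
#>     Naive  0.5292
#>     LR     0.8279

head(res$consensus$diseases$Disease.A, 3)
#>    gene frequency     ave_p     hig_p     low_p
#> 1 g0040         3 0.9835141 0.9935932 0.9773501
#> 2 g0004         3 0.9665010 0.9989984 0.9374177
#> 3 g0002         2 0.9812816 0.9926061 0.9699571

head(res$neighbor_test, 2)
#>         disease      p_value
#> 1 Class_Disease 6.253323e-07
#> 2     Disease.A 4.409560e-06
```

The consensus table reads: gene `g0040` was in the per-run top 5 unannotated
genes for `Disease.A` in all 3 runs, with mean predicted probability 0.98
against 0.24 for the remaining negatives (`res$consensus$rest_mean`). The
neighbour-test p-values say the recommended block scores significantly
higher than the next-ranked block. At this toy scale the deep model has no
edge over plain logistic regression; on the 500-gene benchmark
(`generate_benchmark_suite("small")`, the scale used by the acceptance
script) the two-stage model reaches macro AUROC ≈ 0.89 against ≈ 0.79 for
logistic regression on the raw features and ≈ 0.51 for the naive baseline.

A command-line wrapper is installed at
`system.file("scripts", "mdl", package = "mdlgene")`:

```sh
mdl simulate --scale small --seed 1 --out data/
mdl embed --data data/ --dim 32 --out mashup.tsv
mdl run --data data/ --out results/
```

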