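# dompath

Link prediction between **protein structural domains and diseases** on a
five-layer heterogeneous information network.

Protein structural domains are conserved, independently folding functional
units; a dysfunctional domain can be what actually drives the disease
phenotype of its host protein, but curated domain–disease annotations are
essentially nonexistent. `dompath` infers candidate associations by
*guilt-by-association* over a global heterogeneous network with three node
sets — domains (D), proteins (P), diseases (S) — and five binary adjacency
layers: domain–protein composition, protein–protein interaction,
protein–disease association, disease–disease phenotype similarity, and a
domain–disease reference layer obtained by transferring the disease links
of single-domain proteins onto their only domain.

## Method

For a meta-path `Π = D → t₁ → … → disease` (a typed node sequence, e.g.
`DPSS` = domain → protein → disease → disease), the **commuting matrix**

```
M(Π) = A₁ A₂ ⋯ A_L
```

is the product of the adjacency matrices along the path's edges; entry
`M[i, j]` counts the concrete walks from domain *i* to disease *j* that
follow the meta-path's types. A canonical registry of 37 such meta-paths
(2 of length 2, 4 of length 3, 11 of length 4, 10 of length 5, 10 of
length 6) defines the feature space. Counts are optionally **random-walk
normalized** per domain, `RW[i, j] = M[i, j] / Σⱼ M[i, j]`, giving
per-domain outgoing proportions. The standard feature sets are:

| preset     | columns | content                         |
|------------|---------|---------------------------------|
| TF1        | 6       | counts, path lengths ≤ 3        |
| TF2        | 17      | counts, lengths ≤ 4             |
| TF3 = Feature-I | 27 | counts, lengths ≤ 5             |
| TF4        | 37      | counts, lengths ≤ 6             |
| Feature-II | 54      | lengths ≤ 5 counts + RW values  |

Labeled pairs are the transferred reference associations (positives) plus
uniformly sampled non-associated pairs at 1:1; a stratified 2/3–1/3 split
(666 positives give 444+444 training and 222+222 test pairs) feeds a
gradient-boosted tree classifier tuned by 3-fold cross-validated grid
search over `n_estimators`, `max_depth`, `min_child_weight`, `gamma`,
`colsample_bytree`, `reg_alpha` (random forest, SVM and naive Bayes
baselines included). Held-out positive reference edges are removed from
the network before features are computed ("leakage control"); a stricter
mode additionally masks each evaluated pair's own reference edge during
its own feature computation. Performance is reported as trapezoidal ROC
AUC and F1 = 2TP/(2TP+FN+FP).

Because the real source databases cannot be redistributed, the package
ships a seedable **synthetic generator**: diseases fall into similarity
clusters, proteins work inside one cluster and carry one or more domains,
and the reference layer is the transfer rule applied to the generated
single-domain proteins — so the planted truth is recoverable by
construction, and a matched ablation (labels decoupled from every layer)
gives the AUC ≈ 0.5 negative control.

## Worked example

```r
library(dompath)

cfg <- synthetic_config(seed = 11)        # 200 domains, 400 proteins, 60 diseases
bundle <- generate_study(cfg, mask_mode = "strict")
nrow(bundle$truth$positives)              # planted reference associations
#> [1] 434

train_ft <- feature_set(bundle$masked_network,
                        bundle$train[, c("domain", "disease")], "Feature-II")
test_ft  <- feature_set(bundle$masked_network,
                        bundle$test[, c("domain", "disease")], "Feature-II")
ncol(train_ft) - 2                        # 27 counts + 27 RW features
#> [1] 54

model <- tune_and_train(train_ft, bundle$train$label,
                        classifier_spec("gbt", grid = list(n_estimators = 300),
                                        seed = 11))
evaluate(model, test_ft, bundle$test$label)
#> Evaluation on 290 pairs: AUC = 0.9761, F1 = 0.9697 (threshold 0.50)
#>   confusion: TP=144 FP=8 FN=1 TN=137
```

The AUC says a random true association outranks a random non-association
98% of the time on held-out pairs; the planted cluster signal has been
recovered from path counts alone. On an ablated network
(`synthetic_config(seed = 11, ablate_signal = TRUE)`) the same pipeline
drops to chance level, confirming that the features — not an artifact of
the protocol — carry the signal.

Real edge lists are loaded with `read_edge_table()` (TSV, optional
weight threshold such as a STRING combined score ≥ 400) and assembled
with `build_hetnet()`; `run_full()` and the command line
(`inst/cli/dompath.R` with subcommands `simulate`, `features`,
`train-eval`, `full`) orchestrate end-to-end runs.

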