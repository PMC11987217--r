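---
title: "Meta-path features for domain-disease association prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-path features for domain-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dompath)
```

## The model

`dompath` treats domain–disease inference as link prediction on a
heterogeneous information network `G = (H, F)` with node sets
`H = D ∪ P ∪ S` (structural domains, proteins, diseases) and five edge
layers: domain–protein composition (D–P), protein–protein interaction
(P–P), protein–disease association (P–S), disease–disease phenotype
similarity (S–S), and a domain–disease reference layer (D–S). All layers
are stored as binary sparse matrices — an observed link is 1, anything
else is 0 — and the reversed orientation of any layer is simply the
transpose, so five matrices describe the eight directed relations.

A *meta-path* is a typed node sequence from domain to disease, written
over the alphabet D/P/S (for example `DPSS`: domain → protein → disease →
disease). Its *commuting matrix* is the left-to-right product of the
adjacency matrices along the edge sequence; entry `(i, j)` counts the
concrete walks from domain `i` to disease `j` whose node types follow the
meta-path. Two conventions matter and are fixed throughout:

* **Walks, not simple paths.** Matrix products count walks with possible
  node revisits. The test-suite oracle (`brute_force_path_count()`)
  enumerates concrete walks explicitly and must match the product
  entry-for-entry, so the convention is pinned by tests rather than
  prose.
* **Exact integer counts.** Products are accumulated in double precision,
  which is exact for counts below 2^53 — unreachable at any size this
  package is meant for (the count would have to exceed 9·10^15 walks for
  one pair).

### The canonical registry

Feature extraction uses a fixed list of 37 meta-paths: 2 of length 2, 4
of length 3, 11 of length 4, 10 of length 5 (identified `C1`…`C27`), and
10 of length 6 identified by their letter sequences. The list is
deliberately **hard-coded, not enumerated**: the canonical set is a
curated selection, and several schema-valid walks of the same lengths
(e.g. `DSSS`, `DSDS`) are not members. Reproducing the printed table
verbatim is the only faithful choice; `parse_metapath()` accepts any
valid name so users can extend the registry themselves.

### Random-walk normalization

Counts are turned into per-domain proportions by dividing each row of a
commuting matrix by its row sum: `RW[i, j] = M[i, j] / Σ_j M[i, j]`. The
sum runs over the **full disease universe**, not just the pairs being
scored — this is the only reading consistent with a row-wise
normalization, and it is what the tests assert against an explicitly
materialized normalized matrix. Rows that sum to zero are left at zero
(0/0 → 0), which preserves sparsity and keeps every value in [0, 1].

Feature presets stack these blocks: `TF1`/`TF2`/`TF3`/`TF4` are
cumulative count sets for maximum lengths 3/4/5/6 (6/17/27/37 columns);
`Feature-I` is the 27 counts of lengths ≤ 5 and `Feature-II` appends
their 27 RW values (54 columns), with the counts block always a prefix so
Feature-I is literally a column subset of Feature-II.

## Labeled pairs and leakage control

There is no curated reference set of structural-domain–disease
associations, so positives are obtained by the **single-domain transfer
rule**: if a protein consists of exactly one domain and is associated
with a disease, that (domain, disease) pair is labeled positive.
Negatives are sampled uniformly without replacement from the
non-positive pairs at a 1:1 ratio. By default the negative universe is
restricted to domains and diseases that appear in the positive set —
sampling over all nodes would produce negatives dominated by isolated
nodes that are trivially separable; both choices are available.

The split is stratified per label with `round(train_fraction · n)`
training members, which reproduces the reference arithmetic exactly: 666
positives and 666 negatives at 2/3 give 444 + 444 training and 222 + 222
test pairs.

Before features are computed, the D–S reference edges of **test
positives** are removed from the network (`mask_mode = "paper"`), so a
held-out pair's label is never encoded in its own features. Training
positives keep their edges in this mode. The package also offers
`mask_mode = "strict"`, which additionally zeroes each evaluated pair's
own reference edge during that pair's feature computation (implemented as
a per-pair vector–adjacency chain product, bit-identical to recomputing
the full matrix without the edge — a tested invariant).

The strict mode exists because training-positive self-edges are not a
harmless fidelity detail. Several meta-paths pass directly through a
pair's own D–S edge — `DPDS`, for instance, contains the term
(number of proteins carrying `d`) × `DS[d, s]` — so in paper mode such
features take systematically different values on training positives
(edge present) and test positives (edge removed). A flexible learner can
separate the training set on those features alone and then generalize
poorly, and the cross-validation used for tuning cannot detect the
problem because validation folds keep their edges too. For this reason
the package's *synthetic benchmark* (acceptance script and acceptance
tests) runs with strict masking: it is the protocol under which test AUC
measures recovery of the planted signal rather than the size of this
train/test shift. Paper mode remains the default everywhere else, and the
acceptance script reports the paper-mode benchmark AUC alongside the
strict one so the gap is visible rather than hidden.

## The classifier

The main model is gradient-boosted trees (binary logistic objective,
single-threaded for reproducibility). Grid search tunes six
hyperparameters — `n_estimators`, `max_depth`, `min_child_weight`,
`gamma`, `colsample_bytree`, `reg_alpha`; anything not tuned keeps the
library default — scored by mean AUC over stratified 3-fold
cross-validation, ties broken by first-in-grid order. The default grid
(`default_gbt_grid()`: 3·3·2·2·2·2 = 144 combinations) is sized for
desk-scale runs and fully overridable; the benchmark runs use a
single-point grid (`n_estimators = 300`) because tuning is not what those
runs measure. Random forest, SVM (probability outputs) and naive Bayes
baselines share the same interface and seed plumbing, with library
defaults.

Evaluation: ROC curves sweep the distinct score values, grouping tied
scores into one step, and AUC is the trapezoidal area — equivalent to the
Mann–Whitney pairwise statistic with ties counted ½, which the tests
verify on random instances. F1 = 2TP/(2TP+FN+FP) is computed at a fixed
probability threshold of 0.5 (no reference value exists for this choice;
0.5 is the natural operating point of a calibrated probabilistic
classifier), with the degenerate all-zero denominator defined as 0 plus a
warning.

## What the synthetic generator emulates — and what it does not

The generator produces the minimal mechanism that makes meta-path
features informative: **cluster-structured guilt-by-association**.
Diseases are partitioned into `n_disease_clusters` similarity clusters
(S–S dense within, sparse between); each protein belongs to one cluster
and links mostly to its cluster's diseases; proteins carry one or more
domains, with a controllable fraction forced to exactly one; the D–S
reference layer is the transfer rule applied to the generated
single-domain proteins, so the planted truth is *by construction* exactly
what `transfer_single_domain_associations()` recovers (a tested
invariant). Multi-domain proteins spread a domain's paths over several
clusters, which is what makes negatives genuinely confusable rather than
trivially separable.

Defaults (200 domains, 400 proteins, 60 diseases, 4 clusters,
`single_domain_fraction = 0.5`, about 1.8 within-cluster disease links
per protein, within-cluster similarity 0.6, noise rate 0.01, PPI density
0.02) are chosen so a full pipeline run takes seconds on one CPU while
leaving the planted signal strong but not saturated. The benchmark in the
acceptance script runs this configuration over five seeds; the split
arithmetic check uses a larger configuration (400 domains, 900 proteins,
80 diseases) so that at least 666 planted positives exist.

The **ablation control** deserves its own paragraph, because the obvious
implementation does not work. If one simply scrambles the
protein–disease layer and re-derives the labels from it, every positive
still owns the domain–protein–disease walk that defined it, and no
classifier can be driven to chance. If instead the labels are kept and
only the P–S layer is redrawn, positives still share reference edges with
cluster-mates of their diseases, and similarity-mediated paths (`DSS` and
relatives) retain real signal. The implemented control therefore decouples
labels from *every* layer: the truth-defining link draw runs on a
per-disease shuffle of the cluster assignment (so sibling positives of a
domain are no longer similar diseases), while the network's P–S layer is
an independent redraw under the original assignment. The marginal
statistics match the signal case; the mutual information between labels
and features does not. Residual test AUC slightly above 0.5 remains
possible for an honest reason: diseases with many planted positives
appear more often among test positives than among uniformly sampled
negatives, so global popularity features carry a little information even
when all pairing signal is gone.

What the generator does **not** emulate: the heavy-tailed degree
distributions of real domain, interaction and annotation databases; the
scale (hundreds of thousands of domains); identifier noise and mapping
ambiguity; disease similarity derived from phenotype text rather than
block structure. Passing the synthetic benchmark shows the machinery is
correct and can recover a planted association signal through meta-path
counting; it does not certify performance numbers on any real database.

## Numerical and degenerate-case decisions

* Square layers (P–P, S–S) are symmetrized from either input orientation
  and their diagonals forced to zero: protein self-interactions and a
  disease's similarity to itself would create degenerate walk instances
  (e.g. a `DSS` walk that uses the pair's own reference edge followed by
  a self-similarity hop). A tested consequence: `DSS[d, s]` gets no
  contribution from the pair's own edge.
* Edge weights (e.g. STRING combined scores) are used only for inclusive
  thresholding at load time (`min_weight`); the network itself is binary.
  No stance is taken on the similarity threshold for binarizing disease
  similarity scores — the loader exposes `min_weight` and the caller
  decides.
* Removing an absent reference edge is a no-op, so split plumbing can
  delete idempotently.
* Node indices contain observed labels only, in first-appearance order;
  a label occurring under two node types is a hard schema error.
* The walk-enumeration oracle refuses networks whose layer-size product
  exceeds 10^7 potential walks or that materialize more than 10^6 partial
  walks; it exists for verification, not production use.
* All randomness (generation, negative sampling, splitting, fold
  assignment, model fitting) flows from explicit integer seeds, with
  derived seeds kept inside the 32-bit range.

## Known limitations

* The registry's selection rule for lengths ≤ 5 is a fixed canonical list;
  there is no principled generator for "which walks count", and none is
  offered.
* Paper-mode leakage control is asymmetric by design (training positives
  keep their edges); the resulting optimism/shift is documented above and
  measurable with the strict mode, but not corrected.
* Real-data performance (including headline AUCs around 0.94 reported for
  this class of method on curated databases) is out of scope: it depends
  on database snapshots and identifier mapping that cannot be bundled.
  The package checks orderings that survive synthetic transfer — richer
  feature sets (more path lengths, counts + RW) do at least as well on
  average as poorer ones — as stochastic trends, not as point estimates.
* `evaluate()` reports a single-threshold F1; threshold selection or
  calibration is left to the user.
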