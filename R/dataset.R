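## Labeled pair construction: single-domain transfer positives, sampled
## negatives, stratified splits and leakage-controlled networks.

#' Transfer single-domain-protein associations to their domains
#'
#' There is no manually curated reference set of domain-disease
#' associations, but a protein that consists of exactly one structural
#' domain passes its disease associations to that domain.  A pair (d, s)
#' is emitted iff some protein contains d as its only domain and is linked
#' to disease s; duplicates (several such proteins) are collapsed.
#'
#' @param network A `hetnet` with domain-protein and protein-disease
#'   layers.
#' @return Data frame with columns `domain`, `disease`, ordered by node
#'   index.
#' @export
transfer_single_domain_associations <- function(network) {
  stopifnot(inherits(network, "hetnet"))
  dp <- network$adj$DP
  ps <- network$adj$PS
  single <- which(Matrix::colSums(dp) == 1)
  if (!length(single))
    return(data.frame(domain = character(0), disease = character(0),
                      stringsAsFactors = FALSE))
  m <- dp[, single, drop = FALSE] %*% ps[single, , drop = FALSE]
  tr <- Matrix::summary(as(m, "TsparseMatrix"))
  out <- data.frame(domain = network$nodes$domain[tr$i],
                    disease = network$nodes$disease[tr$j],
                    stringsAsFactors = FALSE)
  out <- out[order(out$domain, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample negative (unrelated) pairs
#'
#' Draws pairs uniformly without replacement from the candidate domain x
#' disease universe minus the positive set.  By default the candidates are
#' the domains and diseases that appear in the positive set, which keeps
#' negatives comparable to positives instead of being dominated by
#' isolated nodes; pass explicit vectors for the full universe.
#'
#' @param positives Data frame of positive (domain, disease) pairs.
#' @param domains,diseases Candidate label vectors; default: those in
#'   `positives`.
#' @param ratio Negatives per positive (default 1, the 1:1 design).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Data frame with columns `domain`, `disease`.
#' @export
sample_negatives <- function(positives, domains = NULL, diseases = NULL,
                             ratio = 1, seed = 1L) {
  pf <- as_pair_frame(positives)
  domains <- domains %||% unique(pf$domain)
  diseases <- diseases %||% unique(pf$disease)
  nd <- length(domains); ns <- length(diseases)
  n_neg <- round(ratio * nrow(pf))
  pos_in <- pf[pf$domain %in% domains & pf$disease %in% diseases, , drop = FALSE]
  pos_id <- (match(pos_in$domain, domains) - 1) * ns + match(pos_in$disease, diseases)
  n_universe <- as.numeric(nd) * ns
  if (n_neg > n_universe - length(unique(pos_id)))
    stopf("not enough non-positive pairs: need %d, universe has %g",
          n_neg, n_universe - length(unique(pos_id)))
  set.seed(seed)
  if (n_universe <= 2e6) {
    cand <- setdiff(seq_len(n_universe), pos_id)
    ids <- sample(cand, n_neg)
  } else {
    # rejection sampling for large universes
    ids <- integer(0)
    pos_set <- unique(pos_id)
    while (length(ids) < n_neg) {
      draw <- ceiling(runif(2L * (n_neg - length(ids))) * n_universe)
      draw <- setdiff(draw, c(pos_set, ids))
      ids <- c(ids, draw)
    }
    ids <- ids[seq_len(n_neg)]
  }
  di <- ((ids - 1) %/% ns) + 1
  si <- ((ids - 1) %% ns) + 1
  data.frame(domain = domains[di], disease = diseases[si],
             stringsAsFactors = FALSE)
}

#' Combine positives and negatives into a labeled pair set
#'
#' @param positives,negatives Data frames of (domain, disease) pairs.
#' @return An object of class `labeled_pair_set`: data.frame with columns
#'   `domain`, `disease`, `label` (1/0), `origin`
#'   (`"transferred"`/`"sampled"`), `split` (initially `"none"`).
#' @export
labeled_pair_set <- function(positives, negatives) {
  pos <- as_pair_frame(positives); neg <- as_pair_frame(negatives)
  df <- rbind(
    data.frame(pos, label = 1L, origin = "transferred",
               stringsAsFactors = FALSE),
    data.frame(neg, label = 0L, origin = "sampled", stringsAsFactors = FALSE)
  )
  dup <- duplicated(df[, c("domain", "disease")])
  if (any(dup))
    stopf("pair (%s, %s) appears more than once in the labeled set",
          df$domain[dup][1L], df$disease[dup][1L])
  df$split <- "none"
  rownames(df) <- NULL
  structure(df, class = c("labeled_pair_set", "data.frame"))
}

#' Split specification
#'
#' @param train_fraction Fraction of each label class assigned to
#'   training (default 2/3, giving 444+444 train and 222+222 test from
#'   666 positives with 1:1 negatives).
#' @param negative_ratio Negatives per positive (default 1).
#' @param seed Integer seed driving all sampling.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 2 / 3, negative_ratio = 1, seed = 1L) {
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be strictly between 0 and 1")
  if (!is_number(negative_ratio) || negative_ratio <= 0)
    stopf("negative_ratio must be positive")
  structure(list(train_fraction = train_fraction,
                 negative_ratio = negative_ratio,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split of a labeled pair set
#'
#' Splits each label class separately: per class, `round(train_fraction *
#' n)` pairs go to training (so 666 positives at 2/3 give exactly 444
#' train / 222 test) and the rest to test.  Reproducible given the spec's
#' seed.
#'
#' @param pairs A [labeled_pair_set()] containing both labels.
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test`, both labeled pair sets
#'   with the `split` column filled in.
#' @export
train_test_split <- function(pairs, spec = split_spec()) {
  stopifnot(inherits(pairs, "labeled_pair_set"), inherits(spec, "split_spec"))
  tab <- table(pairs$label)
  if (length(tab) < 2L) stopf("labeled pair set must contain both labels")
  if (any(tab < 2L)) stopf("each label class needs at least 2 members to split")
  set.seed(spec$seed)
  in_train <- logical(nrow(pairs))
  for (lab in c(1L, 0L)) {
    idx <- which(pairs$label == lab)
    n_train <- round(spec$train_fraction * length(idx))
    in_train[sample(idx, n_train)] <- TRUE
  }
  train <- pairs[in_train, , drop = FALSE]
  test <- pairs[!in_train, , drop = FALSE]
  train$split <- "train"; test$split <- "test"
  rownames(train) <- rownames(test) <- NULL
  list(train = structure(train, class = class(pairs)),
       test = structure(test, class = class(pairs)))
}

#' Leakage-controlled network for feature computation
#'
#' Before computing features, the reference edges of held-out test
#' positives are removed from the domain-disease layer so a pair's label
#' is never encoded in its own features.  `mask_mode = "paper"` removes
#' exactly the test-positive edges (training positives keep theirs).
#' `mask_mode = "strict"` additionally zeroes, for each evaluated pair,
#' that pair's own reference edge during its feature computation (see
#' [assemble_features()]) — training-positive self-edges are a known
#' optimistic bias that the default mode does not address.
#'
#' @param network A `hetnet`.
#' @param test_positives Data frame of held-out positive pairs.
#' @param mask_mode `"paper"` (default) or `"strict"`.
#' @return A new `hetnet` with the edges removed and the leakage mode
#'   recorded as attribute `"leakage_mode"`.
#' @export
leakage_controlled_network <- function(network, test_positives,
                                       mask_mode = c("paper", "strict")) {
  mask_mode <- match.arg(mask_mode)
  out <- remove_domain_disease_edges(network, test_positives)
  attr(out, "leakage_mode") <- mask_mode
  out
}

#' Write a labeled pair set as CSV
#' @param pairs A [labeled_pair_set()].
#' @param path Output CSV path.
#' @export
write_labeled_pairs <- function(pairs, path) {
  write.csv(as.data.frame(pairs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
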