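## Seedable synthetic heterogeneous networks with planted domain-disease
## signal, built from a cluster-structured block model: diseases fall into
## similarity clusters, proteins work inside one cluster, and
## guilt-by-association signal flows from domains through proteins to the
## diseases of their cluster.

#' Synthetic network configuration
#'
#' Defaults describe a desk-scale study: 200 domains, 400 proteins, 60
#' diseases in 4 similarity clusters.  Half the proteins are single-domain
#' (these generate the planted reference associations through the
#' single-domain transfer rule); multi-domain proteins carry 2 or more
#' domains, which spreads a domain's paths over several clusters and makes
#' negatives genuinely confusable.  Disease similarity is dense within a
#' cluster (0.6) and sparse between (0.01); a protein is linked to each
#' disease of its own cluster with probability 0.12 (about 1.8 disease
#' links per protein) and to any other disease at the noise rate.
#'
#' @param n_domains,n_proteins,n_diseases Node counts.
#' @param n_disease_clusters Number of disease similarity clusters.
#' @param single_domain_fraction Fraction of proteins forced to carry
#'   exactly one domain.
#' @param mean_domains_per_protein Mean domain count of multi-domain
#'   proteins (at least 2).
#' @param p_protein_disease_in_cluster Probability of a protein-disease
#'   link within the protein's cluster.
#' @param p_similarity_in_cluster Probability of a disease-disease
#'   similarity edge within a cluster.
#' @param p_noise_edge Probability of any cross-cluster (noise) edge.
#' @param ppi_density Overall protein-protein interaction density;
#'   within-cluster pairs are linked at three times this rate, others at
#'   half of it.
#' @param ablate_signal If TRUE, the disease-cluster assignment is
#'   permuted across diseases before the truth-defining protein-disease
#'   draw, and the network's protein-disease layer is an independent
#'   redraw under the original assignment — a negative control in which
#'   the planted labels carry no usable network signal (expected AUC 0.5).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_domains = 200L, n_proteins = 400L,
                             n_diseases = 60L, n_disease_clusters = 4L,
                             single_domain_fraction = 0.5,
                             mean_domains_per_protein = 2.5,
                             p_protein_disease_in_cluster = 0.12,
                             p_similarity_in_cluster = 0.6,
                             p_noise_edge = 0.01,
                             ppi_density = 0.02,
                             ablate_signal = FALSE,
                             seed = 1L) {
  cfg <- list(n_domains = as.integer(n_domains),
              n_proteins = as.integer(n_proteins),
              n_diseases = as.integer(n_diseases),
              n_disease_clusters = as.integer(n_disease_clusters),
              single_domain_fraction = single_domain_fraction,
              mean_domains_per_protein = mean_domains_per_protein,
              p_protein_disease_in_cluster = p_protein_disease_in_cluster,
              p_similarity_in_cluster = p_similarity_in_cluster,
              p_noise_edge = p_noise_edge,
              ppi_density = ppi_density,
              ablate_signal = isTRUE(ablate_signal),
              seed = as.integer(seed))
  with(cfg, {
    if (n_domains < 1L || n_proteins < 1L || n_diseases < 1L)
      stopf("node counts must be positive")
    if (n_disease_clusters < 1L || n_disease_clusters > n_diseases)
      stopf("n_disease_clusters must be between 1 and n_diseases")
    if (single_domain_fraction < 0 || single_domain_fraction > 1)
      stopf("single_domain_fraction must be in [0, 1]")
    if (mean_domains_per_protein < 1)
      stopf("mean_domains_per_protein must be at least 1")
    for (p in c(p_protein_disease_in_cluster, p_similarity_in_cluster,
                p_noise_edge))
      if (p < 0 || p > 1) stopf("probabilities must be in [0, 1]")
  })
  structure(cfg, class = "synthetic_config")
}

## Bernoulli edges between two label vectors with a probability matrix
## given per (row, col) pair; returns a 2-column index matrix.
draw_pairs <- function(pmat) {
  hits <- which(matrix(runif(length(pmat)), nrow(pmat)) < pmat, arr.ind = TRUE)
  hits
}

#' Generate a synthetic heterogeneous network with planted truth
#'
#' Diseases are partitioned into similarity clusters and linked densely
#' within them; each protein belongs to one cluster, carries one or more
#' domains, and is linked mostly to diseases of its cluster; protein
#' interactions are denser within clusters.  The domain-disease reference
#' layer is the single-domain transfer rule applied to the intended
#' (cluster-consistent) protein-disease links of single-domain proteins;
#' these pairs are the planted truth.  Without ablation the network's
#' protein-disease layer equals the intended links, so the truth is
#' exactly what [transfer_single_domain_associations()] recovers from the
#' generated network.  With `ablate_signal = TRUE` the cluster assignment
#' is shuffled across diseases before the truth-defining draw and the
#' network's protein-disease layer is an independent redraw under the
#' original assignment, so the planted labels are decoupled from every
#' network layer — a negative control with the same marginal statistics
#' but no usable signal.
#'
#' @param config A [synthetic_config()].
#' @return List with `network` (a `hetnet`) and `truth` (class
#'   `synthetic_truth`: planted `positives`, `disease_clusters`,
#'   `protein_clusters`, `single_domain_proteins`, `config`).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nd <- config$n_domains; np <- config$n_proteins; ns <- config$n_diseases
  k <- config$n_disease_clusters
  dom <- sprintf("D%04d", seq_len(nd))
  pro <- sprintf("P%04d", seq_len(np))
  dis <- sprintf("S%04d", seq_len(ns))

  dis_cluster <- sample(rep(seq_len(k), length.out = ns))
  pro_cluster <- sample(seq_len(k), np, replace = TRUE)

  # disease-disease similarity
  p_ss <- matrix(config$p_noise_edge, ns, ns)
  same <- outer(dis_cluster, dis_cluster, "==")
  p_ss[same] <- config$p_similarity_in_cluster
  p_ss[lower.tri(p_ss, diag = TRUE)] <- 0   # draw upper triangle only
  ss_idx <- draw_pairs(p_ss)

  # domain assignment: forced single-domain proteins first
  n_single <- round(config$single_domain_fraction * np)
  is_single <- logical(np)
  if (n_single > 0L) is_single[sample(np, n_single)] <- TRUE
  dp_i <- integer(0); dp_j <- integer(0)
  # a domain family rarely spawns many single-domain proteins: assign
  # distinct domains while possible
  if (n_single > 0L) {
    sd_doms <- if (n_single <= nd) sample(nd, n_single)
               else sample(nd, n_single, replace = TRUE)
    dp_i <- sd_doms
    dp_j <- which(is_single)
  }
  lambda <- max(config$mean_domains_per_protein - 2, 0.1)
  for (p in which(!is_single)) {
    ndom_p <- min(2L + rpois(1L, lambda), nd)
    dp_i <- c(dp_i, sample(nd, ndom_p))
    dp_j <- c(dp_j, rep(p, ndom_p))
  }

  # intended protein-disease links (cluster-consistent); these define the
  # planted truth.  Under ablation the truth-defining draw runs on a
  # per-disease shuffle of the cluster assignment, so the labels follow a
  # partition unrelated to the similarity layer.
  lab_cluster <- if (config$ablate_signal) dis_cluster[sample(ns)] else dis_cluster
  p_ps <- matrix(config$p_noise_edge, np, ns)
  in_cl <- outer(pro_cluster, lab_cluster, "==")
  p_ps[in_cl] <- config$p_protein_disease_in_cluster
  ps_idx <- draw_pairs(p_ps)

  # planted truth: transfer intended links of single-domain proteins
  single_of <- setNames(rep(NA_integer_, np), pro)
  if (n_single > 0L) single_of[dp_j[seq_len(n_single)]] <- dp_i[seq_len(n_single)]
  sd_links <- ps_idx[is_single[ps_idx[, 1L]], , drop = FALSE]
  truth_pairs <- unique(data.frame(
    domain = dom[single_of[sd_links[, 1L]]],
    disease = dis[sd_links[, 2L]], stringsAsFactors = FALSE))
  truth_pairs <- truth_pairs[order(truth_pairs$domain, truth_pairs$disease), ,
                             drop = FALSE]
  rownames(truth_pairs) <- NULL

  # network protein-disease layer: the intended links themselves, or —
  # under ablation — an independent redraw with the original cluster
  # assignment, so no network layer carries information about the labels
  if (config$ablate_signal) {
    p_ps2 <- matrix(config$p_noise_edge, np, ns)
    in_cl2 <- outer(pro_cluster, dis_cluster, "==")
    p_ps2[in_cl2] <- config$p_protein_disease_in_cluster
    ps_idx <- draw_pairs(p_ps2)
  }

  # protein-protein interactions, denser within clusters
  p_pp <- matrix(config$ppi_density / 2, np, np)
  same_p <- outer(pro_cluster, pro_cluster, "==")
  p_pp[same_p] <- min(3 * config$ppi_density, 1)
  p_pp[lower.tri(p_pp, diag = TRUE)] <- 0
  pp_idx <- draw_pairs(p_pp)

  tabs <- list(
    edge_table(dom[dp_i], pro[dp_j], "domain", "protein"),
    edge_table(pro[pp_idx[, 1L]], pro[pp_idx[, 2L]], "protein", "protein"),
    edge_table(pro[ps_idx[, 1L]], dis[ps_idx[, 2L]], "protein", "disease"),
    edge_table(dis[ss_idx[, 1L]], dis[ss_idx[, 2L]], "disease", "disease"),
    edge_table(truth_pairs$domain, truth_pairs$disease, "domain", "disease")
  )
  network <- build_hetnet(tabs)

  truth <- structure(list(positives = truth_pairs,
                          disease_clusters = setNames(dis_cluster, dis),
                          protein_clusters = setNames(pro_cluster, pro),
                          single_domain_proteins = pro[is_single],
                          config = config),
                     class = "synthetic_truth")
  list(network = network, truth = truth)
}

#' Generate a complete synthetic study bundle
#'
#' One call yields an end-to-end fixture: a network with planted truth, a
#' labeled pair set (subsampled planted positives plus sampled 1:1
#' negatives), a stratified train/test split, and the leakage-controlled
#' network with the test-positive reference edges removed.
#'
#' @param config A [synthetic_config()].
#' @param n_positives Number of planted positives to use (default: all).
#' @param split A [split_spec()].
#' @param mask_mode Leakage mode for [leakage_controlled_network()].
#' @return An object of class `study_bundle`: list with `network`,
#'   `masked_network`, `truth`, `pairs`, `train`, `test`, `config`,
#'   `split`.
#' @export
generate_study <- function(config, n_positives = NULL, split = split_spec(),
                           mask_mode = c("paper", "strict")) {
  stopifnot(inherits(config, "synthetic_config"), inherits(split, "split_spec"))
  mask_mode <- match.arg(mask_mode)
  gen <- generate_network(config)
  planted <- gen$truth$positives
  if (is.null(n_positives)) n_positives <- nrow(planted)
  if (n_positives > nrow(planted))
    stopf("config yields only %d planted positives (requested %d); increase n_proteins or single_domain_fraction",
          nrow(planted), n_positives)
  if (n_positives < 1L)
    stopf("at least one planted positive is required")
  set.seed(child_seed(config$seed, 7919L))
  positives <- planted[sample(nrow(planted), n_positives), , drop = FALSE]
  negatives <- sample_negatives(positives, ratio = split$negative_ratio,
                                seed = child_seed(split$seed, 104729L))
  pairs <- labeled_pair_set(positives, negatives)
  sp <- train_test_split(pairs, split)
  test_pos <- sp$test[sp$test$label == 1L, c("domain", "disease")]
  masked <- leakage_controlled_network(gen$network, test_pos, mask_mode)
  structure(list(network = gen$network, masked_network = masked,
                 truth = gen$truth, pairs = pairs,
                 train = sp$train, test = sp$test,
                 config = config, split = split),
            class = "study_bundle")
}

#' Write a synthetic study as a fixture directory
#'
#' Emits the same TSV edge-list directory and manifest as
#' [write_hetnet()], plus `truth.csv` (planted pairs) and `pairs.csv`
#' (labeled pairs with split membership).
#'
#' @param bundle A [generate_study()] bundle.
#' @param dir Output directory.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_hetnet(bundle$network, dir)
  write.csv(bundle$truth$positives, file.path(dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  all_pairs <- rbind(as.data.frame(bundle$train), as.data.frame(bundle$test))
  write.csv(all_pairs, file.path(dir, "pairs.csv"),
            row.names = FALSE, quote = FALSE)
  meta <- list(config = unclass(bundle$config),
               split = unclass(bundle$split),
               n_train = nrow(bundle$train), n_test = nrow(bundle$test))
  write_json_file(meta, file.path(dir, "study.json"))
  invisible(dir)
}
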