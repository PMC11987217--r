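## End-to-end orchestration shared by the R interface and the command line.

#' Build a run configuration
#'
#' A run is driven either by a synthetic configuration or by a directory
#' of real edge-list TSVs (exactly one of the two), plus a feature preset,
#' leakage mode, classifier and split specification.
#'
#' @param synthetic A [synthetic_config()], or NULL when `edge_dir` is
#'   given.
#' @param edge_dir Directory of edge-list TSVs as written by
#'   [write_hetnet()], or NULL.
#' @param preset Feature preset name (see [feature_set()]).
#' @param leakage `"paper"` or `"strict"`.
#' @param classifier A [classifier_spec()].
#' @param split A [split_spec()].
#' @param n_positives Positives to use from the planted truth
#'   (NULL: all).
#' @param seed Global seed; overrides the seeds of the component specs so
#'   one integer reproduces a whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(), edge_dir = NULL,
                       preset = "Feature-II", leakage = "paper",
                       classifier = classifier_spec(), split = split_spec(),
                       n_positives = NULL, seed = NULL) {
  if (is.null(synthetic) == is.null(edge_dir))
    stopf("exactly one of synthetic config or edge_dir must be supplied")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (!is.null(synthetic)) synthetic$seed <- seed
    classifier$seed <- child_seed(seed, 2L)
    split$seed <- child_seed(seed, 3L)
  }
  structure(list(synthetic = synthetic, edge_dir = edge_dir, preset = preset,
                 leakage = leakage, classifier = classifier, split = split,
                 n_positives = n_positives, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Recognized keys mirror the [run_config()] arguments; nested blocks
#' `synthetic`, `classifier` and `split` take the corresponding
#' constructor arguments.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param overrides Named list applied on top of the file's values (used
#'   by the command line for flag overrides).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- utils::modifyList(raw, overrides)
  syn <- if (!is.null(raw$edge_dir)) NULL
         else do.call(synthetic_config, raw$synthetic %||% list())
  cls <- do.call(classifier_spec, raw$classifier %||% list())
  spl <- do.call(split_spec, raw$split %||% list())
  run_config(synthetic = syn, edge_dir = raw$edge_dir,
             preset = raw$preset %||% "Feature-II",
             leakage = raw$leakage %||% "paper",
             classifier = cls, split = spl,
             n_positives = raw$n_positives,
             seed = raw$seed)
}

build_study <- function(config) {
  if (!is.null(config$synthetic)) {
    generate_study(config$synthetic, n_positives = config$n_positives,
                   split = config$split, mask_mode = config$leakage)
  } else {
    network <- read_hetnet(config$edge_dir)
    positives <- transfer_single_domain_associations(network)
    if (!is.null(config$n_positives) &&
        config$n_positives < nrow(positives)) {
      set.seed(child_seed(config$split$seed, 7919L))
      positives <- positives[sample(nrow(positives), config$n_positives), ,
                             drop = FALSE]
    }
    negatives <- sample_negatives(positives,
                                  ratio = config$split$negative_ratio,
                                  seed = child_seed(config$split$seed, 104729L))
    pairs <- labeled_pair_set(positives, negatives)
    sp <- train_test_split(pairs, config$split)
    test_pos <- sp$test[sp$test$label == 1L, c("domain", "disease")]
    masked <- leakage_controlled_network(network, test_pos, config$leakage)
    structure(list(network = network, masked_network = masked, truth = NULL,
                   pairs = pairs, train = sp$train, test = sp$test,
                   config = config, split = config$split),
              class = "study_bundle")
  }
}

#' Simulate a study and write it as a fixture directory
#'
#' @param config A [run_config()] with a synthetic component.
#' @param out Output directory.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config, out) {
  if (is.null(config$synthetic))
    stopf("run_simulate needs a synthetic configuration")
  bundle <- build_study(config)
  write_study(bundle, out)
  invisible(out)
}

#' Compute and write train/test feature tables
#'
#' @param config A [run_config()].
#' @param out Output directory.
#' @return List with `train` and `test` feature tables (labels attached
#'   as a `label` column), invisibly.
#' @export
run_features <- function(config, out = NULL) {
  bundle <- build_study(config)
  fts <- study_features(bundle, config$preset)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(fts$train, file.path(out, "train_features.csv"))
    write_feature_table(fts$test, file.path(out, "test_features.csv"))
  }
  invisible(fts)
}

## Feature tables for a bundle's train/test pairs on its masked network.
## Features for every pair are computed on the one leakage-controlled
## network (training positives keep their reference edges in paper mode).
study_features <- function(bundle, preset = "Feature-II") {
  mk <- function(part) {
    ft <- feature_set(bundle$masked_network, part[, c("domain", "disease")],
                      preset = preset)
    ft$label <- part$label
    ft
  }
  list(train = mk(bundle$train), test = mk(bundle$test))
}

#' Train, evaluate and write a metrics report
#'
#' Runs the configured grid-search training on the training features and
#' evaluates on the held-out test pairs.
#'
#' @param config A [run_config()].
#' @param out Output directory for `metrics.json`, `roc_points.csv` and
#'   `pr_points.csv` (NULL: no files).
#' @return List with `report` (an [evaluate()] report), `model`, `bundle`.
#' @export
run_train_eval <- function(config, out = NULL) {
  bundle <- build_study(config)
  fts <- study_features(bundle, config$preset)
  model <- tune_and_train(fts$train, fts$train$label, config$classifier)
  report <- evaluate(model, fts$test, fts$test$label)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    metrics <- list(auc = report$auc, f1 = report$f1,
                    threshold = report$threshold,
                    n_train = nrow(fts$train), n_test = nrow(fts$test),
                    best_params = model$best_params,
                    algorithm = model$algorithm,
                    preset = config$preset, leakage = config$leakage,
                    seed = config$seed %||% config$classifier$seed)
    write_json_file(metrics, file.path(out, "metrics.json"))
    write.csv(report$roc_points, file.path(out, "roc_points.csv"),
              row.names = FALSE)
    write.csv(report$pr_points, file.path(out, "pr_points.csv"),
              row.names = FALSE)
  }
  list(report = report, model = model, bundle = bundle)
}

#' Full pipeline: simulate (or load), featurize, train, evaluate
#'
#' @param config A [run_config()].
#' @param out Optional output directory; when given, the fixture, feature
#'   tables and metrics are all written there.
#' @return As [run_train_eval()].
#' @export
run_full <- function(config, out = NULL) {
  if (!is.null(out) && !is.null(config$synthetic)) run_simulate(config, out)
  res <- run_train_eval(config, out)
  if (!is.null(out)) {
    fts <- study_features(res$bundle, config$preset)
    write_feature_table(fts$train, file.path(out, "train_features.csv"))
    write_feature_table(fts$test, file.path(out, "test_features.csv"))
  }
  res
}
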