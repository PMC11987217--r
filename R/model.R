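## Classifier specification, grid-search cross-validation and training.

GBT_PARAM_NAMES <- c("n_estimators", "max_depth", "min_child_weight",
                     "gamma", "colsample_bytree", "reg_alpha")

GBT_PARAM_DEFAULTS <- list(n_estimators = 300, max_depth = 5,
                           min_child_weight = 1, gamma = 0,
                           colsample_bytree = 1, reg_alpha = 0)

#' Default hyperparameter grid for the gradient-boosted tree model
#'
#' The six tuned boosting hyperparameters with small candidate lists
#' suitable for desk-scale grid search; every entry can be overridden (or
#' shrunk to a single value) through [classifier_spec()].
#'
#' @return Named list of candidate value vectors.
#' @export
default_gbt_grid <- function() {
  list(n_estimators = c(100, 300, 500),
       max_depth = c(3, 5, 7),
       min_child_weight = c(1, 3),
       gamma = c(0, 0.1),
       colsample_bytree = c(0.8, 1.0),
       reg_alpha = c(0, 0.1))
}

#' Classifier specification
#'
#' @param algorithm `"gbt"` (gradient-boosted trees, the main model) or a
#'   baseline: `"rf"` (random forest), `"svm"` (support vector machine
#'   with probability outputs), `"nb"` (naive Bayes).
#' @param grid Named list mapping hyperparameter names to candidate value
#'   vectors.  For `"gbt"` the tunable names are exactly `n_estimators`,
#'   `max_depth`, `min_child_weight`, `gamma`, `colsample_bytree`,
#'   `reg_alpha`; parameters not listed keep their defaults.  `NULL`
#'   selects [default_gbt_grid()] for `"gbt"` and library defaults (a
#'   single combination) for the baselines.
#' @param cv_folds Number of stratified cross-validation folds
#'   (default 3).
#' @param seed Integer seed for fold assignment and model fitting.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("gbt", "rf", "svm", "nb"),
                            grid = NULL, cv_folds = 3L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (!is_number(cv_folds) || cv_folds < 2)
    stopf("cv_folds must be at least 2")
  if (is.null(grid)) grid <- if (algorithm == "gbt") default_gbt_grid() else list()
  if (algorithm == "gbt" && length(grid)) {
    extra <- setdiff(names(grid), GBT_PARAM_NAMES)
    if (length(extra))
      stopf("unknown gbt hyperparameter(s): %s", paste(extra, collapse = ", "))
  }
  structure(list(algorithm = algorithm, grid = grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "classifier_spec")
}

fit_one <- function(algorithm, X, y, params, seed) {
  set.seed(seed)
  switch(algorithm,
    gbt = {
      p <- utils::modifyList(GBT_PARAM_DEFAULTS, params)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = p$max_depth,
                      min_child_weight = p$min_child_weight,
                      gamma = p$gamma,
                      colsample_bytree = p$colsample_bytree,
                      alpha = p$reg_alpha,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(X, label = y),
        nrounds = p$n_estimators, verbose = 0)
    },
    rf = do.call(randomForest::randomForest,
                 c(list(x = X, y = factor(y, levels = c(0, 1))), params)),
    svm = do.call(e1071::svm,
                  c(list(x = X, y = factor(y, levels = c(0, 1)),
                         probability = TRUE), params)),
    nb = {
      xdf <- as.data.frame(X)
      yf <- factor(y, levels = c(0, 1))
      e1071::naiveBayes(xdf, yf, laplace = params$laplace %||% 0)
    }
  )
}

score_one <- function(algorithm, fit, X) {
  if (nrow(X) == 0L) return(numeric(0))
  switch(algorithm,
    gbt = as.numeric(predict(fit, xgboost::xgb.DMatrix(X))),
    rf = unname(predict(fit, X, type = "prob")[, "1"]),
    svm = {
      p <- predict(fit, X, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    },
    nb = unname(predict(fit, as.data.frame(X), type = "raw")[, "1"])
  )
}

#' Grid-search cross-validation and final fit
#'
#' Scores every hyperparameter combination of the spec's grid by mean AUC
#' over stratified cross-validation folds (3 by default), then refits the
#' best combination — ties broken by first-in-grid order — on the full
#' training set.  Fully reproducible given the spec's seed.
#'
#' @param features A [feature_table()] (id columns are dropped) or a
#'   numeric matrix / data frame of features.
#' @param labels 0/1 labels aligned with the feature rows.
#' @param spec A [classifier_spec()].
#' @return An object of class `dd_model`: list with `algorithm`, `fit`,
#'   `feature_names`, `best_params`, `cv_results` (one row per grid
#'   combination with its mean CV AUC) and `spec`.
#' @export
tune_and_train <- function(features, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- if (is.matrix(features)) features else feature_matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stopf("training labels contain a single class")

  combos <- if (length(spec$grid)) {
    expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(row.names = 1L)  # one empty combination: library defaults
  }

  # stratified fold assignment
  set.seed(spec$seed)
  fold <- integer(length(y))
  for (lab in c(1L, 0L)) {
    idx <- which(y == lab)
    fold[idx] <- sample(rep(seq_len(spec$cv_folds), length.out = length(idx)))
  }
  if (min(table(fold, y)) < 1L)
    stopf("too few members of a class for %d-fold stratified CV", spec$cv_folds)

  mean_auc <- numeric(nrow(combos))
  for (g in seq_len(nrow(combos))) {
    params <- if (ncol(combos)) as.list(combos[g, , drop = FALSE]) else list()
    aucs <- vapply(seq_len(spec$cv_folds), function(k) {
      tr <- fold != k
      fit <- fit_one(spec$algorithm, X[tr, , drop = FALSE], y[tr], params,
                     child_seed(spec$seed, g * 100L + k))
      sc <- score_one(spec$algorithm, fit, X[!tr, , drop = FALSE])
      roc_auc(sc, y[!tr])$auc
    }, 0)
    mean_auc[g] <- mean(aucs)
  }
  best <- which.max(mean_auc)   # first-in-grid order breaks ties
  best_params <- if (ncol(combos)) as.list(combos[best, , drop = FALSE]) else list()
  fit <- fit_one(spec$algorithm, X, y, best_params, child_seed(spec$seed, 0L))

  cv_results <- cbind(combos, mean_auc = mean_auc)
  rownames(cv_results) <- NULL
  structure(list(algorithm = spec$algorithm, fit = fit,
                 feature_names = colnames(X),
                 best_params = lapply(best_params, unname),
                 cv_results = cv_results, spec = spec),
            class = "dd_model")
}

#' @export
print.dd_model <- function(x, ...) {
  cat(sprintf("dompath %s model on %d features\n", x$algorithm,
              length(x$feature_names)))
  if (length(x$best_params)) {
    cat("  best grid point:",
        paste(names(x$best_params), unlist(x$best_params),
              sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  mean CV AUC of best combination: %.4f\n",
              max(x$cv_results$mean_auc)))
  invisible(x)
}

#' Predict association scores
#'
#' Feature columns must match the training columns by name and order;
#' any mismatch is an error naming the missing/extra columns, since a
#' silently reordered matrix would scramble the model inputs.
#'
#' @param model A [tune_and_train()] model.
#' @param features Feature table or numeric matrix.
#' @return Numeric vector of scores in `[0, 1]`, one per row.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "dd_model"))
  X <- if (is.matrix(features)) features else feature_matrix(features)
  if (!identical(colnames(X), model$feature_names)) {
    missing <- setdiff(model$feature_names, colnames(X))
    extra <- setdiff(colnames(X), model$feature_names)
    if (length(missing) || length(extra))
      stopf("feature columns do not match training columns; missing: [%s]; extra: [%s]",
            paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    stopf("feature columns are not in training order; expected %s",
          paste(head(model$feature_names, 3L), collapse = ", "))
  }
  score_one(model$algorithm, model$fit, X)
}
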