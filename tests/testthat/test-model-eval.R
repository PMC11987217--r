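test_that("roc_auc reproduces hand-computed values and boundary points", {
  labels <- c(1, 1, 0, 0)
  expect_equal(roc_auc(c(1, 1, 0, 0), labels)$auc, 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), labels)$auc, 0)
  # one tie across classes: 3.5 of 4 pairs ordered correctly
  r <- roc_auc(c(0.9, 0.4, 0.4, 0.1), labels)
  expect_equal(r$auc, 0.875)
  expect_equal(unlist(r$roc_points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]), c(fpr = 1, tpr = 1))
  # constant scores: everything ties, AUC 1/2
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(1:3 / 3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc equals the pairwise Mann-Whitney statistic with ties", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    # rounding forces plenty of ties
    scores <- round(runif(n), sample(1:2, 1))
    expect_equal(roc_auc(scores, labels)$auc, mann_whitney_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  scores <- runif(60); labels <- rbinom(60, 1, 0.4)
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(3 * scores), labels)$auc, base)
  expect_equal(roc_auc(rank(scores), labels)$auc, base)
})

test_that("F1 follows its closed form and handles degenerate counts", {
  expect_equal(f1_score(list(TP = 2, FP = 1, FN = 1)), 2 / 3)
  expect_equal(f1_score(list(TP = 0, FP = 0, FN = 5)), 0)
  expect_equal(f1_score(list(TP = 10, FP = 0, FN = 0)), 1)
  expect_warning(out <- f1_score(list(TP = 0, FP = 0, FN = 0)), "undefined")
  expect_equal(out, 0)
  # harmonic-mean identity whenever precision and recall are defined
  cc <- confusion_counts(c(0.9, 0.8, 0.3, 0.6), c(1, 0, 1, 0), 0.5)
  prec <- cc$TP / (cc$TP + cc$FP); rec <- cc$TP / (cc$TP + cc$FN)
  expect_equal(f1_score(cc), 2 * prec * rec / (prec + rec))
})

make_toy_features <- function(n = 30) {
  # separable blocks: positives all ones, negatives all zeros, tiny jitter
  set.seed(1)
  X <- rbind(matrix(1 + rnorm(n * 3, 0, 0.01), n),
             matrix(rnorm(n * 3, 0, 0.01), n))
  colnames(X) <- c("DPS_count", "DSS_count", "DPSS_count")
  list(X = X, y = rep(c(1L, 0L), each = n))
}

test_that("grid search selects by CV AUC, refits, and is seed-reproducible", {
  toy <- make_toy_features()
  spec1 <- classifier_spec("gbt", grid = list(n_estimators = 50, max_depth = 2),
                           seed = 7)
  m1 <- tune_and_train(toy$X, toy$y, spec1)
  expect_equal(nrow(m1$cv_results), 1L)
  expect_equal(m1$best_params$n_estimators, 50)
  # separable training data scores perfectly
  expect_equal(roc_auc(predict_scores(m1, toy$X), toy$y)$auc, 1)

  m1b <- tune_and_train(toy$X, toy$y, spec1)
  expect_identical(m1$best_params, m1b$best_params)
  expect_equal(predict_scores(m1, toy$X), predict_scores(m1b, toy$X))

  # ties in mean CV AUC resolve to the first grid combination
  spec2 <- classifier_spec("gbt", grid = list(n_estimators = c(50, 100)),
                           seed = 7)
  m2 <- tune_and_train(toy$X, toy$y, spec2)
  expect_equal(m2$cv_results$mean_auc[1], m2$cv_results$mean_auc[2])
  expect_equal(m2$best_params$n_estimators, 50)

  expect_error(tune_and_train(toy$X, rep(1L, nrow(toy$X)), spec1),
               "single class")
})

test_that("baseline algorithms produce probability scores on the toy", {
  toy <- make_toy_features(20)
  for (alg in c("rf", "svm", "nb")) {
    m <- tune_and_train(toy$X, toy$y, classifier_spec(alg, seed = 11))
    sc <- predict_scores(m, toy$X)
    expect_length(sc, nrow(toy$X))
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(roc_auc(sc, toy$y)$auc, 0.9)
  }
})

test_that("predict_scores enforces the training column contract", {
  toy <- make_toy_features(15)
  m <- tune_and_train(toy$X, toy$y,
                      classifier_spec("gbt", grid = list(n_estimators = 20),
                                      seed = 2))
  expect_length(predict_scores(m, toy$X[0, , drop = FALSE]), 0L)
  dup <- toy$X[c(1, 1), , drop = FALSE]
  expect_equal(predict_scores(m, dup)[1], predict_scores(m, dup)[2])
  perm <- toy$X[, c(2, 1, 3)]
  expect_error(predict_scores(m, perm), "training order")
  expect_error(predict_scores(m, toy$X[, 1:2]), "missing")
})

test_that("evaluate assembles AUC, F1 and curves into one report", {
  toy <- make_toy_features(15)
  m <- tune_and_train(toy$X, toy$y,
                      classifier_spec("gbt", grid = list(n_estimators = 30),
                                      seed = 3))
  rep_ <- evaluate(m, toy$X, toy$y)
  expect_equal(rep_$auc, 1)
  expect_equal(rep_$f1, 1)
  expect_equal(unlist(rep_$roc_points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rep_$roc_points[nrow(rep_$roc_points), ]),
               c(fpr = 1, tpr = 1))
  expect_equal(rep_$confusion$TP + rep_$confusion$FP +
                 rep_$confusion$FN + rep_$confusion$TN, rep_$n)
  expect_output(print(rep_), "AUC = 1")
})

test_that("our ROC/AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- round(runif(80), 2)
  labels <- rbinom(80, 1, 0.5)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})
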