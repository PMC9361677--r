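test_that("default specs carry the published hyperparameters", {
  ada <- default_spec("ADABOOST")
  expect_equal(ada$hyperparameters$n_estimators, 90L)
  expect_equal(ada$hyperparameters$algorithm, "SAMME")
  expect_equal(ada$hyperparameters$max_depth, 6L)
  expect_equal(ada$hyperparameters$min_samples_split, 2L)

  xgb <- default_spec("XGBOOST")
  expect_equal(xgb$hyperparameters$n_estimators, 75L)  # int(75.5942)
  expect_equal(xgb$hyperparameters$learning_rate, 0.2612)
  expect_equal(xgb$hyperparameters$reg_alpha, 0.9925)
  expect_equal(xgb$hyperparameters$max_depth, 5L)

  rf <- default_spec("RANDOM_FOREST")
  expect_equal(rf$hyperparameters$n_estimators, 115L)
  expect_equal(rf$hyperparameters$max_features, 0.3)
  expect_equal(rf$hyperparameters$min_samples_split, 16L)

  svm <- default_spec("SVM")
  expect_equal(svm$hyperparameters$C, 1.0)
  expect_equal(svm$hyperparameters$gamma, "scale")

  lgb <- default_spec("LIGHTBOOST")
  expect_equal(lgb$hyperparameters$tuning_grid$learning_rate,
               c(0.001, 0.01, 0.1, 0.2, 0.3))

  expect_error(default_spec("DBN"))
  expect_error(classifier_spec("SVM", list(bogus = 1)), "bogus")
})

test_that("stratified folds partition the data evenly", {
  set.seed(51)
  for (i in 1:5) {
    n <- sample(40:120, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    folds <- sample(2:10, 1)
    id <- make_folds(y, folds, seed = i)
    expect_equal(sort(unique(id)), seq_len(folds))
    expect_equal(length(id), n)                       # union = all samples
    sizes <- tabulate(id, folds)
    expect_lte(diff(range(sizes)), 1L)                # sizes differ by <= 1
    class1 <- tabulate(id[y == 1], folds)
    expect_lte(diff(range(class1)), 1L)               # stratification
  }
  expect_identical(make_folds(rbinom(50, 1, .5), 5, seed = 9),
                   make_folds(rbinom(50, 1, .5), 5, seed = 9))
})

test_that("all five classifiers separate a separable benchmark", {
  d <- make_separable(n = 400, p = 20, delta = 2, seed = 52)
  for (alg in c("SVM", "RANDOM_FOREST", "ADABOOST", "XGBOOST",
                "LIGHTBOOST")) {
    r <- cross_validate(d$X, d$y, default_spec(alg, seed = 7),
                        cv_protocol(folds = 10, seed = 7))
    expect_gte(r$mean$auc, 0.99)
    expect_gte(r$mean$accuracy, 0.95)
    expect_lte(r$mean$mse, 0.1)
  }
})

test_that("fold means equal the arithmetic mean of fold metrics", {
  d <- make_separable(n = 100, p = 5, delta = 1, seed = 53)
  r <- cross_validate(d$X, d$y, default_spec("XGBOOST", seed = 3),
                      cv_protocol(folds = 5, seed = 3))
  for (m in c("accuracy", "precision", "recall", "f1", "mcc", "mse", "auc")) {
    expect_equal(r$mean[[m]], mean(r$per_fold[[m]]), tolerance = 1e-12)
  }
})

test_that("identical seeds give identical reports", {
  d <- make_separable(n = 120, p = 6, delta = 0.7, seed = 54)
  for (alg in c("RANDOM_FOREST", "ADABOOST", "XGBOOST")) {
    r1 <- cross_validate(d$X, d$y, default_spec(alg, seed = 11),
                         cv_protocol(folds = 4, seed = 11))
    r2 <- cross_validate(d$X, d$y, default_spec(alg, seed = 11),
                         cv_protocol(folds = 4, seed = 11))
    expect_identical(r1$per_fold, r2$per_fold)
  }
})

test_that("predictions are row-wise pure (no test-set leakage channel)", {
  d <- make_separable(n = 100, p = 5, delta = 1, seed = 55)
  model <- fit_classifier(default_spec("ADABOOST", seed = 2), d$X, d$y)
  xt <- d$X[1:3, , drop = FALSE]
  p_alone <- predict_prob(model, xt)
  adversarial <- rbind(xt, -xt, d$X[4:10, ])
  p_mixed <- predict_prob(model, adversarial)
  expect_identical(p_alone, p_mixed[1:3])
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(40), ncol = 4)
  expect_error(cross_validate(X, rep(1, 10), default_spec("SVM", seed = 1)),
               "single class")
  expect_error(fit_classifier(default_spec("SVM", seed = 1), X, rep(0, 10)),
               "single class")
  expect_error(fit_classifier(default_spec("SVM"), X, rep(c(0, 1), 5)),
               "seed")
  expect_error(cross_validate(X, rep(c(0, 1), 3), default_spec("SVM", seed = 1)),
               "align")
})

test_that("single-class test folds are flagged with undefined AUC", {
  rep1 <- classification_report(rep(1L, 10), runif(10))
  expect_false(rep1$auc_defined)
  expect_true(is.na(rep1$auc))
})

test_that("balancing is applied inside training folds only", {
  set.seed(56)
  X <- rbind(matrix(rnorm(30 * 4, 1.5), ncol = 4),
             matrix(rnorm(120 * 4, -1.5), ncol = 4))
  y <- c(rep(1, 30), rep(0, 120))
  for (bal in c("undersample", "smote")) {
    r <- cross_validate(X, y, default_spec("XGBOOST", seed = 5),
                        cv_protocol(folds = 5, seed = 5), balance = bal)
    # test folds keep the original imbalance: fold metrics still computed
    # on 6/24 splits, so n per fold stays 30
    expect_equal(nrow(r$per_fold), 5L)
    expect_gte(r$mean$auc, 0.95)
  }
})
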