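# The five-classifier benchmark: RBF-SVM, random forest, SAMME AdaBoost,
# and second-order gradient boosting in depth-wise ("XGBOOST") and leaf-wise
# ("LIGHTBOOST") flavors, under stratified k-fold cross-validation. The tree
# ensembles run on the compiled tree engine (src/tree.cpp); the SVM on the
# dual solver in svm.R.

ALGORITHMS <- c("SVM", "RANDOM_FOREST", "ADABOOST", "XGBOOST", "LIGHTBOOST")

spec_schema <- function(algorithm) {
  switch(algorithm,
    SVM = c("C", "kernel", "gamma"),
    RANDOM_FOREST = c("n_estimators", "max_features", "min_samples_split",
                      "max_depth"),
    ADABOOST = c("n_estimators", "max_depth", "min_samples_split",
                 "algorithm", "splitter", "learning_rate"),
    XGBOOST = c("n_estimators", "max_depth", "learning_rate", "reg_alpha",
                "reg_lambda", "objective"),
    LIGHTBOOST = c("n_estimators", "learning_rate", "num_leaves", "max_depth",
                   "reg_alpha", "reg_lambda", "objective", "tuning_grid"),
    stop("unknown algorithm: ", algorithm))
}

#' Default hyperparameters per algorithm
#'
#' Returns the framework's fixed parameter set for each of the five
#' algorithms: SVM C = 1.0, RBF kernel, gamma = "scale"; random forest
#' max_features = 0.3, min_samples_split = 16, n_estimators = 115; AdaBoost
#' with depth-6 base trees, min_samples_split = 2, discrete SAMME,
#' n_estimators = 90; depth-wise booster max_depth = 5,
#' learning_rate = 0.2612, n_estimators = trunc(75.5942) = 75,
#' reg_alpha = 0.9925, binary logistic objective. The leaf-wise booster has
#' no single published point, only a tuning grid; its defaults are
#' learning_rate = 0.1, num_leaves = 31, binary objective, with the grid
#' exposed as `tuning_grid`.
#'
#' @param algorithm One of `"SVM"`, `"RANDOM_FOREST"`, `"ADABOOST"`,
#'   `"XGBOOST"`, `"LIGHTBOOST"`.
#' @param seed Integer seed stored in the spec (required before fitting).
#' @return A `classifier_spec`.
#' @export
default_spec <- function(algorithm, seed = NULL) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  hp <- switch(algorithm,
    SVM = list(C = 1.0, kernel = "rbf", gamma = "scale"),
    RANDOM_FOREST = list(n_estimators = 115L, max_features = 0.3,
                         min_samples_split = 16L, max_depth = 30L),
    ADABOOST = list(n_estimators = 90L, max_depth = 6L,
                    min_samples_split = 2L, algorithm = "SAMME",
                    splitter = "best", learning_rate = 1.0),
    XGBOOST = list(n_estimators = as.integer(75.5942), max_depth = 5L,
                   learning_rate = 0.2612, reg_alpha = 0.9925,
                   reg_lambda = 1.0, objective = "binary:logistic"),
    LIGHTBOOST = list(n_estimators = 100L, learning_rate = 0.1,
                      num_leaves = 31L, max_depth = 50L, reg_alpha = 0.0,
                      reg_lambda = 1.0, objective = "binary",
                      tuning_grid = list(
                        learning_rate = c(0.001, 0.01, 0.1, 0.2, 0.3))))
  classifier_spec(algorithm, hp, seed)
}

#' Construct a classifier specification
#'
#' @param algorithm Algorithm name, see [default_spec()].
#' @param hyperparameters Named list; names are validated against the
#'   algorithm's schema.
#' @param seed Integer seed for all fitting randomness.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm, hyperparameters = list(), seed = NULL) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  schema <- spec_schema(algorithm)
  bad <- setdiff(names(hyperparameters), schema)
  if (length(bad) > 0L) {
    stop("unknown hyperparameter(s) for ", algorithm, ": ",
         paste(bad, collapse = ", "))
  }
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 seed = seed),
            class = "classifier_spec")
}

hp <- function(spec, name) spec$hyperparameters[[name]]

#' Fit a classifier
#'
#' @param spec A `classifier_spec` with a non-NULL seed.
#' @param X Numeric feature matrix (or `pair_feature_matrix`).
#' @param y Binary 0/1 label vector.
#' @return A fitted model of class `dti_classifier`.
#' @export
fit_classifier <- function(spec, X, y) {
  X <- as_feature_matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("labels do not align with feature rows")
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (is.null(spec$seed)) stop("classifier_spec seed is required")
  restore <- .Random.seed_guard(spec$seed)
  on.exit(restore(), add = TRUE)

  fit <- switch(spec$algorithm,
    SVM = fit_svm_binary(spec, X, y),
    RANDOM_FOREST = fit_random_forest(spec, X, y),
    ADABOOST = fit_adaboost(spec, X, y),
    XGBOOST = fit_gbt(spec, X, y, leafwise = FALSE),
    LIGHTBOOST = fit_gbt(spec, X, y, leafwise = TRUE))
  structure(c(fit, list(spec = spec, n_features = ncol(X))),
            class = c(paste0("dti_", tolower(spec$algorithm)),
                      "dti_classifier"))
}

#' Predicted class-1 probability
#'
#' For the SVM the decision-function value is mapped through a sigmoid: it is
#' monotone, so ranking metrics (AUC) are identical to using the raw
#' decision values.
#'
#' @param model A fitted [fit_classifier()] model.
#' @param X Feature matrix.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != model$n_features) {
    stop("feature width mismatch: ", ncol(X), " vs ", model$n_features)
  }
  switch(model$spec$algorithm,
    SVM = plogis(decision_csvc(model$svm, scale_apply(model, X))),
    RANDOM_FOREST = {
      p <- rowMeans(vapply(model$trees, function(tr) cpp_predict_tree(tr, X),
                           numeric(nrow(X))))
      pmin(pmax(p, 0), 1)
    },
    ADABOOST = {
      margins <- vapply(model$trees, function(tr) {
        2 * (cpp_predict_tree(tr, X) >= 0.5) - 1
      }, numeric(nrow(X)))
      score <- as.vector(margins %*% model$alphas) / sum(model$alphas)
      pmin(pmax((score + 1) / 2, 0), 1)
    },
    XGBOOST = ,
    LIGHTBOOST = {
      f <- rep(0, nrow(X))
      for (i in seq_along(model$trees)) {
        f <- f + model$lr * cpp_predict_tree(model$trees[[i]], X)
      }
      plogis(f)
    })
}

scale_apply <- function(model, X) {
  sweep(sweep(X, 2, model$center), 2, model$scale, "/")
}

grow_tree <- function(X, mode, y = numeric(0), w = numeric(0),
                      g = numeric(0), h = numeric(0),
                      rows = seq_len(nrow(X)), max_depth = 30L,
                      max_leaves = .Machine$integer.max,
                      min_samples_split = 2L, min_samples_leaf = 1L,
                      max_features = 0L, reg_lambda = 1, reg_alpha = 0,
                      seed = 1L) {
  cpp_grow_tree(X, mode, as.numeric(y), as.numeric(w), as.numeric(g),
                as.numeric(h), as.integer(rows - 1L), as.integer(max_depth),
                as.integer(max_leaves), as.integer(min_samples_split),
                as.integer(min_samples_leaf), as.integer(max_features),
                reg_lambda, reg_alpha, as.integer(seed))
}

tree_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

fit_svm_binary <- function(spec, X, y) {
  if (!identical(tolower(hp(spec, "kernel") %||% "rbf"), "rbf")) {
    stop("only the RBF kernel is supported")
  }
  center <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[!is.finite(sds) | sds < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, sds, "/")
  list(svm = fit_csvc(Xs, y, C = hp(spec, "C") %||% 1,
                      gamma = hp(spec, "gamma") %||% "scale"),
       center = center, scale = sds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_random_forest <- function(spec, X, y) {
  n_est <- hp(spec, "n_estimators") %||% 115L
  mtry <- max(1L, floor((hp(spec, "max_features") %||% 0.3) * ncol(X)))
  seeds <- tree_seeds(n_est)
  n <- nrow(X)
  trees <- lapply(seq_len(n_est), function(t) {
    rows <- sample.int(n, n, replace = TRUE)
    grow_tree(X, mode = 0L, y = y, w = rep(1, n), rows = rows,
              max_depth = hp(spec, "max_depth") %||% 30L,
              min_samples_split = hp(spec, "min_samples_split") %||% 16L,
              max_features = mtry, seed = seeds[t])
  })
  list(trees = trees)
}

fit_adaboost <- function(spec, X, y) {
  n_est <- hp(spec, "n_estimators") %||% 90L
  lr <- hp(spec, "learning_rate") %||% 1.0
  if (!identical(hp(spec, "algorithm") %||% "SAMME", "SAMME")) {
    stop("only discrete SAMME boosting is implemented")
  }
  n <- nrow(X)
  w <- rep(1 / n, n)
  seeds <- tree_seeds(n_est)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_est)) {
    tr <- grow_tree(X, mode = 0L, y = y, w = w,
                    max_depth = hp(spec, "max_depth") %||% 6L,
                    min_samples_split = hp(spec, "min_samples_split") %||% 2L,
                    seed = seeds[m])
    pred <- as.integer(cpp_predict_tree(tr, X) >= 0.5)
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 1e-12) {            # perfect stump: dominate and stop
      trees <- c(trees, list(tr)); alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) {              # no better than chance: stop boosting
      if (length(trees) == 0L) { trees <- list(tr); alphas <- 1e-10 }
      break
    }
    alpha <- lr * log((1 - err) / err)
    trees <- c(trees, list(tr)); alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(trees = trees, alphas = alphas)
}

fit_gbt <- function(spec, X, y, leafwise) {
  n_est <- hp(spec, "n_estimators") %||% 100L
  lr <- hp(spec, "learning_rate") %||% 0.1
  lambda <- hp(spec, "reg_lambda") %||% 1.0
  alpha <- hp(spec, "reg_alpha") %||% 0.0
  max_depth <- hp(spec, "max_depth") %||% if (leafwise) 50L else 5L
  max_leaves <- if (leafwise) hp(spec, "num_leaves") %||% 31L
                else .Machine$integer.max
  n <- nrow(X)
  seeds <- tree_seeds(n_est)
  f <- rep(0, n)
  trees <- vector("list", n_est)
  importance <- numeric(ncol(X))
  for (m in seq_len(n_est)) {
    p <- plogis(f)
    g <- p - y
    h <- pmax(p * (1 - p), 1e-16)
    tr <- grow_tree(X, mode = 1L, g = g, h = h, max_depth = max_depth,
                    max_leaves = max_leaves, min_samples_split = 2L,
                    reg_lambda = lambda, reg_alpha = alpha, seed = seeds[m])
    trees[[m]] <- tr
    importance <- importance + tr$importance
    f <- f + lr * cpp_predict_tree(tr, X)
  }
  list(trees = trees, lr = lr, importance = importance)
}

# ---- cross-validation -------------------------------------------------------

#' Cross-validation protocol
#'
#' @param folds Number of folds (>= 2), default 10.
#' @param stratified Stratify folds by class (default TRUE).
#' @param seed Integer seed for the fold split (required).
#' @return A list of class `cv_protocol`.
#' @export
cv_protocol <- function(folds = 10L, stratified = TRUE, seed = NULL) {
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(folds = as.integer(folds), stratified = stratified,
                 seed = seed),
            class = "cv_protocol")
}

#' Stratified fold assignment
#'
#' Every sample lands in exactly one fold; fold sizes differ by at most one
#' (per-class remainders go to the currently least-loaded folds).
#'
#' @param labels 0/1 vector.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify by class.
#' @return Integer vector of fold ids in 1..folds.
#' @export
make_folds <- function(labels, folds, seed, stratified = TRUE) {
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  n <- length(labels)
  if (!stratified) return(sample(rep_len(seq_len(folds), n)))
  fold_id <- integer(n)
  load <- integer(folds)
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    base <- length(idx) %/% folds
    extra <- length(idx) %% folds
    gets_extra <- order(load, sample.int(folds))[seq_len(extra)]
    sizes <- rep(base, folds)
    sizes[gets_extra] <- sizes[gets_extra] + 1L
    fold_of <- rep.int(seq_len(folds), sizes)
    fold_id[idx] <- fold_of
    load <- load + sizes
  }
  fold_id
}

#' Cross-validated benchmark of one classifier
#'
#' Stratified k-fold cross-validation. Any class balancing is applied inside
#' each training fold only, never to the test fold, so test metrics are
#' leakage-free. Per-fold accuracy, precision, recall, F1, MCC, Brier-style
#' MSE and AUC are reported together with their arithmetic means over folds;
#' a fold whose test split holds a single class is flagged and its undefined
#' AUC excluded from the AUC mean.
#'
#' @param features `pair_feature_matrix` or numeric matrix.
#' @param labels 0/1 vector aligned with rows.
#' @param spec A `classifier_spec` (seed required).
#' @param protocol A [cv_protocol()] (seed required).
#' @param balance `"none"` (default), `"undersample"`, or `"smote"`; applied
#'   per training fold.
#' @return A `metrics_report`: list with `per_fold` data.frame, `mean` named
#'   list, `spec`, `protocol`.
#' @export
cross_validate <- function(features, labels, spec,
                           protocol = cv_protocol(seed = spec$seed),
                           balance = c("none", "undersample", "smote")) {
  balance <- match.arg(balance)
  X <- as_feature_matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(X)) stop("labels do not align with feature rows")
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (is.null(protocol$seed)) stop("cv_protocol seed is required")

  fold_id <- make_folds(y, protocol$folds, protocol$seed,
                        protocol$stratified)
  per_fold <- vector("list", protocol$folds)
  for (f in seq_len(protocol$folds)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (balance == "undersample") {
      b <- random_undersample(Xtr, ytr, seed = protocol$seed + f)
      Xtr <- b$features; ytr <- b$labels
    } else if (balance == "smote") {
      b <- smote_oversample(Xtr, ytr,
                            balance_spec("SMOTE", seed = protocol$seed + f))
      Xtr <- b$features; ytr <- b$labels
    }
    model <- fit_classifier(spec, Xtr, ytr)
    prob <- predict_prob(model, X[!tr, , drop = FALSE])
    rep_f <- classification_report(y[!tr], prob)
    per_fold[[f]] <- data.frame(fold = f, accuracy = rep_f$accuracy,
                                precision = rep_f$precision,
                                recall = rep_f$recall, f1 = rep_f$f1,
                                mcc = rep_f$mcc, mse = rep_f$mse,
                                auc = rep_f$auc,
                                auc_defined = rep_f$auc_defined)
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "mcc", "mse",
                   "auc")
  means <- lapply(metric_cols, function(m) {
    v <- per_fold[[m]]
    if (m == "auc") v <- v[per_fold$auc_defined]
    mean(v)
  })
  names(means) <- metric_cols
  structure(list(per_fold = per_fold, mean = means, spec = spec,
                 protocol = protocol, balance = balance),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report: ", x$spec$algorithm, ", ", nrow(x$per_fold),
      "-fold CV\n", sep = "")
  cat(sprintf("  mean: acc=%.4f prec=%.4f rec=%.4f f1=%.4f mcc=%.4f ",
              x$mean$accuracy, x$mean$precision, x$mean$recall, x$mean$f1,
              x$mean$mcc))
  cat(sprintf("mse=%.4f auc=%.4f\n", x$mean$mse, x$mean$auc))
  invisible(x)
}

#' Write a metrics report as TSV
#'
#' Column contract: feature_set, algorithm, fold, accuracy, precision,
#' recall, f1, mcc, mse, auc.
#'
#' @param report A `metrics_report`.
#' @param path Output TSV path.
#' @param feature_set Feature-set tag for the first column.
#' @export
write_metrics_report <- function(report, path, feature_set = "ALL") {
  out <- cbind(data.frame(feature_set = feature_set,
                          algorithm = report$spec$algorithm),
               report$per_fold[, c("fold", "accuracy", "precision", "recall",
                                   "f1", "mcc", "mse", "auc")])
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
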