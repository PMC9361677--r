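# Shared fixtures built in code.

# run the reliable-negative selection pipeline on one synthetic dataset
run_negselect <- function(seed, shift = 3, k = NULL,
                          consensus = "ALL_SETS", nu = 0.01,
                          cfg = synth_config(seed = seed,
                                             negative_cluster_shift = shift)) {
  g <- synth_generate(cfg)
  pos <- g$interactions$label == "POSITIVE"
  unk <- !pos
  tabs <- lapply(g$features[c("FS1", "FS2", "FS3", "FS4")], function(fm) {
    model <- fit_one_class(fm$matrix[pos, , drop = FALSE],
                           one_class_spec(nu = nu), folds = 0)
    cand <- subset_fm(fm, unk)
    signed_distances(model, cand)
  })
  if (is.null(k)) k <- sum(g$truth$truth == "TRUE_NEGATIVE")
  sel <- select_negatives(tabs, k = k, consensus = consensus)
  list(data = g, tables = tabs, selection = sel, k = k)
}

subset_fm <- function(fm, idx) {
  dtibalance:::new_pair_feature_matrix(
    fm$feature_set_id, fm$pair_keys[idx, , drop = FALSE],
    fm$matrix[idx, , drop = FALSE], fm$feature_names)
}

# two well-separated Gaussian classes
make_separable <- function(n = 400, p = 20, delta = 2, seed = 5) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n / 2 * p, delta), ncol = p),
             matrix(stats::rnorm(n / 2 * p, -delta), ncol = p))
  list(X = X, y = rep(c(1L, 0L), each = n / 2))
}

# confusion metrics recomputed from explicit label/prediction vectors:
# an oracle independent of the closed-form implementation (MCC via the
# Pearson correlation identity for binary vectors)
vector_confusion_oracle <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  mcc <- suppressWarnings(stats::cor(truth, pred))
  if (is.na(mcc)) mcc <- 0
  list(accuracy = mean(truth == pred),
       precision = if (sum(pred) > 0) mean(truth[pred == 1]) else 0,
       recall = if (sum(truth) > 0) mean(pred[truth == 1]) else 0,
       mcc = mcc)
}

# trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}

# brute-force AUC by enumerating positive-negative pairs
pairwise_auc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

tiny_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
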