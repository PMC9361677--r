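# Baseline class-balancing strategies the framework is compared against:
# random undersampling of the majority class and SMOTE oversampling of the
# minority class. Inside cross_validate() these are applied to training
# folds only.

#' Balancing specification
#'
#' @param method `"RANDOM_UNDERSAMPLE"` or `"SMOTE"`.
#' @param seed Integer seed.
#' @param smote_k Number of nearest minority neighbors for SMOTE
#'   interpolation (default 5; must be < minority class size).
#' @return A list of class `balance_spec`.
#' @export
balance_spec <- function(method = c("RANDOM_UNDERSAMPLE", "SMOTE"),
                         seed = NULL, smote_k = 5L) {
  method <- match.arg(method)
  if (smote_k < 1L) stop("smote_k must be >= 1")
  structure(list(method = method, seed = seed, smote_k = as.integer(smote_k)),
            class = "balance_spec")
}

split_classes <- function(labels) {
  labels <- as.integer(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("both classes must be non-empty")
  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  list(minority = minority, majority = 1L - minority,
       n_min = min(counts), n_maj = max(counts))
}

#' Random undersampling of the majority class
#'
#' Samples the majority class without replacement down to the minority-class
#' size; the minority class is untouched. Deterministic given `seed`.
#'
#' @param features Numeric matrix or `pair_feature_matrix`.
#' @param labels 0/1 vector.
#' @param seed Integer seed.
#' @return List: `features`, `labels`, `index` (rows kept, in original
#'   order).
#' @export
random_undersample <- function(features, labels, seed) {
  X <- as_feature_matrix(features)
  labels <- as.integer(labels)
  cls <- split_classes(labels)
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  maj_idx <- which(labels == cls$majority)
  keep_maj <- sort(sample(maj_idx, cls$n_min))
  idx <- sort(c(which(labels == cls$minority), keep_maj))
  list(features = X[idx, , drop = FALSE], labels = labels[idx], index = idx)
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority rows `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`
#' and `x_nn` one of the `smote_k` nearest minority neighbors of `x_i`
#' (Euclidean, raw feature scale). Output classes are exactly balanced;
#' synthetic rows are flagged.
#'
#' @param features Numeric matrix or `pair_feature_matrix`.
#' @param labels 0/1 vector.
#' @param spec A [balance_spec()] with method `"SMOTE"` and a seed.
#' @return List: `features`, `labels`, `synthetic` (logical flag per row).
#' @export
smote_oversample <- function(features, labels,
                             spec = balance_spec("SMOTE", seed = 1L)) {
  X <- as_feature_matrix(features)
  labels <- as.integer(labels)
  cls <- split_classes(labels)
  k <- spec$smote_k
  if (cls$n_min <= k) {
    stop("minority class size (", cls$n_min, ") must exceed smote_k (", k,
         "); use a smaller smote_k")
  }
  restore <- .Random.seed_guard(spec$seed %||% 1L)
  on.exit(restore(), add = TRUE)

  min_idx <- which(labels == cls$minority)
  M <- X[min_idx, , drop = FALSE]
  d2 <- outer(rowSums(M^2), rowSums(M^2), "+") - 2 * tcrossprod(M)
  diag(d2) <- Inf
  nn <- apply(d2, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1L) matrix(nn, ncol = 1L) else t(nn)

  n_new <- cls$n_maj - cls$n_min
  base <- sample.int(cls$n_min, n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  synth <- M[base, , drop = FALSE] +
    u * (M[pick, , drop = FALSE] - M[base, , drop = FALSE])

  features_out <- rbind(X, synth)
  rownames(features_out) <- NULL
  list(features = features_out,
       labels = c(labels, rep(cls$minority, n_new)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
}
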