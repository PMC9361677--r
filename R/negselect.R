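# Reliable-negative selection: a one-class SVM learns the region occupied by
# the known positive pairs in each feature set; unlabeled pairs get a signed
# distance to that boundary (>= 0 inside, < 0 outside); a consensus over the
# four feature sets picks the most outlying pairs as predicted negatives.

#' One-class SVM model specification
#'
#' @param kernel Only `"RBF"` is supported.
#' @param nu Upper bound on the fraction of training positives treated as
#'   outliers and lower bound on the fraction of support vectors; the
#'   framework's default is 0.01.
#' @param gamma RBF bandwidth: a positive number or `"scale"`
#'   (1 / (n_features * var)).
#' @return A list of class `one_class_spec`.
#' @export
one_class_spec <- function(kernel = "RBF", nu = 0.01, gamma = "scale") {
  if (!identical(kernel, "RBF")) stop("only the RBF kernel is supported")
  if (!is.numeric(nu) || nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  structure(list(kernel = kernel, nu = nu, gamma = gamma),
            class = "one_class_spec")
}

as_feature_matrix <- function(x) {
  if (inherits(x, "pair_feature_matrix")) return(x$matrix)
  if (is.matrix(x)) return(x)
  stop("expected a pair_feature_matrix or a numeric matrix")
}

pair_keys_of <- function(x) {
  if (inherits(x, "pair_feature_matrix")) {
    return(paste(x$pair_keys$drug_id, x$pair_keys$protein_id, sep = "|"))
  }
  m <- as_feature_matrix(x)
  if (!is.null(rownames(m))) rownames(m) else sprintf("row%06d", seq_len(nrow(m)))
}

#' Fit a one-class SVM on positive pairs
#'
#' Trains on positives only. Features are standardized (center/scale learned
#' from the positives; constant columns left unscaled) before the RBF kernel,
#' since per-set feature scales are incommensurable. Ten-fold diagnostics
#' report how well held-out positives are recognized as inliers: recall (and
#' accuracy) is the held-out inlier fraction; precision is trivially 1 when
#' any held-out positive is recognized because no negatives enter the fold.
#'
#' @param positive_features `pair_feature_matrix` (or numeric matrix) of the
#'   positive pairs.
#' @param spec A [one_class_spec()].
#' @param folds Number of diagnostic folds (default 10); set 0 to skip.
#' @param seed Integer seed for the fold split (required when folds > 0).
#' @param scale Standardize features before the kernel (default TRUE).
#' @return An object of class `one_class_svm` with fields `alpha`, `rho`,
#'   `gamma`, `sv` and `fold_diagnostics` (data.frame with per-fold
#'   precision/recall/f1/accuracy).
#' @export
fit_one_class <- function(positive_features, spec = one_class_spec(),
                          folds = 10L, seed = NULL, scale = TRUE) {
  X <- as_feature_matrix(positive_features)
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (folds > 0 && nrow(X) < folds) {
    stop("need at least `folds` (", folds, ") positive rows, got ", nrow(X))
  }
  if (folds > 0 && is.null(seed)) stop("seed is required for fold diagnostics")

  center <- if (scale) colMeans(X) else rep(0, ncol(X))
  sds <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  sds[!is.finite(sds) | sds < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, sds, "/")

  fit_core <- function(Xtr) {
    gamma <- resolve_gamma(spec$gamma, Xtr)
    K <- rbf_kernel(Xtr, gamma = gamma)
    sol <- solve_ocsvm_dual(K, spec$nu)
    keep <- sol$alpha > 1e-10 * sol$C
    list(sv = Xtr[keep, , drop = FALSE], alpha = sol$alpha[keep],
         rho = sol$rho, gamma = gamma)
  }

  diagnostics <- NULL
  if (folds > 0) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    fold_id <- sample(rep_len(seq_len(folds), nrow(Xs)))
    diagnostics <- do.call(rbind, lapply(seq_len(folds), function(f) {
      core <- fit_core(Xs[fold_id != f, , drop = FALSE])
      d <- ocsvm_decision(core, Xs[fold_id == f, , drop = FALSE])
      tp <- sum(d >= 0); fn <- sum(d < 0)
      recall <- tp / (tp + fn)
      precision <- if (tp > 0) 1 else 0
      f1 <- if (precision + recall > 0)
        2 * precision * recall / (precision + recall) else 0
      data.frame(fold = f, precision = precision, recall = recall,
                 f1 = f1, accuracy = recall)
    }))
  }

  core <- fit_core(Xs)
  structure(list(sv = core$sv, alpha = core$alpha, rho = core$rho,
                 gamma = core$gamma, center = center, scale = sds,
                 n_features = ncol(X), spec = spec,
                 fold_diagnostics = diagnostics),
            class = "one_class_svm")
}

# RNG guard: run under a seed, restore previous RNG state after
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

ocsvm_decision <- function(core, Xs) {
  if (nrow(Xs) == 0L) return(numeric(0))
  as.vector(rbf_kernel(Xs, core$sv, core$gamma) %*% core$alpha) - core$rho
}

#' Signed distances of candidate pairs to the positive boundary
#'
#' Applies the model's stored standardization, then evaluates the one-class
#' decision function: `>= 0` inside the positive region, `< 0` outside.
#' Candidates can be scored in chunks; results are per-pair deterministic so
#' chunking cannot change them.
#'
#' @param model A fitted [fit_one_class()] model.
#' @param candidates `pair_feature_matrix` (or matrix) with the same feature
#'   width as the training data.
#' @param feature_set_id Tag recorded in the output (defaults to the
#'   candidates' own id when available).
#' @param chunk_size Number of rows scored per block.
#' @return A data.frame (distance table) with columns `pair_key`,
#'   `feature_set_id`, `distance`.
#' @export
signed_distances <- function(model, candidates, feature_set_id = NULL,
                             chunk_size = 50000L) {
  X <- as_feature_matrix(candidates)
  if (ncol(X) != model$n_features) {
    stop("candidate width ", ncol(X), " != training width ", model$n_features)
  }
  if (is.null(feature_set_id)) {
    feature_set_id <- if (inherits(candidates, "pair_feature_matrix"))
      candidates$feature_set_id else "FS?"
  }
  keys <- pair_keys_of(candidates)
  n <- nrow(X)
  if (n == 0L) {
    return(data.frame(pair_key = character(0),
                      feature_set_id = character(0),
                      distance = numeric(0)))
  }
  dist <- numeric(n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    Xs <- sweep(sweep(X[idx, , drop = FALSE], 2, model$center),
                2, model$scale, "/")
    dist[idx] <- ocsvm_decision(model, Xs)
  }
  if (any(!is.finite(dist))) stop("non-finite signed distance")
  data.frame(pair_key = keys, feature_set_id = feature_set_id,
             distance = dist, stringsAsFactors = FALSE)
}

#' Consensus selection of predicted-negative pairs
#'
#' Combines per-feature-set distance tables: each set's distances are
#' z-scored (set widths 50-1424 make raw scales incomparable), the combined
#' score is the mean standardized distance, and qualifying candidates are
#' ranked most-outlying first (ascending combined score; ties broken by
#' `pair_key` lexicographic order). Qualification by consensus rule:
#' `ALL_SETS` (default) requires raw distance < 0 in every set, `ANY_SET` in
#' at least one set, `MEAN_SCORE` requires combined score < 0.
#'
#' @param tables Named list of distance tables from [signed_distances()],
#'   one per feature set, all covering the same pairs.
#' @param k Number of negatives requested (>= 1). If fewer candidates
#'   qualify, all qualifiers are returned with a `shortfall` warning flag.
#' @param consensus Consensus rule, see above.
#' @return An object of class `negative_selection`: `selected` (pair keys,
#'   most outlying first), `combined_score`, `per_set_distance` matrix,
#'   `k_requested`, `shortfall`.
#' @export
select_negatives <- function(tables, k,
                             consensus = c("ALL_SETS", "ANY_SET",
                                           "MEAN_SCORE")) {
  consensus <- match.arg(consensus)
  if (k < 1) stop("k must be >= 1")
  if (length(tables) < 1L) stop("need at least one distance table")
  ref_keys <- sort(tables[[1L]]$pair_key)
  D <- sapply(tables, function(tb) {
    if (!identical(sort(tb$pair_key), ref_keys)) {
      stop("distance tables cover inconsistent pair sets")
    }
    tb$distance[match(ref_keys, tb$pair_key)]
  })
  D <- matrix(D, nrow = length(ref_keys),
              dimnames = list(ref_keys, names(tables)))

  Z <- apply(D, 2, function(d) {
    s <- stats::sd(d)
    if (!is.finite(s) || s < 1e-12) s <- 1
    (d - mean(d)) / s
  })
  Z <- matrix(Z, nrow = nrow(D), dimnames = dimnames(D))
  combined <- rowMeans(Z)

  qualifies <- switch(consensus,
    ALL_SETS = rowSums(D < 0) == ncol(D),
    ANY_SET = rowSums(D < 0) > 0,
    MEAN_SCORE = combined < 0)

  cand <- ref_keys[qualifies]
  ord <- order(combined[qualifies], cand, method = "radix")
  cand <- cand[ord]
  shortfall <- length(cand) < k
  if (shortfall) {
    warning("only ", length(cand), " candidates qualify under ", consensus,
            " (k = ", k, ")")
  }
  sel <- utils::head(cand, k)
  structure(list(selected = sel,
                 combined_score = combined[sel],
                 per_set_distance = D[sel, , drop = FALSE],
                 all_scores = combined,
                 k_requested = as.integer(k),
                 consensus = consensus,
                 shortfall = shortfall),
            class = "negative_selection")
}

#' @export
print.negative_selection <- function(x, ...) {
  cat("negative_selection: ", length(x$selected), " of ", x$k_requested,
      " requested (", x$consensus, ")\n", sep = "")
  invisible(x)
}

selection_pairs <- function(selection) {
  parts <- strsplit(selection$selected, "|", fixed = TRUE)
  interaction_set(vapply(parts, `[[`, "", 1L),
                  vapply(parts, `[[`, "", 2L),
                  "PREDICTED_NEGATIVE")
}

#' Build the balanced labeled interaction set
#'
#' Positives plus the selected predicted negatives. The recommended
#' `k = nrow(positives)` yields a 1:1 class ratio; a shortfall in the
#' selection produces an imbalance warning.
#'
#' @param positives `interaction_set` of POSITIVE pairs.
#' @param selection A [select_negatives()] result.
#' @return An `interaction_set` with labels POSITIVE and PREDICTED_NEGATIVE.
#' @export
build_balanced_set <- function(positives, selection) {
  negs <- selection_pairs(selection)
  pos_key <- paste(positives$drug_id, positives$protein_id, sep = "|")
  if (any(selection$selected %in% pos_key)) {
    stop("selection overlaps the positive set")
  }
  if (nrow(negs) < nrow(positives)) {
    warning("class imbalance: ", nrow(positives), " positives vs ",
            nrow(negs), " predicted negatives")
  }
  out <- rbind(as.data.frame(positives), as.data.frame(negs))
  interaction_set(out$drug_id, out$protein_id, out$label)
}
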