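# Feature-importance selection: a genetic-algorithm search over binary
# column masks with a fast tree-ensemble CV fitness, and a booster
# gain-importance ranking. Either mask feeds the downstream benchmark
# classifier, which is re-trained on the masked columns.

#' Genetic-algorithm configuration
#'
#' Operator choices are documented package defaults (the search design is
#' open in the source method): tournament selection of size 3, uniform
#' crossover, per-bit mutation 1/L, elitism 1.
#'
#' @param population Population size (>= 2), default 50.
#' @param generations Number of generations, default 20.
#' @param crossover_rate,mutation_rate Rates in \[0, 1\]; `mutation_rate =
#'   NULL` means 1/L per bit.
#' @param fitness_folds CV folds used in the fitness function, default 3.
#' @param elitism Number of elites carried over unchanged, default 1.
#' @param seed Integer seed (required).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 50L, generations = 20L,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      fitness_folds = 3L, elitism = 1L, seed = NULL) {
  if (population < 2L) stop("population must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1) stop("invalid crossover_rate")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 fitness_folds = as.integer(fitness_folds),
                 elitism = as.integer(elitism), seed = seed),
            class = "ga_config")
}

# fast fitness: mean CV accuracy of a small depth-wise booster on the
# masked columns, with folds fixed once so all masks are compared paired
mask_fitness_fn <- function(X, y, folds, fold_id) {
  cache <- new.env(parent = emptyenv())
  function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    Xm <- X[, mask, drop = FALSE]
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      spec <- classifier_spec("XGBOOST",
                              list(n_estimators = 15L, max_depth = 3L,
                                   learning_rate = 0.3), seed = 97L)
      model <- fit_classifier(spec, Xm[tr, , drop = FALSE], y[tr])
      mean((predict_prob(model, Xm[!tr, , drop = FALSE]) >= 0.5) == y[!tr])
    }, numeric(1))
    cache[[key]] <- mean(acc)
    cache[[key]]
  }
}

#' Genetic-algorithm feature-mask search
#'
#' Evolves binary column masks; fitness is the mean cross-validated accuracy
#' of a fast shallow booster restricted to the masked columns (the final
#' benchmark re-trains the full classifier on the winning mask). Elitism
#' makes the reported best fitness non-decreasing across generations. After
#' the search, one backward-elimination sweep drops, in column order, every
#' bit whose removal does not reduce fitness, so ties resolve to the
#' lexicographically smallest equivalent mask. Deterministic given
#' `cfg$seed`.
#'
#' @param features Numeric matrix or `pair_feature_matrix` (>= 2 columns).
#' @param labels 0/1 vector, both classes present.
#' @param cfg A [ga_config()] with a seed.
#' @return A list of class `feature_mask`: `bits` (logical vector over
#'   columns), `fitness`, `history` (best fitness per generation).
#' @export
ga_select <- function(features, labels, cfg = ga_config(seed = 1L)) {
  X <- as_feature_matrix(features)
  y <- as.integer(labels)
  if (ncol(X) < 2L) stop("need at least 2 feature columns")
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (is.null(cfg$seed)) stop("ga_config seed is required")
  restore <- .Random.seed_guard(cfg$seed)
  on.exit(restore(), add = TRUE)

  L <- ncol(X)
  pmut <- cfg$mutation_rate %||% (1 / L)
  fold_id <- make_folds(y, cfg$fitness_folds, seed = cfg$seed + 1L)
  fitness <- mask_fitness_fn(X, y, cfg$fitness_folds, fold_id)

  random_mask <- function() {
    m <- stats::runif(L) < 0.5
    if (!any(m)) m[sample.int(L, 1L)] <- TRUE
    m
  }
  pop <- replicate(cfg$population, random_mask(), simplify = FALSE)
  fit <- vapply(pop, fitness, numeric(1))
  history <- numeric(cfg$generations)

  tournament <- function() {
    cand <- sample.int(cfg$population, 3L, replace = TRUE)
    cand[which.max(fit[cand])]
  }

  for (gen in seq_len(cfg$generations)) {
    elite_ord <- order(-fit)
    newpop <- pop[elite_ord[seq_len(cfg$elitism)]]
    while (length(newpop) < cfg$population) {
      p1 <- pop[[tournament()]]; p2 <- pop[[tournament()]]
      child <- if (stats::runif(1) < cfg$crossover_rate) {
        take1 <- stats::runif(L) < 0.5
        ifelse(take1, p1, p2)
      } else p1
      flip <- stats::runif(L) < pmut
      child <- xor(child, flip)
      if (!any(child)) child[sample.int(L, 1L)] <- TRUE
      newpop <- c(newpop, list(child))
    }
    pop <- newpop
    fit <- vapply(pop, fitness, numeric(1))
    history[gen] <- max(fit)
  }

  best <- pop[[which.max(fit)]]
  best_fit <- max(fit)
  # canonicalization: (a) backward elimination in column order drops bits
  # whose removal does not reduce fitness; (b) a shift-left pass moves the
  # highest selected column down to the earliest free column when fitness
  # ties. Together they resolve fitness ties to the lexicographically
  # smallest equivalent mask.
  for (j in which(best)) {
    if (sum(best) == 1L) break
    trial <- best; trial[j] <- FALSE
    if (fitness(trial) >= best_fit) {
      best <- trial
      best_fit <- fitness(trial)
    }
  }
  for (i in seq_len(L)) {
    if (best[i]) next
    j <- max(which(best))
    if (j <= i) break
    trial <- best; trial[j] <- FALSE; trial[i] <- TRUE
    if (fitness(trial) >= best_fit) {
      best <- trial
      best_fit <- fitness(trial)
    }
  }
  structure(list(bits = best, fitness = best_fit, history = history,
                 feature_names = colnames(X)),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat("feature_mask: ", sum(x$bits), "/", length(x$bits),
      " columns, fitness ", format(x$fitness, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Booster gain-importance feature selection
#'
#' Fits a depth-wise second-order gradient booster and ranks columns by
#' total split gain; the mask keeps the `top_k` columns (ties broken by
#' column index). A constant column can never be split on, so its importance
#' is 0 and it ranks after every split-used column.
#'
#' @param features Numeric matrix or `pair_feature_matrix`.
#' @param labels 0/1 vector.
#' @param top_k Number of columns to keep (1 <= top_k <= ncol).
#' @param seed Integer seed.
#' @return A `feature_mask` with an extra `importance` vector.
#' @export
booster_importance_select <- function(features, labels, top_k, seed = 1L) {
  X <- as_feature_matrix(features)
  y <- as.integer(labels)
  if (top_k < 1L) stop("top_k must be >= 1")
  if (top_k > ncol(X)) {
    stop("top_k (", top_k, ") exceeds feature count (", ncol(X), ")")
  }
  model <- fit_classifier(default_spec("XGBOOST", seed = seed), X, y)
  imp <- model$importance
  keep <- order(-imp, seq_along(imp))[seq_len(top_k)]
  bits <- seq_along(imp) %in% keep
  structure(list(bits = bits, fitness = NA_real_, importance = imp,
                 feature_names = colnames(X)),
            class = "feature_mask")
}

#' Persist / load a feature mask as a feature-name list
#' @param mask A `feature_mask` (needs feature names).
#' @param path Text file, one selected feature name per line.
#' @export
write_feature_mask <- function(mask, path) {
  if (is.null(mask$feature_names)) stop("mask has no feature names")
  writeLines(mask$feature_names[mask$bits], path)
  invisible(path)
}

#' @rdname write_feature_mask
#' @param feature_names Full column-name vector the mask indexes into.
#' @export
read_feature_mask <- function(path, feature_names) {
  sel <- readLines(path, warn = FALSE)
  bad <- setdiff(sel, feature_names)
  if (length(bad) > 0L) stop("unknown feature name in mask file: ", bad[1L])
  structure(list(bits = feature_names %in% sel, fitness = NA_real_,
                 feature_names = feature_names),
            class = "feature_mask")
}
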