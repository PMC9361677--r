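test_that("one_class_spec validates its domain", {
  expect_error(one_class_spec(kernel = "linear"), "RBF")
  expect_error(one_class_spec(nu = 0), "nu")
  expect_error(one_class_spec(nu = 1.5), "nu")
  expect_equal(one_class_spec()$nu, 0.01)
})

test_that("fit_one_class enforces preconditions", {
  X <- matrix(rnorm(40), ncol = 4)
  expect_error(fit_one_class(X, folds = 20, seed = 1), "at least")
  X[1, 1] <- NA
  expect_error(fit_one_class(X, folds = 0), "non-finite")
  expect_error(fit_one_class(matrix(rnorm(40), ncol = 2), folds = 10),
               "seed")
})

test_that("nu bounds the training outlier fraction", {
  set.seed(31)
  X <- matrix(rnorm(200 * 3), ncol = 3)
  m <- fit_one_class(X, one_class_spec(nu = 0.05), folds = 0)
  d <- signed_distances(m, X)$distance
  # free support vectors sit numerically at zero: count strict outliers
  expect_lte(mean(d < -1e-6), 0.05 + 1e-9)
  # held-out positives from the same cluster are mostly recognized
  m2 <- fit_one_class(X, one_class_spec(nu = 0.01), folds = 10, seed = 2)
  expect_gte(mean(m2$fold_diagnostics$recall), 0.7)
  expect_equal(m2$fold_diagnostics$accuracy, m2$fold_diagnostics$recall)
})

test_that("nu = 1 turns nearly all training points into boundary/outliers", {
  set.seed(32)
  X <- matrix(rnorm(60 * 2), ncol = 2)
  m <- fit_one_class(X, one_class_spec(nu = 1), folds = 10, seed = 3)
  expect_lte(mean(m$fold_diagnostics$recall), 0.2)
})

test_that("a degenerate duplicated cloud scores itself inside", {
  X <- matrix(rep(c(1, 2, 3), each = 50), nrow = 50)
  m <- fit_one_class(X, one_class_spec(nu = 0.1), folds = 0)
  expect_true(all(signed_distances(m, X)$distance >= -1e-9))
})

test_that("signed distances: deep inliers positive, far field negative", {
  set.seed(33)
  X <- matrix(rnorm(150 * 4), ncol = 4)
  m <- fit_one_class(X, one_class_spec(nu = 0.05), folds = 0, scale = FALSE)
  centroid <- matrix(colMeans(X), nrow = 1)
  expect_gt(signed_distances(m, centroid)$distance, 0)
  far <- matrix(100, nrow = 1, ncol = 4)
  expect_lt(signed_distances(m, far)$distance, 0)
  empty <- m
  tab <- signed_distances(m, X[0, , drop = FALSE])
  expect_equal(nrow(tab), 0L)
  expect_error(signed_distances(m, X[, 1:2]), "width")
})

test_that("select_negatives consensus rules and ranking contracts", {
  keys <- c("A|1", "B|1", "C|1")
  tab <- function(fs, d) data.frame(pair_key = keys, feature_set_id = fs,
                                    distance = d)
  # inside (>= 0) in FS2 only, outside elsewhere; ALL_SETS -> empty
  tabs <- list(FS1 = tab("FS1", c(-1, -2, -3)),
               FS2 = tab("FS2", c(1, 2, 3)),
               FS3 = tab("FS3", c(-1, -2, -3)),
               FS4 = tab("FS4", c(-0.5, -1, -2)))
  expect_warning(sel <- select_negatives(tabs, k = 2), "qualify")
  expect_equal(length(sel$selected), 0L)
  expect_true(sel$shortfall)
  # ANY_SET admits them
  sel <- select_negatives(tabs, k = 3, consensus = "ANY_SET")
  expect_equal(sel$selected, c("C|1", "B|1", "A|1"))

  # dominance: C strictly most negative in every set ranks first
  tabs <- list(FS1 = tab("FS1", c(-1, -2, -5)),
               FS2 = tab("FS2", c(-2, -1, -6)),
               FS3 = tab("FS3", c(-3, -2, -9)),
               FS4 = tab("FS4", c(-1, -4, -8)))
  sel <- select_negatives(tabs, k = 1)
  expect_equal(sel$selected, "C|1")

  # inconsistent coverage errors
  bad <- tabs
  bad$FS4 <- bad$FS4[1:2, ]
  expect_error(select_negatives(bad, k = 1), "inconsistent")
  expect_error(select_negatives(tabs, k = 0), "k must be")
})

test_that("combined ranking matches a brute-force re-sort oracle", {
  set.seed(34)
  n <- 600
  keys <- sprintf("D%03d|P%03d", sample(n), sample(n))
  tabs <- lapply(c(FS1 = 1, FS2 = 2, FS3 = 3, FS4 = 4), function(i) {
    data.frame(pair_key = keys, feature_set_id = paste0("FS", i),
               distance = rnorm(n, sd = i))
  })
  # oracle: plain-R z-score, mean, filter, sort (~600*(1/2)^4 ~ 37 qualify)
  D <- sapply(tabs, function(tb) tb$distance[match(sort(keys), tb$pair_key)])
  Z <- scale(D)
  comb <- rowMeans(Z)
  qual <- rowSums(D < 0) == 4
  ord <- order(comb[qual], sort(keys)[qual])
  k <- min(25L, sum(qual))
  sel <- select_negatives(tabs, k = k)
  expect_equal(sel$selected, sort(keys)[qual][ord][seq_len(k)])
  # prefix property: growing k never removes earlier selections
  sel2 <- suppressWarnings(select_negatives(tabs, k = 1000))
  expect_equal(length(sel2$selected), sum(qual))
  expect_equal(sel2$selected[seq_len(k)], sel$selected)
})

test_that("selection recovers planted negatives and stays within unknowns", {
  run <- run_negselect(seed = 101)
  sel <- run$selection
  pos_keys <- with(run$data$interactions[
    run$data$interactions$label == "POSITIVE", ],
    paste(drug_id, protein_id, sep = "|"))
  expect_false(any(sel$selected %in% pos_keys))
  rep <- truth_report(sel, run$data$truth)
  expect_gte(rep$precision, 0.8)

  lab <- build_balanced_set(
    interaction_set(
      run$data$interactions$drug_id[run$data$interactions$label == "POSITIVE"],
      run$data$interactions$protein_id[
        run$data$interactions$label == "POSITIVE"],
      "POSITIVE"),
    sel)
  expect_true(all(lab$label %in% c("POSITIVE", "PREDICTED_NEGATIVE")))
})

test_that("build_balanced_set balances and flags shortfalls", {
  pos <- interaction_set(sprintf("D%02d", 1:50), rep("P1", 50), "POSITIVE")
  mk_sel <- function(keys) {
    structure(list(selected = keys,
                   combined_score = seq_along(keys),
                   per_set_distance = NULL,
                   all_scores = stats::setNames(seq_along(keys), keys),
                   k_requested = 50L, consensus = "ALL_SETS",
                   shortfall = length(keys) < 50),
              class = "negative_selection")
  }
  sel <- mk_sel(sprintf("E%02d|P2", 1:50))
  bal <- build_balanced_set(pos, sel)
  expect_equal(nrow(bal), 100L)
  expect_equal(unname(table(bal$label)["POSITIVE"]), 50L)

  expect_warning(bal <- build_balanced_set(pos, mk_sel(sprintf("E%02d|P2", 1:30))),
                 "imbalance")
  expect_equal(nrow(bal), 80L)

  overlap <- mk_sel(c("D01|P1", "E01|P2"))
  expect_error(build_balanced_set(pos, overlap), "overlap")
})
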