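test_that("synth_config validates its domain", {
  expect_error(synth_config(positive_rate = 0.6), "positive_rate")
  expect_error(synth_config(positive_rate = 0), "positive_rate")
  expect_error(synth_config(negative_cluster_shift = -1), "shift")
  expect_error(synth_generate(synth_config(n_drugs = 3, n_proteins = 3,
                                           positive_rate = 0.01)),
               "infeasible")
})

test_that("quantile count arithmetic fixes the truth-positive count", {
  g <- synth_generate(synth_config(n_drugs = 30, n_proteins = 30,
                                   positive_rate = 0.05, seed = 1))
  expect_equal(nrow(g$interactions), 900L)
  expect_equal(sum(g$truth$truth == "TRUE_POSITIVE"), 45L)
  # observed positives are a subset of truth positives; the rest are latent
  obs <- g$interactions$label == "POSITIVE"
  expect_true(all(g$truth$truth[obs] == "TRUE_POSITIVE"))
  expect_gt(sum(g$truth$truth == "TRUE_POSITIVE" & !obs), 0L)
  # planted negatives are all unlabeled
  expect_true(all(g$interactions$label[g$truth$truth == "TRUE_NEGATIVE"] ==
                    "UNKNOWN"))
})

test_that("same seed gives identical output, different seed differs", {
  cfg <- synth_config(n_drugs = 15, n_proteins = 15, seed = 4)
  a <- synth_generate(cfg)
  b <- synth_generate(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$features$ALL$matrix, b$features$ALL$matrix)
  expect_identical(a$drugs, b$drugs)
  c <- synth_generate(synth_config(n_drugs = 15, n_proteins = 15, seed = 5))
  expect_false(identical(a$truth$truth, c$truth$truth))
})

test_that("generated blocks satisfy the descriptor invariants", {
  g <- synth_generate(synth_config(n_drugs = 12, n_proteins = 12, seed = 6))
  widths <- c(FS1 = 1044L, FS2 = 1424L, FS3 = 50L, FS4 = 430L, ALL = 1474L)
  for (fs in names(widths)) {
    expect_equal(ncol(g$features[[fs]]$matrix), unname(widths[[fs]]))
  }
  morgan <- g$features$FS1$matrix[, 1:1024]
  expect_true(all(morgan %in% c(0, 1)))
  aac <- g$features$FS1$matrix[, 1025:1044]
  expect_true(all(aac >= 0))
  expect_equal(unname(rowSums(aac)), rep(1, nrow(aac)), tolerance = 1e-9)
  dc <- g$features$FS2$matrix[, 1025:1424]
  expect_true(all(dc >= 0))
  expect_equal(unname(rowSums(dc)), rep(1, nrow(dc)), tolerance = 1e-9)
})

test_that("synthetic files round-trip through the io layer", {
  g <- synth_generate(synth_config(n_drugs = 8, n_proteins = 8, seed = 7))
  dir <- withr::local_tempdir()
  synth_write(g, dir)
  drugs <- read_drug_table(file.path(dir, "drugs.tsv"))
  expect_equal(drugs, g$drugs, ignore_attr = TRUE)
  prots <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_equal(prots$sequence, g$proteins$sequence)
  pos <- read_pairs(file.path(dir, "positives.tsv"))
  expect_equal(nrow(pos), sum(g$interactions$label == "POSITIVE"))
  # pair-universe bookkeeping: positives + unknowns = full grid
  unk <- enumerate_unknown_pairs(drugs, prots, pos)
  expect_equal(nrow(unk) + nrow(pos), 64L)
})

test_that("SMILES_FASTA mode emits parseable records without features", {
  g <- synth_generate(synth_config(n_drugs = 10, n_proteins = 10, seed = 8,
                                   mode = "SMILES_FASTA"))
  expect_null(g$features)
  expect_true(all(nzchar(g$drugs$smiles)))
  expect_true(all(nchar(g$proteins$sequence) >= 50))
  expect_true(all(strsplit(paste(g$proteins$sequence, collapse = ""),
                           "")[[1]] %in% AA_ALPHABET))
})

test_that("truth_report scores selections against the oracle", {
  g <- synth_generate(synth_config(n_drugs = 10, n_proteins = 10, seed = 9))
  planted <- g$truth$pair_key[g$truth$truth == "TRUE_NEGATIVE"]
  r <- truth_report(planted, g$truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_warning(r0 <- truth_report(character(0), g$truth), "empty")
  expect_equal(r0$precision, 0)
  expect_error(truth_report("D9999|P9999", g$truth), "missing")
})

test_that("random selection precision concentrates at the planted rate", {
  g <- synth_generate(synth_config(seed = 10))
  unk <- g$truth$pair_key[g$interactions$label == "UNKNOWN"]
  rate <- mean(g$truth$truth[g$interactions$label == "UNKNOWN"] ==
                 "TRUE_NEGATIVE")
  set.seed(10)
  prec <- replicate(20, {
    truth_report(sample(unk, 100), g$truth, universe = unk)$precision
  })
  se <- sqrt(rate * (1 - rate) / 100)
  expect_lt(abs(mean(prec) - rate), 4 * se / sqrt(20) + 0.01)
})

test_that("selection precision is monotone in the cluster shift", {
  shifts <- c(0, 1, 3)
  prec <- sapply(shifts, function(sh) {
    mean(vapply(1:3, function(s) {
      run <- run_negselect(seed = 200 + s, shift = sh)
      truth_report(run$selection, run$data$truth)$precision
    }, numeric(1)))
  })
  expect_true(all(diff(prec) >= -0.02))
  expect_gt(prec[3], prec[1] + 0.3)
})
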