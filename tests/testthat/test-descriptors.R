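test_that("compute_aac matches hand counts and normalizes", {
  a <- compute_aac("AAAA")
  expect_equal(unname(a[["aac_A"]]), 1)
  expect_equal(sum(a), 1)
  expect_equal(length(a), 20L)

  u <- compute_aac("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(abs(u - 0.05) < 1e-12))

  m <- compute_aac("MKVM")
  expect_equal(unname(m[c("aac_M", "aac_K", "aac_V")]), c(0.5, 0.25, 0.25))

  expect_error(compute_aac("MKX"), "'X'")
  expect_equal(unname(compute_aac("MKX", policy = "drop")[["aac_M"]]), 0.5)
})

test_that("compute_dipeptide matches window enumeration", {
  d <- compute_dipeptide("AAA")
  expect_equal(unname(d[["dc_AA"]]), 1)
  expect_equal(length(d), 400L)
  expect_equal(names(d)[1], "dc_AA")
  expect_equal(names(d)[400], "dc_YY")

  d <- compute_dipeptide("ACAC")
  expect_equal(unname(d[["dc_AC"]]), 2 / 3)
  expect_equal(unname(d[["dc_CA"]]), 1 / 3)

  expect_error(compute_dipeptide("A"), "length >= 2")
})

test_that("AAC and DC always lie on the probability simplex", {
  set.seed(21)
  for (i in 1:20) {
    seq <- paste(sample(AA_ALPHABET, sample(2:200, 1), replace = TRUE),
                 collapse = "")
    a <- compute_aac(seq)
    d <- compute_dipeptide(seq)
    expect_true(all(a >= 0) && abs(sum(a) - 1) < 1e-9)
    expect_true(all(d >= 0) && abs(sum(d) - 1) < 1e-9)
  }
})

test_that("Morgan fingerprints are 1024-bit, binary, spelling-invariant", {
  fp <- compute_morgan(c("CCO", "c1ccccc1", "C1=CC=CC=C1", "OCC", "CC(=O)O"))
  expect_equal(ncol(fp), 1024L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(fp[2, ], fp[3, ])      # benzene, kekulized spelling
  expect_identical(fp[1, ], fp[4, ])      # ethanol, reversed spelling
  expect_false(identical(fp[1, ], fp[5, ]))

  # toolkit canonicalization oracle
  expect_equal(canonical_smiles("c1ccccc1"), canonical_smiles("C1=CC=CC=C1"))
})

test_that("unparseable SMILES raise a structured error", {
  err <- tryCatch(compute_morgan("C(("), error = identity)
  expect_s3_class(err, "smiles_parse_error")
  expect_equal(err$smiles, "C((")
  expect_match(conditionMessage(err), "C((", fixed = TRUE)
})

test_that("constitutional block has the frozen 30 descriptors", {
  cd <- compute_constitutional(c("C", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"))
  expect_equal(ncol(cd), 30L)
  expect_identical(colnames(cd), dtibalance:::CONSTITUTIONAL_NAMES)
  expect_true(all(is.finite(cd)))
  # methane
  expect_equal(unname(cd[1, "heavy_atom_count"]), 1)
  expect_equal(unname(cd[1, "ring_count"]), 0)
  # benzene: hand counts from the structure
  expect_equal(unname(cd[2, "n_C"]), 6)
  expect_equal(unname(cd[2, "ring_count"]), 1)
  expect_equal(unname(cd[2, "aromatic_bonds"]), 6)
  expect_equal(unname(cd[2, "n_H_total"]), 6)
  # aspirin: 9 carbons, 4 oxygens
  expect_equal(unname(cd[3, "n_C"]), 9)
  expect_equal(unname(cd[3, "n_O"]), 4)
})

make_fake_blocks <- function(drug_ids, protein_ids) {
  fake <- function(ids, width, prefix) {
    m <- matrix(seq_len(length(ids) * width), nrow = length(ids),
                dimnames = list(ids, paste0(prefix, seq_len(width))))
    m
  }
  list(drug = list(MORGAN = fake(drug_ids, 1024L, "m"),
                   CONSTITUTIONAL = fake(drug_ids, 30L, "c")),
       protein = list(AAC = fake(protein_ids, 20L, "a"),
                      DC = fake(protein_ids, 400L, "d")))
}

test_that("pair feature widths follow the five recipes", {
  blocks <- make_fake_blocks(c("D1", "D2"), c("P1", "P2", "P3"))
  pairs <- interaction_set(c("D1", "D2", "D1"), c("P1", "P2", "P3"))
  widths <- c(FS1 = 1044L, FS2 = 1424L, FS3 = 50L, FS4 = 430L, ALL = 1474L)
  for (fs in names(widths)) {
    fm <- build_pair_features(pairs, blocks$drug, blocks$protein, fs)
    expect_equal(ncol(fm$matrix), unname(widths[[fs]]))
    expect_equal(nrow(fm$matrix), 3L)
  }
  # ALL is drug blocks then protein blocks
  fm <- build_pair_features(pairs, blocks$drug, blocks$protein, "ALL")
  expect_equal(fm$feature_names[1], "m1")
  expect_equal(fm$feature_names[1025], "c1")
  expect_equal(fm$feature_names[1055], "a1")
  expect_equal(fm$feature_names[1075], "d1")
})

test_that("pair assembly is stateless: permuting pairs permutes rows", {
  blocks <- make_fake_blocks(c("D1", "D2"), c("P1", "P2"))
  pairs <- interaction_set(c("D1", "D2", "D1", "D2"),
                           c("P1", "P1", "P2", "P2"))
  fm <- build_pair_features(pairs, blocks$drug, blocks$protein, "FS3")
  perm <- c(3L, 1L, 4L, 2L)
  pairs2 <- interaction_set(pairs$drug_id[perm], pairs$protein_id[perm])
  fm2 <- build_pair_features(pairs2, blocks$drug, blocks$protein, "FS3")
  expect_equal(fm2$matrix, fm$matrix[perm, ], ignore_attr = TRUE)
})

test_that("missing blocks are reported by id", {
  blocks <- make_fake_blocks("D1", "P1")
  pairs <- interaction_set(c("D1", "D2"), c("P1", "P1"))
  expect_error(build_pair_features(pairs, blocks$drug, blocks$protein, "FS1"),
               "'D2'")
  pairs <- interaction_set(c("D1", "D1"), c("P1", "P9"))
  expect_error(build_pair_features(pairs, blocks$drug, blocks$protein, "FS1"),
               "'P9'")
  expect_error(build_pair_features(pairs, blocks$drug, blocks$protein, "FS9"),
               "unknown feature_set_id")
})

test_that("drug and protein block helpers attach rownames", {
  drugs <- data.frame(drug_id = c("DA", "DB"), smiles = c("CCO", "CCN"))
  db <- drug_feature_blocks(drugs)
  expect_equal(rownames(db$MORGAN), c("DA", "DB"))
  expect_equal(dim(db$CONSTITUTIONAL), c(2L, 30L))
  prots <- data.frame(protein_id = "PX", sequence = "MKVLAC")
  pb <- protein_feature_blocks(prots)
  expect_equal(dim(pb$AAC), c(1L, 20L))
  expect_equal(dim(pb$DC), c(1L, 400L))
  expect_equal(rownames(pb$DC), "PX")
})
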