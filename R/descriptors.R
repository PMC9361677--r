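# Descriptor families and the five pair-feature recipes:
#   FS1 = Morgan (1024) ++ AAC (20)            -> 1044
#   FS2 = Morgan (1024) ++ DC (400)            -> 1424
#   FS3 = constitutional (30) ++ AAC (20)      -> 50
#   FS4 = constitutional (30) ++ DC (400)      -> 430
#   ALL = Morgan ++ constitutional ++ AAC ++ DC -> 1474

#' Amino-acid composition (AAC)
#'
#' Fraction of each of the 20 canonical residues, in fixed alphabetical
#' single-letter order (A, C, D, ..., Y). Entries sum to 1.
#'
#' @param sequence Amino-acid string; length >= 1.
#' @param policy Residue policy, see [read_fasta()].
#' @return Named numeric vector of length 20.
#' @export
compute_aac <- function(sequence, policy = c("reject", "drop")) {
  policy <- match.arg(policy)
  sequence <- apply_residue_policy(toupper(sequence), policy)
  if (nchar(sequence) < 1L) stop("sequence empty after residue policy")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  v <- as.numeric(counts) / length(chars)
  names(v) <- paste0("aac_", AA_ALPHABET)
  v
}

#' Dipeptide composition (DC)
#'
#' Fraction of each of the 400 ordered adjacent residue pairs among the
#' sequence's length-1 windows, indexed lexicographically (AA, AC, ..., YY).
#' Entries sum to 1.
#'
#' @inheritParams compute_aac
#' @return Named numeric vector of length 400.
#' @export
compute_dipeptide <- function(sequence, policy = c("reject", "drop")) {
  policy <- match.arg(policy)
  sequence <- apply_residue_policy(toupper(sequence), policy)
  n <- nchar(sequence)
  if (n < 2L) stop("dipeptide composition needs sequence length >= 2")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  windows <- paste0(chars[-n], chars[-1L])
  counts <- table(factor(windows, levels = DIPEPTIDES))
  v <- as.numeric(counts) / (n - 1L)
  names(v) <- paste0("dc_", DIPEPTIDES)
  v
}

# ---- rdkit subprocess bridge -------------------------------------------------

descriptor_tool_path <- function() {
  p <- system.file("python", "descriptors.py", package = "dtibalance")
  if (p == "") stop("descriptors.py helper not found in installed package")
  p
}

python_binary <- function() {
  p <- Sys.which("python")
  if (p == "") p <- Sys.which("python3")
  if (p == "") stop("no python interpreter on PATH (needed for SMILES ",
                    "descriptors); use precomputed-features mode instead")
  p
}

run_descriptor_tool <- function(smiles, mode, n_bits = 1024L, radius = 2L) {
  ids <- sprintf("m%06d", seq_along(smiles))
  inp <- tempfile(fileext = ".tsv"); outp <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(inp, outp)), add = TRUE)
  data.table::fwrite(data.table::data.table(id = ids, smiles = smiles),
                     inp, sep = "\t")
  err <- tempfile(); on.exit(unlink(err), add = TRUE)
  status <- system2(python_binary(),
                    c(shQuote(descriptor_tool_path()), mode, shQuote(inp),
                      shQuote(outp), n_bits, radius),
                    stdout = FALSE, stderr = err)
  if (status != 0L) {
    msg <- readLines(err, warn = FALSE)
    pe <- grep("^PARSE_ERROR\t", msg, value = TRUE)
    if (length(pe) > 0L) {
      bad <- strsplit(pe[[1L]], "\t", fixed = TRUE)[[1L]]
      cond <- structure(
        class = c("smiles_parse_error", "error", "condition"),
        list(message = paste0("unparseable SMILES: '", bad[[3L]], "'"),
             call = sys.call(-1), smiles = bad[[3L]]))
      stop(cond)
    }
    stop("descriptor helper failed (exit ", status, "): ",
         paste(msg, collapse = "; "))
  }
  out <- data.table::fread(outp, sep = "\t", header = TRUE,
                           colClasses = list(character = "id"))
  stopifnot(identical(out$id, ids))
  out
}

#' Morgan (ECFP-style circular) fingerprints
#'
#' Folded binary circular fingerprints of radius 2 (ECFP4) hashed to
#' `n_bits` bits, computed with the RDKit toolkit through a batched
#' subprocess. Deterministic for a molecule regardless of SMILES spelling.
#'
#' @param smiles Character vector of SMILES strings.
#' @param n_bits Fingerprint length (default 1024).
#' @param radius Circular radius (default 2; ECFP4).
#' @return Integer 0/1 matrix, `length(smiles)` x `n_bits`, columns
#'   `morgan_0001` ...
#' @export
compute_morgan <- function(smiles, n_bits = 1024L, radius = 2L) {
  if (length(smiles) == 0L) stop("no SMILES given")
  out <- run_descriptor_tool(smiles, "morgan", n_bits, radius)
  bits <- do.call(rbind, lapply(strsplit(out$bits, "", fixed = TRUE),
                                as.integer))
  stopifnot(ncol(bits) == n_bits, all(bits %in% c(0L, 1L)))
  colnames(bits) <- sprintf("morgan_%04d", seq_len(n_bits))
  rownames(bits) <- NULL
  bits
}

#' Constitutional descriptors
#'
#' A fixed, documented block of 30 composition-only scalar descriptors
#' (weights, atom counts by element, ring counts, bond-type counts,
#' hydrogen-bond donor/acceptor counts); no topology or geometry. The exact
#' list is frozen in `CONSTITUTIONAL_NAMES` for column stability.
#'
#' @inheritParams compute_morgan
#' @return Numeric matrix, `length(smiles)` x 30.
#' @export
compute_constitutional <- function(smiles) {
  if (length(smiles) == 0L) stop("no SMILES given")
  out <- run_descriptor_tool(smiles, "constitutional")
  m <- as.matrix(out[, CONSTITUTIONAL_NAMES, with = FALSE])
  stopifnot(ncol(m) == 30L, all(is.finite(m)))
  rownames(m) <- NULL
  m
}

#' Canonical SMILES (toolkit oracle)
#' @inheritParams compute_morgan
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  run_descriptor_tool(smiles, "canonical")$canonical_smiles
}

#' Compute all drug feature blocks
#'
#' @param drugs data.frame with `drug_id`, `smiles`.
#' @return List with `MORGAN` (n x 1024) and `CONSTITUTIONAL` (n x 30)
#'   matrices, rownames = drug_id.
#' @export
drug_feature_blocks <- function(drugs) {
  morgan <- compute_morgan(drugs$smiles)
  constitutional <- compute_constitutional(drugs$smiles)
  rownames(morgan) <- rownames(constitutional) <- drugs$drug_id
  list(MORGAN = morgan, CONSTITUTIONAL = constitutional)
}

#' Compute all protein feature blocks
#'
#' @param proteins data.frame with `protein_id`, `sequence`.
#' @param policy Residue policy, see [read_fasta()].
#' @return List with `AAC` (n x 20) and `DC` (n x 400) matrices,
#'   rownames = protein_id.
#' @export
protein_feature_blocks <- function(proteins, policy = "reject") {
  aac <- t(vapply(proteins$sequence, compute_aac, numeric(20L),
                  policy = policy))
  dc <- t(vapply(proteins$sequence, compute_dipeptide, numeric(400L),
                 policy = policy))
  rownames(aac) <- rownames(dc) <- proteins$protein_id
  list(AAC = aac, DC = dc)
}

new_pair_feature_matrix <- function(feature_set_id, pair_keys, matrix,
                                    feature_names) {
  stopifnot(nrow(pair_keys) == nrow(matrix),
            length(feature_names) == ncol(matrix))
  colnames(matrix) <- feature_names
  structure(list(feature_set_id = feature_set_id,
                 pair_keys = pair_keys,
                 matrix = matrix,
                 feature_names = feature_names),
            class = "pair_feature_matrix")
}

#' @export
print.pair_feature_matrix <- function(x, ...) {
  cat("pair_feature_matrix [", x$feature_set_id, "]: ",
      nrow(x$matrix), " pairs x ", ncol(x$matrix), " features\n", sep = "")
  invisible(x)
}

#' @export
dim.pair_feature_matrix <- function(x) dim(x$matrix)

feature_set_recipe <- function(feature_set_id) {
  switch(feature_set_id,
         FS1 = list(drug = "MORGAN", protein = "AAC"),
         FS2 = list(drug = "MORGAN", protein = "DC"),
         FS3 = list(drug = "CONSTITUTIONAL", protein = "AAC"),
         FS4 = list(drug = "CONSTITUTIONAL", protein = "DC"),
         ALL = list(drug = c("MORGAN", "CONSTITUTIONAL"),
                    protein = c("AAC", "DC")),
         stop("unknown feature_set_id: ", feature_set_id))
}

#' Assemble a pair feature matrix
#'
#' Each row is the concatenation of the pair's drug block(s) followed by its
#' protein block(s), per the recipe. Widths: FS1 1044, FS2 1424, FS3 50,
#' FS4 430, ALL 1474.
#'
#' @param pairs An `interaction_set` (row order is preserved).
#' @param drug_blocks List from [drug_feature_blocks()] (or equivalent
#'   precomputed matrices with drug_id rownames).
#' @param protein_blocks List from [protein_feature_blocks()].
#' @param feature_set_id One of `"FS1"`, `"FS2"`, `"FS3"`, `"FS4"`, `"ALL"`.
#' @return A `pair_feature_matrix`.
#' @export
build_pair_features <- function(pairs, drug_blocks, protein_blocks,
                                feature_set_id = "ALL") {
  recipe <- feature_set_recipe(feature_set_id)
  fetch <- function(blocks, kinds, ids, what) {
    parts <- lapply(kinds, function(k) {
      b <- blocks[[k]]
      if (is.null(b)) stop("missing ", k, " block")
      miss <- setdiff(unique(ids), rownames(b))
      if (length(miss) > 0L) {
        stop("missing ", k, " block for ", what, " '", miss[1L], "'")
      }
      b[ids, , drop = FALSE]
    })
    do.call(cbind, parts)
  }
  dm <- fetch(drug_blocks, recipe$drug, pairs$drug_id, "drug_id")
  pm <- fetch(protein_blocks, recipe$protein, pairs$protein_id, "protein_id")
  m <- cbind(dm, pm)
  rownames(m) <- NULL
  new_pair_feature_matrix(
    feature_set_id,
    data.frame(drug_id = pairs$drug_id, protein_id = pairs$protein_id,
               stringsAsFactors = FALSE),
    m, colnames(m))
}
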