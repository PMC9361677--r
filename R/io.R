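# On-disk contracts: FASTA proteins, TSV/CSV drug tables (drug_id, smiles),
# TSV pair lists (drug_id, protein_id[, label]), delimited feature matrices
# with a header row and a leading pair-key column.

#' Read protein records from a FASTA file
#'
#' Sequences are uppercased. Residues outside the 20-letter amino-acid
#' alphabet are rejected by default; `policy = "drop"` silently removes them
#' (amino-acid and dipeptide composition are defined only over the 20
#' canonical residues).
#'
#' @param path Path to a FASTA file.
#' @param policy `"reject"` (default) errors on a non-standard residue
#'   (B, J, O, U, X, Z, ...); `"drop"` removes such residues.
#' @return A data.frame with columns `protein_id`, `sequence`.
#' @export
read_fasta <- function(path, policy = c("reject", "drop")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(lines[[1L]], ">")) {
    stop("FASTA parse error at line 1: expected '>' header, got: ", lines[[1L]])
  }
  is_header <- startsWith(lines, ">")
  ids <- sub("^>\\s*(\\S*).*$", "\\1", lines[is_header])
  if (any(ids == "")) {
    line_no <- which(is_header)[which(ids == "")[1L]]
    stop("FASTA parse error at line ", line_no, ": empty header")
  }
  grp <- cumsum(is_header)
  seqs <- vapply(split(lines[!is_header], grp[!is_header]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  # headers with no sequence lines
  all_grp <- as.character(seq_along(ids))
  missing <- setdiff(all_grp, names(seqs))
  if (length(missing) > 0L) {
    stop("FASTA record '", ids[as.integer(missing[1L])], "' has no sequence")
  }
  seqs <- unname(seqs[all_grp])
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in FASTA: ", ids[duplicated(ids)][1L])
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    apply_residue_policy(seqs[[i]], policy, ids[[i]])
  }, character(1))
  data.frame(protein_id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

apply_residue_policy <- function(sequence, policy, id = "<sequence>") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% AA_ALPHABET)
  if (!any(bad)) return(sequence)
  if (policy == "reject") {
    stop("non-standard residue '", chars[bad][1L], "' in sequence '", id,
         "' (position ", which(bad)[1L],
         "); use policy = \"drop\" to remove such residues")
  }
  paste(chars[!bad], collapse = "")
}

#' Read a drug table (drug_id, smiles)
#'
#' @param path Delimited text file with at least columns `drug_id`, `smiles`.
#'   Tab and comma separators are auto-detected.
#' @return A data.frame with columns `drug_id`, `smiles`, in file order.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop("drug table not found: ", path)
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  if (!all(c("drug_id", "smiles") %in% names(dt))) {
    stop("drug table schema error: required columns drug_id, smiles; found: ",
         paste(names(dt), collapse = ", "))
  }
  if (anyDuplicated(dt$drug_id)) {
    stop("duplicate drug_id: ", dt$drug_id[duplicated(dt$drug_id)][1L])
  }
  if (any(is.na(dt$smiles) | dt$smiles == "")) {
    stop("empty smiles for drug_id: ", dt$drug_id[which(dt$smiles == "")[1L]])
  }
  if (any(is.na(dt$drug_id) | dt$drug_id == "")) stop("empty drug_id")
  as.data.frame(dt[, c("drug_id", "smiles")])
}

#' Construct an interaction set
#'
#' An interaction set is a data.frame of (drug_id, protein_id, label) pairs
#' with label in POSITIVE / UNKNOWN / PREDICTED_NEGATIVE, no duplicate pairs.
#'
#' @param drug_id,protein_id Character vectors of equal length.
#' @param label Labels, recycled if scalar.
#' @return A data.frame of class `interaction_set`.
#' @export
interaction_set <- function(drug_id, protein_id,
                            label = "POSITIVE") {
  if (length(drug_id) != length(protein_id)) {
    stop("drug_id and protein_id lengths differ")
  }
  label <- rep_len(as.character(label), length(drug_id))
  if (!all(label %in% INTERACTION_LABELS)) {
    stop("invalid label; must be one of ",
         paste(INTERACTION_LABELS, collapse = ", "))
  }
  key <- paste(drug_id, protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (drug_id, protein_id) pair: ",
         sub("\r", " / ", key[duplicated(key)][1L]))
  }
  out <- data.frame(drug_id = as.character(drug_id),
                    protein_id = as.character(protein_id),
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Read a pair list (`drug_id`, `protein_id`, optional `label`) from TSV
#' @param path TSV file with a one-line header.
#' @param default_label Label used when the file has no label column.
#' @return An `interaction_set`.
#' @export
read_pairs <- function(path, default_label = "POSITIVE") {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  if (!all(c("drug_id", "protein_id") %in% names(dt))) {
    stop("pair list schema error: need drug_id, protein_id; found: ",
         paste(names(dt), collapse = ", "))
  }
  lab <- if ("label" %in% names(dt)) dt$label else default_label
  interaction_set(dt$drug_id, dt$protein_id, lab)
}

#' Write a pair list as TSV
#' @param pairs An `interaction_set`.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  data.table::fwrite(as.data.frame(pairs)[, c("drug_id", "protein_id", "label")],
                     path, sep = "\t")
  invisible(path)
}

#' Enumerate unknown drug-protein pairs
#'
#' The full `|drugs| x |proteins|` candidate grid minus the known positives,
#' labeled UNKNOWN. At the scale of a full interactome extract (tens of
#' millions of pairs) the grid must not be materialized at once; use
#' `unknown_pair_chunks()` for streaming. This eager version enforces a guard
#' on the grid size.
#'
#' @param drugs data.frame with `drug_id` (from [read_drug_table()]).
#' @param proteins data.frame with `protein_id` (from [read_fasta()]).
#' @param positives `interaction_set` of known positive pairs.
#' @param max_pairs Guard against accidental materialization of a huge grid.
#' @return An `interaction_set` of UNKNOWN pairs.
#' @export
enumerate_unknown_pairs <- function(drugs, proteins, positives,
                                    max_pairs = 5e6) {
  check_positives_resolve(drugs, proteins, positives)
  n_total <- as.numeric(nrow(drugs)) * nrow(proteins)
  if (n_total > max_pairs) {
    stop("pair grid has ", format(n_total, big.mark = ","),
         " cells; use unknown_pair_chunks() to stream, or raise max_pairs")
  }
  grid <- expand.grid(protein_id = proteins$protein_id,
                      drug_id = drugs$drug_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$drug_id, grid$protein_id, sep = "\r")
  pos_key <- paste(positives$drug_id, positives$protein_id, sep = "\r")
  keep <- !(key %in% pos_key)
  interaction_set(grid$drug_id[keep], grid$protein_id[keep], "UNKNOWN")
}

check_positives_resolve <- function(drugs, proteins, positives) {
  bad_d <- setdiff(positives$drug_id, drugs$drug_id)
  if (length(bad_d) > 0L) {
    stop("positive pair references unloaded drug_id: ", bad_d[1L])
  }
  bad_p <- setdiff(positives$protein_id, proteins$protein_id)
  if (length(bad_p) > 0L) {
    stop("positive pair references unloaded protein_id: ", bad_p[1L])
  }
  invisible(TRUE)
}

#' Stream the unknown-pair grid in chunks
#'
#' Returns an iterator function; each call yields the next chunk of the
#' drug-major pair grid (positives removed, labeled UNKNOWN) as an
#' `interaction_set`, or `NULL` when exhausted. Chunking cannot change any
#' downstream result because candidate scoring is deterministic per pair.
#'
#' @inheritParams enumerate_unknown_pairs
#' @param chunk_size Number of grid cells per chunk before positive removal.
#' @return A function: call repeatedly to obtain chunks, `NULL` at end.
#' @export
unknown_pair_chunks <- function(drugs, proteins, positives,
                                chunk_size = 100000L) {
  check_positives_resolve(drugs, proteins, positives)
  stopifnot(chunk_size >= 1L)
  pos_key <- paste(positives$drug_id, positives$protein_id, sep = "\r")
  n_d <- nrow(drugs); n_p <- nrow(proteins)
  n_total <- as.numeric(n_d) * n_p
  offset <- 0
  function() {
    if (offset >= n_total) return(NULL)
    idx <- offset + seq_len(min(chunk_size, n_total - offset))
    offset <<- offset + length(idx)
    di <- ((idx - 1) %/% n_p) + 1
    pi <- ((idx - 1) %% n_p) + 1
    d <- drugs$drug_id[di]; p <- proteins$protein_id[pi]
    keep <- !(paste(d, p, sep = "\r") %in% pos_key)
    if (!any(keep)) return(interaction_set(character(0), character(0),
                                           character(0)))
    interaction_set(d[keep], p[keep], "UNKNOWN")
  }
}

#' Write / read a pair feature matrix
#'
#' Persisted as delimited text: header row of feature names, leading
#' `drug_id` and `protein_id` key columns. Round-trips exactly (values are
#' written in full precision).
#'
#' @param fm A `pair_feature_matrix` (see [build_pair_features()]).
#' @param path Output TSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "pair_feature_matrix"))
  out <- data.table::data.table(drug_id = fm$pair_keys$drug_id,
                                protein_id = fm$pair_keys$protein_id)
  # %.17g guarantees bit-exact double round-trip through text
  m <- data.table::as.data.table(
    matrix(sprintf("%.17g", fm$matrix), nrow = nrow(fm$matrix)))
  data.table::setnames(m, fm$feature_names)
  data.table::fwrite(cbind(out, m), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param feature_set_id Feature set tag to attach on read.
#' @export
read_feature_matrix <- function(path, feature_set_id = "PRECOMPUTED") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("drug_id", "protein_id") %in% names(dt))) {
    stop("feature matrix file must have drug_id, protein_id key columns")
  }
  keys <- data.frame(drug_id = as.character(dt$drug_id),
                     protein_id = as.character(dt$protein_id),
                     stringsAsFactors = FALSE)
  feat_cols <- setdiff(names(dt), c("drug_id", "protein_id"))
  m <- as.matrix(dt[, feat_cols, with = FALSE])
  new_pair_feature_matrix(feature_set_id, keys, m, colnames(m))
}
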