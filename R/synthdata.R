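# Desk-scale synthetic DTI data with the statistical structure the pipeline
# assumes: a drugs x proteins pair grid where true positives are the top
# quantile of a latent bilinear affinity, observed positives are a subset of
# them (the rest stay latent among the unknowns), and a planted fraction of
# unknowns are true negatives displaced from the positive feature manifold.
# Hidden truth is returned separately and is never consumed by any pipeline
# stage.

BLOCK_WIDTHS <- c(MORGAN = 1024L, CONSTITUTIONAL = 30L, AAC = 20L, DC = 400L)

#' Synthetic-data configuration
#'
#' @param n_drugs,n_proteins Grid dimensions (default 50 x 50: 2,500 pairs,
#'   end-to-end in seconds).
#' @param positive_rate Fraction of the grid that is truly interacting
#'   (0 < rate < 0.5); default 0.05, a small minority as in a real
#'   interactome extract.
#' @param latent_dim Latent embedding dimension for drugs and proteins.
#' @param negative_cluster_shift Displacement of planted true negatives from
#'   the positive manifold, in units of the latent feature noise scale;
#'   0 means no planted separation.
#' @param noise_sd Gaussian noise added to every pair feature before the
#'   block nonlinearity.
#' @param seed Integer seed; identical seeds give identical output.
#' @param mode `"FEATURE_VECTORS"` (features drawn from the latent model;
#'   default) or `"SMILES_FASTA"` (features left to the real descriptor
#'   pipeline; no planted feature signal).
#' @param observed_positive_frac Fraction of true positives revealed as
#'   POSITIVE labels; the rest remain latent positives among the unknowns.
#' @param negative_rate Fraction of non-positive pairs planted as true
#'   negatives (the lowest-affinity pairs).
#' @param signal_strength Magnitude of the positive-manifold displacement
#'   shared by (latent and observed) true positives.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 50L, n_proteins = 50L,
                         positive_rate = 0.05, latent_dim = 8L,
                         negative_cluster_shift = 3, noise_sd = 0.5,
                         seed = 1L,
                         mode = c("FEATURE_VECTORS", "SMILES_FASTA"),
                         observed_positive_frac = 0.8,
                         negative_rate = 0.1, signal_strength = 1) {
  mode <- match.arg(mode)
  if (positive_rate <= 0 || positive_rate >= 0.5) {
    stop("positive_rate must be in (0, 0.5)")
  }
  if (negative_cluster_shift < 0) stop("negative_cluster_shift must be >= 0")
  structure(list(n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 positive_rate = positive_rate,
                 latent_dim = as.integer(latent_dim),
                 negative_cluster_shift = negative_cluster_shift,
                 noise_sd = noise_sd, seed = as.integer(seed), mode = mode,
                 observed_positive_frac = observed_positive_frac,
                 negative_rate = negative_rate,
                 signal_strength = signal_strength),
            class = "synth_config")
}

packaged_smiles <- function() {
  p <- system.file("extdata", "smiles_library.txt", package = "dtibalance")
  if (p == "") stop("packaged SMILES library not found")
  x <- readLines(p, warn = FALSE)
  x[!grepl("^#", x) & nzchar(x)]
}

# Sparse motif-like direction: signal lives on a subset of descriptor
# coordinates (shared substructure bits / dipeptides), unit magnitude each.
# A dense direction would push clusters beyond the RBF kernel's resolving
# range and collapse the signed-distance ranking into ties at the far-field
# floor; a sparse one keeps distances graded.
block_signal_direction <- function(width) {
  support <- max(8L, ceiling(0.1 * width))
  support <- min(support, width)
  dir <- numeric(width)
  dir[sample.int(width, support)] <- sample(c(-1, 1), support, replace = TRUE)
  dir
}

random_protein_sequence <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, sample(50:300, 1L), replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Generate a synthetic DTI dataset
#'
#' Latent model: drug vectors `u_i` and protein vectors `v_j` are standard
#' normal in `latent_dim`; the top `positive_rate` quantile of the bilinear
#' affinity `u_i . v_j` are true positives (a fraction of which is observed
#' as POSITIVE); the `negative_rate` lowest-affinity non-positive pairs are
#' planted true negatives. Pair features embed entity-level latent structure
#' into four blocks mimicking the descriptor shapes (1024 thresholded
#' binary, 30 real, 20-simplex, 400-simplex via softmax); true positives
#' share a common manifold displacement of `signal_strength`, and planted
#' negatives are displaced a further `negative_cluster_shift` noise units
#' along an independent direction, all before the block nonlinearity.
#'
#' @param cfg A [synth_config()].
#' @return List of class `synth_data`: `drugs`, `proteins`, `interactions`
#'   (`interaction_set` with POSITIVE/UNKNOWN labels), `truth` (data.frame
#'   `pair_key`, `drug_id`, `protein_id`, `truth` in TRUE_POSITIVE /
#'   TRUE_NEGATIVE / OTHER — the hidden oracle, not a pipeline input),
#'   `features` (named list of `pair_feature_matrix` FS1..FS4 and ALL over
#'   the full grid; `NULL` in SMILES_FASTA mode), `cfg`.
#' @export
synth_generate <- function(cfg = synth_config()) {
  restore <- .Random.seed_guard(cfg$seed)
  on.exit(restore(), add = TRUE)

  n_pairs <- cfg$n_drugs * cfg$n_proteins
  n_pos <- round(cfg$positive_rate * n_pairs)
  if (n_pos < 1L) {
    stop("positive_rate ", cfg$positive_rate, " is infeasible for a grid of ",
         n_pairs, " pairs")
  }

  drug_ids <- sprintf("D%04d", seq_len(cfg$n_drugs))
  protein_ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  lib <- packaged_smiles()
  drugs <- data.frame(drug_id = drug_ids,
                      smiles = sample(lib, cfg$n_drugs, replace = TRUE),
                      stringsAsFactors = FALSE)
  proteins <- data.frame(protein_id = protein_ids,
                         sequence = random_protein_sequence(cfg$n_proteins),
                         stringsAsFactors = FALSE)

  U <- matrix(stats::rnorm(cfg$n_drugs * cfg$latent_dim), cfg$n_drugs)
  V <- matrix(stats::rnorm(cfg$n_proteins * cfg$latent_dim), cfg$n_proteins)
  affinity <- tcrossprod(U, V)            # drugs x proteins

  # drug-major flattening of the grid
  di <- rep(seq_len(cfg$n_drugs), each = cfg$n_proteins)
  pj <- rep(seq_len(cfg$n_proteins), times = cfg$n_drugs)
  s <- affinity[cbind(di, pj)]

  ord <- order(s, decreasing = TRUE)
  truth <- rep("OTHER", n_pairs)
  truth[ord[seq_len(n_pos)]] <- "TRUE_POSITIVE"
  non_pos <- ord[(n_pos + 1L):n_pairs]
  n_neg <- round(cfg$negative_rate * length(non_pos))
  if (n_neg > 0L) truth[rev(ord)[seq_len(n_neg)]] <- "TRUE_NEGATIVE"

  is_pos <- truth == "TRUE_POSITIVE"
  observed <- is_pos & stats::runif(n_pairs) < cfg$observed_positive_frac
  if (!any(observed)) observed[which(is_pos)[1L]] <- TRUE
  label <- ifelse(observed, "POSITIVE", "UNKNOWN")

  interactions <- interaction_set(drug_ids[di], protein_ids[pj], label)
  pair_key <- paste(drug_ids[di], protein_ids[pj], sep = "|")
  truth_df <- data.frame(pair_key = pair_key, drug_id = drug_ids[di],
                         protein_id = protein_ids[pj], truth = truth,
                         stringsAsFactors = FALSE)

  features <- NULL
  if (cfg$mode == "FEATURE_VECTORS") {
    # pre-nonlinearity feature sd: unit entity signal plus Gaussian noise;
    # shift and signal_strength are expressed in these units
    sigma_f <- sqrt(1 + cfg$noise_sd^2)
    pos_sig <- cfg$signal_strength * sigma_f * is_pos
    neg_sig <- cfg$negative_cluster_shift * sigma_f *
      (truth == "TRUE_NEGATIVE")
    blocks <- list()
    for (blk in names(BLOCK_WIDTHS)) {
      w <- BLOCK_WIDTHS[[blk]]
      proj <- matrix(stats::rnorm(cfg$latent_dim * w), cfg$latent_dim) /
        sqrt(cfg$latent_dim)
      base <- if (blk %in% c("MORGAN", "CONSTITUTIONAL")) U %*% proj
              else V %*% proj
      ent <- if (blk %in% c("MORGAN", "CONSTITUTIONAL")) di else pj
      a_dir <- block_signal_direction(w)
      b_dir <- block_signal_direction(w)
      logits <- base[ent, , drop = FALSE] +
        outer(pos_sig, a_dir) - outer(neg_sig, b_dir) +
        matrix(stats::rnorm(n_pairs * w, sd = cfg$noise_sd), n_pairs)
      blocks[[blk]] <- switch(blk,
        MORGAN = {
          # threshold at 2 latent sd: ~4% bit density, the sparsity regime
          # of real folded circular fingerprints
          m <- (logits > 2) + 0
          colnames(m) <- sprintf("morgan_%04d", seq_len(w)); m
        },
        CONSTITUTIONAL = {
          colnames(logits) <- CONSTITUTIONAL_NAMES; logits
        },
        AAC = {
          m <- exp(logits); m <- m / rowSums(m)
          colnames(m) <- paste0("aac_", AA_ALPHABET); m
        },
        DC = {
          m <- exp(logits); m <- m / rowSums(m)
          colnames(m) <- paste0("dc_", DIPEPTIDES); m
        })
    }
    keys <- data.frame(drug_id = drug_ids[di], protein_id = protein_ids[pj],
                       stringsAsFactors = FALSE)
    assemble <- function(id, parts) {
      m <- do.call(cbind, blocks[parts])
      new_pair_feature_matrix(id, keys, m, colnames(m))
    }
    features <- list(
      FS1 = assemble("FS1", c("MORGAN", "AAC")),
      FS2 = assemble("FS2", c("MORGAN", "DC")),
      FS3 = assemble("FS3", c("CONSTITUTIONAL", "AAC")),
      FS4 = assemble("FS4", c("CONSTITUTIONAL", "DC")),
      ALL = assemble("ALL", c("MORGAN", "CONSTITUTIONAL", "AAC", "DC")))
  }

  structure(list(drugs = drugs, proteins = proteins,
                 interactions = interactions, truth = truth_df,
                 features = features, cfg = cfg),
            class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat("synth_data: ", x$cfg$n_drugs, " drugs x ", x$cfg$n_proteins,
      " proteins; ", sum(x$interactions$label == "POSITIVE"),
      " observed positives, ", sum(x$truth$truth == "TRUE_NEGATIVE"),
      " planted negatives\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's file formats
#'
#' Emits `drugs.tsv`, `proteins.fasta`, `positives.tsv` and the hidden
#' oracle `truth.tsv` (plus `features_<set>.tsv` when present).
#'
#' @param data A `synth_data` object.
#' @param dir Output directory (created if absent).
#' @param write_features Also persist the feature matrices (large; default
#'   FALSE).
#' @return `dir`, invisibly.
#' @export
synth_write <- function(data, dir, write_features = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data$drugs, file.path(dir, "drugs.tsv"), sep = "\t")
  writeLines(paste0(">", data$proteins$protein_id, "\n",
                    data$proteins$sequence),
             file.path(dir, "proteins.fasta"))
  pos <- data$interactions[data$interactions$label == "POSITIVE", ]
  write_pairs(interaction_set(pos$drug_id, pos$protein_id, "POSITIVE"),
              file.path(dir, "positives.tsv"))
  data.table::fwrite(data$truth, file.path(dir, "truth.tsv"), sep = "\t")
  if (write_features && !is.null(data$features)) {
    for (nm in names(data$features)) {
      write_feature_matrix(data$features[[nm]],
                           file.path(dir, paste0("features_", nm, ".tsv")))
    }
  }
  invisible(dir)
}

#' Score a selection (or prediction) against the hidden truth
#'
#' Contingency of selected pairs versus the planted TRUE_NEGATIVE oracle
#' labels, over the pairs the selection considered; reuses the metric
#' formulas. An empty selection reports precision 0 with a warning.
#'
#' @param selection A [select_negatives()] result, or a character vector of
#'   selected pair keys (`"drug|protein"`).
#' @param truth The `truth` data.frame from [synth_generate()].
#' @param target Truth label counted as a hit (default `"TRUE_NEGATIVE"`).
#' @param universe Pair keys the selection drew from; defaults to the
#'   selection's scored candidates (or all truth rows for a bare key
#'   vector).
#' @return List: `precision`, `recall`, `counts` (tp/fp/fn/tn).
#' @export
truth_report <- function(selection, truth, target = "TRUE_NEGATIVE",
                         universe = NULL) {
  keys <- if (inherits(selection, "negative_selection")) selection$selected
          else as.character(selection)
  if (is.null(universe)) {
    universe <- if (inherits(selection, "negative_selection"))
      names(selection$all_scores) else truth$pair_key
  }
  missing <- setdiff(c(universe, keys), truth$pair_key)
  if (length(missing) > 0L) {
    stop("oracle is missing evaluated pair: ", missing[1L])
  }
  truth_u <- truth[match(universe, truth$pair_key), ]
  is_hit <- truth_u$truth == target
  sel <- truth_u$pair_key %in% keys
  tp <- sum(sel & is_hit); fp <- sum(sel & !is_hit)
  fn <- sum(!sel & is_hit); tn <- sum(!sel & !is_hit)
  if (length(keys) == 0L) {
    warning("empty selection; precision reported as 0")
    return(list(precision = 0, recall = 0,
                counts = c(tp = 0, fp = 0, fn = fn, tn = tn)))
  }
  list(precision = tp / (tp + fp),
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}
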