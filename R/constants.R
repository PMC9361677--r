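# Frozen column-identity constants shared across modules. These orderings
# are part of the on-disk contract and must never change between releases.

#' The 20 standard amino acids, alphabetical one-letter codes
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Interaction labels
#' @export
INTERACTION_LABELS <- c("POSITIVE", "UNKNOWN", "PREDICTED_NEGATIVE")

#' Feature-set recipes
#' @export
FEATURE_SETS <- c("FS1", "FS2", "FS3", "FS4", "ALL")

# lexicographic dipeptide index (AA, AC, ..., YY)
DIPEPTIDES <- sort(as.vector(outer(AA_ALPHABET, AA_ALPHABET, paste0)))

CONSTITUTIONAL_NAMES <- c(
  "mol_wt", "heavy_atom_mol_wt", "num_valence_electrons", "heavy_atom_count",
  "atom_count_total", "n_C", "n_N", "n_O", "n_S", "n_P", "n_F", "n_Cl",
  "n_Br", "n_I", "n_halogen", "n_heteroatoms", "n_H_total", "h_bond_donors",
  "h_bond_acceptors", "nhoh_count", "no_count", "ring_count",
  "aromatic_ring_count", "saturated_ring_count", "rotatable_bonds",
  "bond_count", "single_bonds", "double_bonds", "triple_bonds",
  "aromatic_bonds")
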