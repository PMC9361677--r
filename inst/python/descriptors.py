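"""Batched molecular descriptor helper.

Called by the R package as a subprocess:

    python descriptors.py <mode> <input.tsv> <output.tsv> [n_bits] [radius]

modes:
  morgan         -- folded binary Morgan (ECFP-style circular) fingerprint,
                    emitted as a 0/1 character string per molecule
  constitutional -- the package's fixed 30-descriptor constitutional block
  canonical      -- RDKit canonical SMILES (used as an independent oracle)

Input: TSV with header columns id, smiles. Output: TSV written to <output.tsv>.
An unparseable SMILES aborts with exit code 3 and a single line on stderr:
    PARSE_ERROR<TAB><id><TAB><smiles>
"""
import sys
import csv

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, Lipinski, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

# Fixed constitutional block: composition-only counts and weights, no
# topological/geometrical descriptors. Order is frozen; R mirrors it.
CONSTITUTIONAL = [
    ("mol_wt", Descriptors.MolWt),
    ("heavy_atom_mol_wt", Descriptors.HeavyAtomMolWt),
    ("num_valence_electrons", Descriptors.NumValenceElectrons),
    ("heavy_atom_count", lambda m: m.GetNumHeavyAtoms()),
    ("atom_count_total", lambda m: Chem.AddHs(m).GetNumAtoms()),
    ("n_C", lambda m: _elem(m, "C")),
    ("n_N", lambda m: _elem(m, "N")),
    ("n_O", lambda m: _elem(m, "O")),
    ("n_S", lambda m: _elem(m, "S")),
    ("n_P", lambda m: _elem(m, "P")),
    ("n_F", lambda m: _elem(m, "F")),
    ("n_Cl", lambda m: _elem(m, "Cl")),
    ("n_Br", lambda m: _elem(m, "Br")),
    ("n_I", lambda m: _elem(m, "I")),
    ("n_halogen", lambda m: sum(_elem(m, e) for e in ("F", "Cl", "Br", "I"))),
    ("n_heteroatoms", rdMolDescriptors.CalcNumHeteroatoms),
    ("n_H_total", lambda m: _elem(Chem.AddHs(m), "H")),
    ("h_bond_donors", Lipinski.NumHDonors),
    ("h_bond_acceptors", Lipinski.NumHAcceptors),
    ("nhoh_count", Lipinski.NHOHCount),
    ("no_count", Lipinski.NOCount),
    ("ring_count", rdMolDescriptors.CalcNumRings),
    ("aromatic_ring_count", rdMolDescriptors.CalcNumAromaticRings),
    ("saturated_ring_count", rdMolDescriptors.CalcNumSaturatedRings),
    ("rotatable_bonds", rdMolDescriptors.CalcNumRotatableBonds),
    ("bond_count", lambda m: m.GetNumBonds()),
    ("single_bonds", lambda m: _bonds(m, Chem.BondType.SINGLE)),
    ("double_bonds", lambda m: _bonds(m, Chem.BondType.DOUBLE)),
    ("triple_bonds", lambda m: _bonds(m, Chem.BondType.TRIPLE)),
    ("aromatic_bonds", lambda m: _bonds(m, Chem.BondType.AROMATIC)),
]


def _elem(mol, symbol):
    return sum(1 for a in mol.GetAtoms() if a.GetSymbol() == symbol)


def _bonds(mol, btype):
    return sum(1 for b in mol.GetBonds() if b.GetBondType() == btype)


def main():
    mode, inp, outp = sys.argv[1], sys.argv[2], sys.argv[3]
    n_bits = int(sys.argv[4]) if len(sys.argv) > 4 else 1024
    radius = int(sys.argv[5]) if len(sys.argv) > 5 else 2

    with open(inp, newline="") as fh:
        rows = list(csv.DictReader(fh, delimiter="\t"))

    out_rows = []
    for row in rows:
        mol = Chem.MolFromSmiles(row["smiles"])
        if mol is None:
            sys.stderr.write(
                "PARSE_ERROR\t%s\t%s\n" % (row["id"], row["smiles"]))
            sys.exit(3)
        if mode == "morgan":
            fp = AllChem.GetMorganFingerprintAsBitVect(
                mol, radius=radius, nBits=n_bits)
            out_rows.append([row["id"], fp.ToBitString()])
        elif mode == "constitutional":
            out_rows.append(
                [row["id"]] + [repr(float(f(mol))) for _, f in CONSTITUTIONAL])
        elif mode == "canonical":
            out_rows.append([row["id"], Chem.MolToSmiles(mol)])
        else:
            sys.stderr.write("unknown mode %s\n" % mode)
            sys.exit(2)

    header = {
        "morgan": ["id", "bits"],
        "constitutional": ["id"] + [n for n, _ in CONSTITUTIONAL],
        "canonical": ["id", "canonical_smiles"],
    }[mode]
    with open(outp, "w", newline="") as fh:
        w = csv.writer(fh, delimiter="\t", lineterminator="\n")
        w.writerow(header)
        w.writerows(out_rows)


if __name__ == "__main__":
    main()
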