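#!/usr/bin/env python
"""Per-molecule atom descriptors and fingerprints for the ddigcl R package.

Reads a two-column TSV (id <TAB> smiles) and writes one JSON array to stdout.
For each record:
  ok        : whether the SMILES parsed to a molecule with >= 1 heavy atom
  atoms     : [symbol, degree, total_h, implicit_valence, aromatic] per heavy atom
  bonds     : 1-based atom index pairs, one entry per covalent bond
  maccs     : 1-based indices of set bits among RDKit MACCS bits 1..166
  morgan    : 1-based indices of set bits of a radius-2 Morgan fp hashed to 166 bits
  canonical : canonical SMILES

Kept dependency-free beyond RDKit; the R side expands one-hot encodings.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import MACCSkeys, rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def featurize(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None or mol.GetNumAtoms() == 0:
        return {"ok": False}
    atoms = [
        [
            a.GetSymbol(),
            a.GetDegree(),
            a.GetTotalNumHs(),
            a.GetImplicitValence(),
            1 if a.GetIsAromatic() else 0,
        ]
        for a in mol.GetAtoms()
    ]
    bonds = [
        [b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1] for b in mol.GetBonds()
    ]
    # MACCS: RDKit returns 167 bits with bit 0 unused; keep keys 1..166.
    maccs = [i for i in MACCSkeys.GenMACCSKeys(mol).GetOnBits() if 1 <= i <= 166]
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=166)
    morgan = [i + 1 for i in gen.GetFingerprint(mol).GetOnBits()]
    return {
        "ok": True,
        "atoms": atoms,
        "bonds": bonds,
        "maccs": maccs,
        "morgan": morgan,
        "canonical": Chem.MolToSmiles(mol),
    }


def main():
    path = sys.argv[1]
    out = []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smiles = line.split("\t", 1)
            rec = featurize(smiles)
            rec["id"] = ident
            out.append(rec)
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
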