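"""RDKit molecule backend for coamscreen.

Reads a JSON job file {"smiles": [...], "embed": bool, "seed": int},
writes a JSON list (one entry per input SMILES) with either
{"error": "..."} or the parsed structure and RDKit-native descriptors.

Only the structure-level quantities live here; graph-topological and
surface-area descriptors are computed on the R side from the returned
atoms/bonds/coordinates/charges.
"""
import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

# acidic / basic group patterns (standard SMARTS-based group counts)
ACID_SMARTS = (
    "[$([O;H1]-[C,S,P]=O),"
    "$([*;-;!$(*~[*;+])]),"
    "$([NH](S(=O)=O)C(F)(F)F),"
    "$(n1nnnc1)]"
)
BASE_SMARTS = (
    "[$([NH2]-[CX4]),"
    "$([NH](-[CX4])-[CX4]),"
    "$(N(-[CX4])(-[CX4])-[CX4]),"
    "$([*;+;!$(*~[*;-])]),"
    "$(N=C-N),"
    "$(N-C=N)]"
)
ACID_PAT = Chem.MolFromSmarts(ACID_SMARTS)
BASE_PAT = Chem.MolFromSmarts(BASE_SMARTS)


def one(smiles, embed, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"error": "unparseable SMILES"}

    props = {
        "MW": Descriptors.MolWt(mol),
        "SLogP": Descriptors.MolLogP(mol),
        "TopoPSA": Descriptors.TPSA(mol),
        "nHBAcc": Descriptors.NumHAcceptors(mol),
        "nHBDon": Descriptors.NumHDonors(mol),
        "nRot": Descriptors.NumRotatableBonds(mol),
        "nAcid": len(mol.GetSubstructMatches(ACID_PAT)),
        "nBase": len(mol.GetSubstructMatches(BASE_PAT)),
        "nAromAtom": sum(a.GetIsAromatic() for a in mol.GetAtoms()),
        "nAromBond": sum(b.GetIsAromatic() for b in mol.GetBonds()),
        "naRing": rdMolDescriptors.CalcNumAromaticRings(mol),
        "nRing": rdMolDescriptors.CalcNumRings(mol),
    }

    molH = Chem.AddHs(mol)
    if embed:
        params = AllChem.ETKDGv3()
        params.randomSeed = int(seed)
        params.useRandomCoords = False
        conf_id = AllChem.EmbedMolecule(molH, params)
        if conf_id < 0:
            # retry once with random-coordinate initialisation, same seed
            params.useRandomCoords = True
            conf_id = AllChem.EmbedMolecule(molH, params)
        if conf_id < 0:
            return {"error": "3D embedding failed"}
        try:
            AllChem.MMFFOptimizeMolecule(molH, maxIters=500)
        except Exception:
            pass
        conf = molH.GetConformer()
        coords = [list(conf.GetAtomPosition(i)) for i in
                  range(molH.GetNumAtoms())]
    else:
        coords = [[0.0, 0.0, 0.0]] * molH.GetNumAtoms()

    AllChem.ComputeGasteigerCharges(molH)
    charges = []
    for a in molH.GetAtoms():
        q = a.GetDoubleProp("_GasteigerCharge")
        charges.append(q if math.isfinite(q) else 0.0)

    atoms = [
        {"element": a.GetSymbol(),
         "x": round(coords[i][0], 6), "y": round(coords[i][1], 6),
         "z": round(coords[i][2], 6), "charge": round(charges[i], 6)}
        for i, a in enumerate(molH.GetAtoms())
    ]
    bonds = [
        {"a1": b.GetBeginAtomIdx() + 1, "a2": b.GetEndAtomIdx() + 1,
         "order": int(b.GetBondTypeAsDouble()) if not b.GetIsAromatic()
                  else 4,
         "aromatic": bool(b.GetIsAromatic())}
        for b in molH.GetBonds()
    ]
    return {
        "canonical": Chem.MolToSmiles(mol),
        "atoms": atoms,
        "bonds": bonds,
        "props": props,
    }


def main():
    with open(sys.argv[1]) as fh:
        job = json.load(fh)
    embed = bool(job.get("embed", False))
    seed = int(job.get("seed", 1))
    out = [one(s, embed, seed) for s in job["smiles"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
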