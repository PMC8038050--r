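"""Deterministic single-conformer 3D embedding for one SMILES.

Usage: python embed3d.py <smiles> <out.sdf> <seed>
Exit codes: 3 = unparsable SMILES, 4 = embedding failure.
Multi-fragment inputs keep the largest fragment (salt stripping).
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

smiles, out_path, seed = sys.argv[1], sys.argv[2], int(sys.argv[3])
mol = Chem.MolFromSmiles(smiles)
if mol is None:
    sys.exit(3)
frags = Chem.GetMolFrags(mol, asMols=True)
if len(frags) > 1:
    mol = max(frags, key=lambda m: m.GetNumAtoms())
mol = Chem.AddHs(mol)
params = AllChem.ETKDGv3()
params.randomSeed = seed
if AllChem.EmbedMolecule(mol, params) != 0:
    sys.exit(4)
Chem.MolToMolFile(mol, out_path)
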