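"""Distance-geometry conformer embedding helper.

Reads a molecule (.smi or .mol file), generates `k` 3D conformers with the
ETKDG v2 distance-geometry method at a fixed random seed, and writes them as
a multi-record SDF (Kekule bond orders, explicit hydrogens, original atom
order; hydrogens added from SMILES are appended after the heavy atoms).

Usage: python embed_conformers.py <in.smi|in.mol> <out.sdf> <k> <seed>

Exit codes: 2 = unparseable input, 3 = embedding failed after the
randomized-coordinates retry.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def main() -> int:
    in_path, out_path, k, seed = (
        sys.argv[1], sys.argv[2], int(sys.argv[3]), int(sys.argv[4]))
    if in_path.endswith(".smi"):
        with open(in_path) as fh:
            mol = Chem.MolFromSmiles(fh.read().strip())
    else:
        with open(in_path) as fh:
            mol = Chem.MolFromMolBlock(fh.read(), removeHs=False)
    if mol is None:
        return 2
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv2()
    params.randomSeed = seed
    cids = AllChem.EmbedMultipleConfs(mol, numConfs=k, params=params)
    if len(cids) == 0:
        # one retry with randomized initial coordinates
        params.useRandomCoords = True
        cids = AllChem.EmbedMultipleConfs(mol, numConfs=k, params=params)
    if len(cids) == 0:
        return 3
    writer = Chem.SDWriter(out_path)
    for cid in cids:
        writer.write(mol, confId=cid)
    writer.close()
    return 0


if __name__ == "__main__":
    sys.exit(main())
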