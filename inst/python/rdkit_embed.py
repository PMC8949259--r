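"""Molecule back end for the paedesign R package.

Reads a JSON job description on argv[1], writes JSON results to argv[2].
Provides seeded 3D embedding (ETKDGv3), MMFF94 minimization, Gasteiger
PEOE partial charges and Wildman-Crippen atomic logP contributions.

Job format:
  {"action": "embed",
   "seed": 20220309, "minimize": true, "max_iter": 10000, "grad_tol": 1e-4,
   "molecules": [{"name": "DAP", "smiles": "..."} |
                 {"name": "x", "molblock": "..."}]}
  {"action": "canonical", "smiles": ["...", ...]}
  {"action": "mollogp", "smiles": ["...", ...]}
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger
from rdkit.Chem import AllChem, Crippen

RDLogger.DisableLog("rdApp.*")


def _mol_from_record(rec):
    if "molblock" in rec:
        mol = Chem.MolFromMolBlock(rec["molblock"], removeHs=False)
        if mol is None:
            raise ValueError("molblock parse failure")
        mol = Chem.AddHs(mol, addCoords=True)
        return mol, True
    mol = Chem.MolFromSmiles(rec["smiles"])
    if mol is None:
        raise ValueError("SMILES parse failure: %s" % rec.get("smiles"))
    return Chem.AddHs(mol), False


def _embed(mol, seed):
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    if AllChem.EmbedMolecule(mol, params) != 0:
        raise ValueError("3D embedding failed")


def process(job):
    out = []
    seed = int(job.get("seed", 20220309))
    minimize = bool(job.get("minimize", False))
    max_iter = int(job.get("max_iter", 10000))
    grad_tol = float(job.get("grad_tol", 1e-4))
    for rec in job["molecules"]:
        res = {"name": rec.get("name"), "error": None}
        try:
            mol, has_coords = _mol_from_record(rec)
            if not has_coords:
                _embed(mol, seed)
            e_before = e_after = None
            converged = None
            if minimize:
                props = AllChem.MMFFGetMoleculeProperties(mol)
                ff = AllChem.MMFFGetMoleculeForceField(mol, props)
                e_before = ff.CalcEnergy()
                # rdkit returns 0 on convergence, 1 when maxIts was hit
                status = ff.Minimize(maxIts=max_iter, forceTol=grad_tol)
                e_after = ff.CalcEnergy()
                converged = status == 0
            AllChem.ComputeGasteigerCharges(mol)
            contribs = Crippen.rdMolDescriptors._CalcCrippenContribs(mol)
            conf = mol.GetConformer()
            atoms = {"element": [], "x": [], "y": [], "z": [],
                     "formal_charge": [], "gasteiger": [], "crippen_logp": [],
                     "aromatic": [], "n_h": []}
            for atom in mol.GetAtoms():
                pos = conf.GetAtomPosition(atom.GetIdx())
                atoms["element"].append(atom.GetSymbol())
                atoms["x"].append(pos.x)
                atoms["y"].append(pos.y)
                atoms["z"].append(pos.z)
                atoms["formal_charge"].append(atom.GetFormalCharge())
                atoms["gasteiger"].append(
                    atom.GetDoubleProp("_GasteigerCharge"))
                atoms["crippen_logp"].append(contribs[atom.GetIdx()][0])
                atoms["aromatic"].append(atom.GetIsAromatic())
                atoms["n_h"].append(atom.GetTotalNumHs(includeNeighbors=True))
            bonds = {"begin": [], "end": [], "order": []}
            for bond in mol.GetBonds():
                bonds["begin"].append(bond.GetBeginAtomIdx() + 1)
                bonds["end"].append(bond.GetEndAtomIdx() + 1)
                bonds["order"].append(1.5 if bond.GetIsAromatic()
                                      else bond.GetBondTypeAsDouble())
            res.update({
                "smiles_canonical": Chem.MolToSmiles(Chem.RemoveHs(mol)),
                "atoms": atoms, "bonds": bonds,
                "energy_before": e_before, "energy_after": e_after,
                "converged": converged,
            })
        except Exception as exc:  # reported back to R, not raised
            res["error"] = str(exc)
        out.append(res)
    return out


def main():
    with open(sys.argv[1]) as fh:
        job = json.load(fh)
    action = job.get("action", "embed")
    if action == "embed":
        result = process(job)
    elif action == "canonical":
        result = []
        for smi in job["smiles"]:
            mol = Chem.MolFromSmiles(smi)
            result.append(None if mol is None else Chem.MolToSmiles(mol))
    elif action == "mollogp":
        result = []
        for smi in job["smiles"]:
            mol = Chem.AddHs(Chem.MolFromSmiles(smi))
            result.append(Crippen.MolLogP(mol))
    else:
        raise SystemExit("unknown action: %s" % action)
    with open(sys.argv[2], "w") as fh:
        json.dump(result, fh)


if __name__ == "__main__":
    main()
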