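"""RDKit backend for the usrml R package.

Thin command-line shim: each subcommand reads SMILES from a text file
(one per line, optionally "SMILES<TAB-or-space>id") and writes a JSON
document to stdout. All chemistry (SMILES parsing, standardization, ETKDG
conformer embedding, MMFF94 single-point energies and charges, Crippen
atomic logP contributions) is delegated to RDKit.
"""

import argparse
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdMolDescriptors
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")


def read_records(path):
    records = []
    with open(path) as fh:
        for i, line in enumerate(fh):
            tokens = line.split()
            if not tokens:
                continue
            mol_id = tokens[1] if len(tokens) > 1 else "mol%04d" % i
            records.append((mol_id, tokens[0]))
    return records


def cmd_validate(args):
    out = []
    for mol_id, smi in read_records(args.infile):
        mol = Chem.MolFromSmiles(smi)
        out.append({
            "mol_id": mol_id,
            "smiles": smi,
            "ok": mol is not None,
            "canonical": Chem.MolToSmiles(mol) if mol is not None else None,
        })
    return out


def cmd_standardize(args):
    chooser = rdMolStandardize.LargestFragmentChooser()
    out = []
    for mol_id, smi in read_records(args.infile):
        try:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                raise ValueError("unparseable SMILES")
            mol = rdMolStandardize.Cleanup(mol)
            mol = chooser.choose(mol)
            mol = rdMolStandardize.Uncharger().uncharge(mol)
            out.append({"mol_id": mol_id, "ok": True,
                        "standardized": Chem.MolToSmiles(mol)})
        except Exception as exc:  # noqa: BLE001 - report, don't crash the batch
            out.append({"mol_id": mol_id, "ok": False, "error": str(exc)})
    return out


def embed_conformers(mol, max_confs, seed):
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    params.numThreads = 1
    ids = AllChem.EmbedMultipleConfs(mol, numConfs=max_confs, params=params)
    return list(ids)


def cmd_conformers(args):
    out = []
    for idx, (mol_id, smi) in enumerate(read_records(args.infile)):
        entry = {"mol_id": mol_id, "smiles": smi, "conformers": []}
        try:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                raise ValueError("unparseable SMILES")
            mol = Chem.AddHs(mol)
            conf_ids = embed_conformers(mol, args.max_confs, args.seed + idx)
            if not conf_ids and mol.GetNumAtoms() > 0:
                conf_ids = embed_conformers(mol, args.max_confs, args.seed + idx + 7919)
            props = AllChem.MMFFGetMoleculeProperties(mol)
            if args.charge_model == "gasteiger" or props is None:
                AllChem.ComputeGasteigerCharges(mol)
                charges = [float(a.GetDoubleProp("_GasteigerCharge"))
                           for a in mol.GetAtoms()]
            else:
                charges = [props.GetMMFFPartialCharge(i)
                           for i in range(mol.GetNumAtoms())]
            logp = [c[0] for c in rdMolDescriptors._CalcCrippenContribs(mol)]
            entry["charges"] = charges
            entry["logp_contribs"] = logp
            entry["elements"] = [a.GetSymbol() for a in mol.GetAtoms()]
            for k, cid in enumerate(conf_ids):
                if props is not None:
                    ff = AllChem.MMFFGetMoleculeForceField(mol, props, confId=cid)
                    energy = ff.CalcEnergy() if ff is not None else 0.0
                else:
                    energy = 0.0
                conf = mol.GetConformer(cid)
                entry["conformers"].append({
                    "conf_id": k,
                    "energy": energy,
                    "coords": [list(conf.GetAtomPosition(i))
                               for i in range(mol.GetNumAtoms())],
                })
        except Exception as exc:  # noqa: BLE001
            entry["error"] = str(exc)
        out.append(entry)
    return out


def main():
    parser = argparse.ArgumentParser(description=__doc__)
    sub = parser.add_subparsers(dest="command", required=True)
    for name in ("validate", "standardize", "conformers"):
        p = sub.add_parser(name)
        p.add_argument("--in", dest="infile", required=True)
        if name == "conformers":
            p.add_argument("--max-confs", type=int, default=200)
            p.add_argument("--seed", type=int, default=42)
            p.add_argument("--charge-model", default="mmff94",
                           choices=("mmff94", "gasteiger"))
    args = parser.parse_args()
    result = {"validate": cmd_validate,
              "standardize": cmd_standardize,
              "conformers": cmd_conformers}[args.command](args)
    json.dump(result, sys.stdout)


if __name__ == "__main__":
    main()
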