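"""RDKit bridge for usrcatkit.

Invoked as a subprocess by the R package; speaks JSON on stdin/stdout.

Subcommands:
  validate_smarts            stdin: {"patterns": {subset: [smarts, ...]}}
  match SDF_PATH             stdin: {"patterns": {...}} -> per-record atom
                             indices (0-based, heavy atoms only)
  embed SMI_PATH OUT_SDF SEED  embed 3D coordinates for SMILES input
  fingerprint SDF_PATH KIND NBITS -> per-record on-bit indices
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, MACCSkeys

RDLogger.DisableLog("rdApp.*")


def _read_json():
    return json.load(sys.stdin)


def _write_json(obj):
    json.dump(obj, sys.stdout)
    sys.stdout.write("\n")


def validate_smarts():
    req = _read_json()
    errors = []
    for subset, patterns in req["patterns"].items():
        for i, smarts in enumerate(patterns):
            if Chem.MolFromSmarts(smarts) is None:
                errors.append({"subset": subset, "index": i + 1,
                               "pattern": smarts})
    _write_json({"ok": not errors, "errors": errors})


def _supplier(path):
    # removeHs=False keeps SDF atom-block order intact so indices returned
    # to R line up with the record as written.
    return Chem.SDMolSupplier(path, removeHs=False, sanitize=True)


def match(sdf_path):
    req = _read_json()
    patterns = {s: [Chem.MolFromSmarts(p) for p in pats]
                for s, pats in req["patterns"].items()}
    for subset, pats in patterns.items():
        if any(p is None for p in pats):
            _write_json({"error": "invalid SMARTS in subset " + subset})
            return
    out = []
    for i, mol in enumerate(_supplier(sdf_path)):
        if mol is None:
            _write_json({"error": "unparsable record", "record": i + 1})
            return
        rec = {"record": i + 1, "n_atoms": mol.GetNumAtoms(), "matches": {}}
        for subset, pats in patterns.items():
            idx = set()
            for pat in pats:
                for hit in mol.GetSubstructMatches(pat, uniquify=True):
                    idx.update(hit)
            # pharmacophore subsets are heavy-atom sets by definition
            idx = sorted(a for a in idx
                         if mol.GetAtomWithIdx(a).GetAtomicNum() != 1)
            rec["matches"][subset] = idx
        out.append(rec)
    _write_json({"records": out})


def embed(smi_path, out_sdf, seed):
    writer = Chem.SDWriter(out_sdf)
    n = 0
    with open(smi_path) as fh:
        for lineno, line in enumerate(fh, 1):
            line = line.strip()
            if not line:
                continue
            parts = line.split(None, 1)
            smiles = parts[0]
            name = parts[1].strip() if len(parts) > 1 else "mol%d" % lineno
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                _write_json({"error": "unparsable SMILES", "record": lineno})
                writer.close()
                return
            mol = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = int(seed)
            if AllChem.EmbedMolecule(mol, params) != 0:
                _write_json({"error": "embedding failed", "record": lineno})
                writer.close()
                return
            AllChem.MMFFOptimizeMolecule(mol)
            mol.SetProp("_Name", name)
            writer.write(mol)
            n += 1
    writer.close()
    _write_json({"n": n})


def fingerprint(sdf_path, kind, nbits):
    nbits = int(nbits)
    out = []
    for i, mol in enumerate(_supplier(sdf_path)):
        if mol is None:
            _write_json({"error": "unparsable record", "record": i + 1})
            return
        mol = Chem.RemoveHs(mol)
        if kind == "circular":
            from rdkit.Chem import rdFingerprintGenerator
            gen = rdFingerprintGenerator.GetMorganGenerator(
                radius=2, fpSize=nbits)
            fp = gen.GetFingerprint(mol)
        elif kind == "path":
            fp = Chem.RDKFingerprint(mol, fpSize=nbits, branchedPaths=False)
        elif kind == "tree":
            fp = Chem.RDKFingerprint(mol, fpSize=nbits, branchedPaths=True)
        elif kind == "maccs":
            fp = MACCSkeys.GenMACCSKeys(mol)
        else:
            _write_json({"error": "unsupported fingerprint kind: " + kind})
            return
        out.append({"record": i + 1, "bits": list(fp.GetOnBits())})
    _write_json({"records": out})


def main(argv):
    cmd = argv[1]
    if cmd == "validate_smarts":
        validate_smarts()
    elif cmd == "match":
        match(argv[2])
    elif cmd == "embed":
        embed(argv[2], argv[3], argv[4])
    elif cmd == "fingerprint":
        fingerprint(argv[2], argv[3], argv[4])
    elif cmd == "ping":
        _write_json({"ok": True})
    else:
        _write_json({"error": "unknown command: " + cmd})


if __name__ == "__main__":
    main(sys.argv)
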