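"""Batch featurizer: SMILES -> ECFP6 / MACCS / 2D-descriptor blocks.

Reads a CSV with columns id,smiles; writes one JSON object with, per
compound: ECFP6 on-bit indices (0-based), MACCS on-bit indices, the
descriptor values in the order of the supplied descriptor list, and any
descriptors whose value was non-finite (reported, value replaced by 0).
Unparsable or empty SMILES are reported under "errors"; the exit code is
0 as long as the batch itself ran.
"""
import argparse
import csv
import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, MACCSkeys, rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--input", required=True, help="CSV with id,smiles columns")
    ap.add_argument("--output", required=True, help="JSON output path")
    ap.add_argument("--ecfp-bits", type=int, default=2048)
    ap.add_argument("--desc-file", required=True,
                    help="one descriptor name per line, order frozen")
    args = ap.parse_args()

    desc_names = [l.strip() for l in open(args.desc_file) if l.strip()]
    desc_fns = []
    for name in desc_names:
        try:
            desc_fns.append((name, getattr(Descriptors, name)))
        except AttributeError:
            sys.exit("unknown descriptor: %s" % name)

    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=3, fpSize=args.ecfp_bits)

    out = {"ecfp_bits": args.ecfp_bits, "descriptors": desc_names,
           "compounds": [], "errors": []}
    with open(args.input, newline="") as fh:
        for row in csv.DictReader(fh):
            cid, smi = row["id"], row["smiles"]
            mol = Chem.MolFromSmiles(smi) if smi.strip() else None
            if mol is None or mol.GetNumAtoms() == 0:
                out["errors"].append({"id": cid, "smiles": smi})
                continue
            ecfp = sorted(gen.GetFingerprint(mol).GetOnBits())
            maccs = sorted(MACCSkeys.GenMACCSKeys(mol).GetOnBits())
            vals, bad = [], []
            for name, fn in desc_fns:
                try:
                    v = float(fn(mol))
                except Exception:
                    v = float("nan")
                if not math.isfinite(v):
                    bad.append(name)
                    v = 0.0
                vals.append(v)
            rec = {"id": cid, "ecfp": ecfp, "maccs": maccs, "desc": vals}
            if bad:
                rec["nonfinite"] = bad
            out["compounds"].append(rec)

    with open(args.output, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
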