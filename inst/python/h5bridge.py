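"""HDF5 <-> JSON bridge for reaction-dataset records.

Layout (grouped dialect): one group per reaction index (Rind), member
datasets Rsmiles, Psmiles, R_E, R_H, R_F, P_E, P_H, P_F, TS_E, TS_H, TS_F
(Hartree scalars) and RG, PG, TSG (N x 3 float arrays, Angstrom). A flat
dialect (those keys at the file root, single record) is auto-detected on
read.

Usage:
  python h5bridge.py read  <file.h5> <out.json> [Rind ...]
  python h5bridge.py write <in.json> <file.h5>
"""
import json
import sys

import h5py
import numpy as np

STR_KEYS = ("Rind", "Rsmiles", "Psmiles")
SCALAR_KEYS = ("R_E", "R_H", "R_F", "P_E", "P_H", "P_F",
               "TS_E", "TS_H", "TS_F")
GEOM_KEYS = ("RG", "PG", "TSG")


def _decode(x):
    if isinstance(x, bytes):
        return x.decode()
    return x


def _read_group(grp, rind):
    rec = {"Rind": rind}
    for k in STR_KEYS[1:]:
        if k in grp:
            rec[k] = _decode(grp[k][()])
    for k in SCALAR_KEYS:
        if k in grp:
            rec[k] = float(np.asarray(grp[k][()]).reshape(-1)[0])
    for k in GEOM_KEYS:
        if k in grp:
            rec[k] = [[float(v) for v in row]
                      for row in np.asarray(grp[k][()]).reshape(-1, 3)]
    return rec


def read(path, out_json, ids):
    records = []
    with h5py.File(path, "r") as f:
        groups = [k for k in f.keys() if isinstance(f[k], h5py.Group)]
        if groups:
            dialect = "grouped"
            names = ids if ids else sorted(groups)
            for name in names:
                if name not in f:
                    raise KeyError(f"no such record: {name}")
                records.append(_read_group(f[name], name))
        elif "Rsmiles" in f:
            dialect = "flat"
            rind = _decode(f["Rind"][()]) if "Rind" in f else "record_0"
            records.append(_read_group(f, rind))
        else:
            raise KeyError("HDF5 schema error: missing key Rsmiles "
                           "(neither grouped nor flat layout found)")
    with open(out_json, "w") as fh:
        json.dump({"dialect": dialect, "records": records}, fh)
    print(f"read {len(records)} record(s), {dialect} layout", file=sys.stderr)


def write(in_json, path):
    with open(in_json) as fh:
        payload = json.load(fh)
    with h5py.File(path, "w") as f:
        for rec in payload["records"]:
            grp = f.create_group(rec["Rind"])
            for k in STR_KEYS[1:]:
                if k in rec and rec[k] is not None:
                    grp[k] = np.bytes_(rec[k])
            for k in SCALAR_KEYS:
                if k in rec and rec[k] is not None:
                    grp[k] = np.float64(rec[k])
            for k in GEOM_KEYS:
                if k in rec and rec[k] is not None:
                    grp[k] = np.asarray(rec[k], dtype=np.float64).reshape(-1, 3)


def main(argv):
    if len(argv) < 3:
        sys.exit(__doc__)
    cmd = argv[0]
    if cmd == "read":
        read(argv[1], argv[2], argv[3:])
    elif cmd == "write":
        write(argv[1], argv[2])
    else:
        sys.exit(f"unknown command: {cmd}")


if __name__ == "__main__":
    main(sys.argv[1:])
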