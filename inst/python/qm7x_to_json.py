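"""Dump molecules from QM7-X-schema HDF5 files to JSON.

Each HDF5 file holds one group per molecule index; inside, one subgroup per
conformation (names ending in 'opt' are equilibrium structures) with datasets
'atNUM' (atomic numbers), 'atXYZ' (Cartesian coordinates, Angstrom), and one
scalar dataset per property. Usage:

    python qm7x_to_json.py FILE [FILE ...] > out.json
"""
import json
import sys

import h5py


def main(paths):
    records = []
    for path in paths:
        with h5py.File(path, "r") as fh:
            for mol_id in fh:
                grp = fh[mol_id]
                for conf_id in grp:
                    conf = grp[conf_id]
                    rec = {
                        "molecule": mol_id,
                        "conformation": conf_id,
                        "equilibrium": conf_id.endswith("opt"),
                        "atNUM": [int(z) for z in conf["atNUM"][()]],
                        "atXYZ": [[float(v) for v in row]
                                  for row in conf["atXYZ"][()]],
                        "properties": {},
                    }
                    for key in conf:
                        if key in ("atNUM", "atXYZ"):
                            continue
                        val = conf[key][()]
                        try:
                            rec["properties"][key] = float(val)
                        except (TypeError, ValueError):
                            pass  # non-scalar entries are not needed
                    records.append(rec)
    json.dump(records, sys.stdout)


if __name__ == "__main__":
    main(sys.argv[1:])
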