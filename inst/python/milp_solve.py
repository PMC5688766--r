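"""Batch mixed-integer linear program solver.

Reads a JSON file with a list of MILP problems, solves each with
scipy.optimize.milp (HiGHS) and writes a JSON list of results.

Problem fields (1-based sparse indices):
  n_vars, c, lb, ub, integrality (0 continuous / 1 integer),
  n_rows, ai, aj, ax (sparse constraint matrix), rlb, rub,
  optional time_limit (seconds).
Magnitudes >= 1e29 in bounds are treated as infinite.

Usage: python milp_solve.py IN.json OUT.json
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e29


def _inf(a, neg):
    a = np.atleast_1d(np.asarray(a, dtype=float))
    a[a <= -BIG] = -np.inf
    a[a >= BIG] = np.inf
    return a


def solve_one(p):
    n = int(p["n_vars"])
    c = np.atleast_1d(np.asarray(p["c"], dtype=float))
    lb = _inf(p["lb"], True)
    ub = _inf(p["ub"], False)
    integrality = np.atleast_1d(np.asarray(p["integrality"], dtype=int))
    constraints = []
    m = int(p["n_rows"])
    if m > 0:
        ai = np.atleast_1d(np.asarray(p["ai"], dtype=int)) - 1
        aj = np.atleast_1d(np.asarray(p["aj"], dtype=int)) - 1
        ax = np.atleast_1d(np.asarray(p["ax"], dtype=float))
        A = sparse.coo_matrix((ax, (ai, aj)), shape=(m, n)).tocsr()
        constraints = [LinearConstraint(A, _inf(p["rlb"], True),
                                        _inf(p["rub"], False))]
    options = {"mip_rel_gap": 0.0, "presolve": True}
    if p.get("time_limit") is not None:
        options["time_limit"] = float(p["time_limit"])
    res = milp(c=c, constraints=constraints, integrality=integrality,
               bounds=Bounds(lb, ub), options=options)
    out = {"success": bool(res.success), "status": int(res.status),
           "message": str(res.message)}
    if res.x is not None:
        x = np.asarray(res.x, dtype=float)
        x[integrality == 1] = np.round(x[integrality == 1])
        out["x"] = [float(v) for v in x]
        out["objective"] = float(c @ x)
    return out


def main(argv):
    with open(argv[1]) as fh:
        problems = json.load(fh)["problems"]
    results = [solve_one(p) for p in problems]
    with open(argv[2], "w") as fh:
        json.dump({"results": results}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
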