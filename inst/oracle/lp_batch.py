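"""Independent LP oracle for the test suite.

Reads a JSON list of LPs on stdin-free file I/O:
  [{"obj": [...], "A": [[...]], "rhs": [...], "lb": [...], "ub": [...],
    "maximize": bool}, ...]
Solves each with scipy.optimize.linprog (HiGHS) and writes
  [{"status": "optimal"|"infeasible"|"unbounded", "objective": float,
    "x": [...]}, ...]
Used only as an oracle against the package's own simplex implementation.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog

STATUS = {0: "optimal", 1: "iteration-limit", 2: "infeasible", 3: "unbounded"}


def solve(p):
    c = np.asarray(p["obj"], dtype=float)
    if p.get("maximize", False):
        c = -c
    A = np.asarray(p["A"], dtype=float)
    b = np.asarray(p["rhs"], dtype=float)
    lb = np.asarray(p["lb"], dtype=float)
    ub = np.asarray(p["ub"], dtype=float)
    res = linprog(c, A_eq=A, b_eq=b, bounds=list(zip(lb, ub)), method="highs")
    status = STATUS.get(res.status, "error")
    obj = float(np.dot(np.asarray(p["obj"], dtype=float), res.x)) \
        if res.status == 0 else None
    return {"status": status, "objective": obj,
            "x": list(map(float, res.x)) if res.status == 0 else None}


def main():
    inp, outp = sys.argv[1], sys.argv[2]
    with open(inp) as fh:
        problems = json.load(fh)
    out = [solve(p) for p in problems]
    with open(outp, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
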