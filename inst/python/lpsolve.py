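"""LP/MILP batch solver bridge (scipy/HiGHS backend).

Reads a JSON list of problems, solves each with scipy.optimize, writes a JSON
object of parallel arrays {status, objective, x}.  Bounds use +-1e30 as the
infinity sentinel.  Called by the R package; not a public interface.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog, milp, LinearConstraint, Bounds

BIG = 1e29


def _inf(v):
    v = np.asarray(v, dtype=float)
    v = np.where(v >= BIG, np.inf, v)
    v = np.where(v <= -BIG, -np.inf, v)
    return v


def solve_one(p):
    c = np.asarray(p["obj"], dtype=float)
    n = c.size
    sgn = -1.0 if p.get("sense", "min") == "max" else 1.0
    lo = _inf(p.get("lower", np.zeros(n)))
    hi = _inf(p.get("upper", np.full(n, np.inf)))
    A_eq = np.asarray(p.get("A_eq") or np.zeros((0, n)), dtype=float).reshape(-1, n)
    b_eq = np.asarray(p.get("b_eq") or [], dtype=float)
    A_le = np.asarray(p.get("A_le") or np.zeros((0, n)), dtype=float).reshape(-1, n)
    b_le = np.asarray(p.get("b_le") or [], dtype=float)
    int_idx = np.asarray(p.get("int_idx") or [], dtype=int)

    if int_idx.size == 0:
        r = linprog(sgn * c, A_ub=A_le if A_le.size else None,
                    b_ub=b_le if b_le.size else None,
                    A_eq=A_eq if A_eq.size else None,
                    b_eq=b_eq if b_eq.size else None,
                    bounds=np.column_stack([lo, hi]), method="highs")
        if r.status == 2:
            return {"status": "infeasible", "objective": None, "x": None}
        if r.status == 3:
            return {"status": "unbounded", "objective": None, "x": None}
        if not r.success:
            return {"status": "error", "objective": None, "x": None}
        return {"status": "optimal", "objective": sgn * r.fun, "x": list(r.x)}

    cons = []
    if A_eq.size:
        cons.append(LinearConstraint(A_eq, b_eq, b_eq))
    if A_le.size:
        cons.append(LinearConstraint(A_le, -np.inf, b_le))
    integrality = np.zeros(n)
    integrality[int_idx] = 1
    r = milp(sgn * c, constraints=cons, bounds=Bounds(lo, hi),
             integrality=integrality,
             options={"mip_rel_gap": 0.0, "presolve": True})
    if r.status == 2:
        return {"status": "infeasible", "objective": None, "x": None}
    if r.status == 3:
        return {"status": "unbounded", "objective": None, "x": None}
    if not r.success:
        return {"status": "error", "objective": None, "x": None}
    return {"status": "optimal", "objective": sgn * r.fun, "x": list(r.x)}


def main():
    fin, fout = sys.argv[1], sys.argv[2]
    with open(fin) as fh:
        problems = json.load(fh)
    res = [solve_one(p) for p in problems]
    out = {
        "status": [r["status"] for r in res],
        "objective": [r["objective"] for r in res],
        "x": [r["x"] for r in res],
    }
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
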