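#!/usr/bin/env python
"""Batch LP/MILP solving backend.

Reads a JSON file holding a list of problems, solves each with scipy's HiGHS
interface, and writes a JSON list of results. Invoked by the R package; not a
user-facing tool.

Problem schema (all arrays plain JSON lists; null bounds mean +/-infinity):
  nvar        number of variables
  obj         objective coefficients (length nvar)
  sense       "min" | "max"
  lb, ub      variable bounds
  vtype       list of "C" (continuous) or "B" (binary, implies [0,1] integer)
  A           {"i": rows, "j": cols, "v": values}, 0-based triplets
  rlb, rub    constraint row bounds (A x between rlb and rub)

Result: {"status": str, "objective": float|None, "x": [..]|None}
status in {"optimal", "infeasible", "unbounded", "limit", "error"}.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def _arr(x, default, n):
    if x is None:
        return np.full(n, default, dtype=float)
    a = np.array([default if v is None else float(v) for v in x], dtype=float)
    return a


def solve_one(p):
    n = int(p["nvar"])
    c = np.asarray(p["obj"], dtype=float)
    if p.get("sense", "min") == "max":
        c = -c
    lb = _arr(p.get("lb"), -np.inf, n)
    ub = _arr(p.get("ub"), np.inf, n)
    vtype = p.get("vtype") or ["C"] * n
    integrality = np.array([1 if t == "B" else 0 for t in vtype])
    if integrality.any():
        lb = np.where(integrality == 1, np.maximum(lb, 0.0), lb)
        ub = np.where(integrality == 1, np.minimum(ub, 1.0), ub)

    constraints = []
    A = p.get("A")
    if A is not None and len(A["i"]) > 0:
        nrow = int(max(A["i"])) + 1
        nrow = max(nrow, len(p["rlb"]))
        mat = sparse.csr_matrix(
            (np.asarray(A["v"], dtype=float),
             (np.asarray(A["i"], dtype=int), np.asarray(A["j"], dtype=int))),
            shape=(len(p["rlb"]), n),
        )
        rlb = _arr(p.get("rlb"), -np.inf, mat.shape[0])
        rub = _arr(p.get("rub"), np.inf, mat.shape[0])
        constraints.append(LinearConstraint(mat, rlb, rub))

    try:
        res = milp(
            c,
            constraints=constraints,
            integrality=integrality,
            bounds=Bounds(lb, ub),
            options={"presolve": True, "mip_rel_gap": 1e-9},
        )
    except Exception as exc:  # pragma: no cover - defensive
        return {"status": "error", "message": str(exc),
                "objective": None, "x": None}

    status_map = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded"}
    status = status_map.get(res.status, "error")
    if res.x is None or res.status != 0:
        return {"status": status, "objective": None, "x": None}
    obj = float(res.fun)
    if p.get("sense", "min") == "max":
        obj = -obj
    return {"status": status, "objective": obj, "x": [float(v) for v in res.x]}


def main(argv):
    infile, outfile = argv[1], argv[2]
    with open(infile) as fh:
        payload = json.load(fh)
    results = [solve_one(p) for p in payload["problems"]]
    with open(outfile, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv)
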