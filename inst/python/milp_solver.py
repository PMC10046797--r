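"""Batch MILP worker.

Reads a JSON file holding a list of MILPs in sparse triplet form, solves
each with scipy's HiGHS interface, and writes a JSON list of results.
One process per batch keeps interpreter start-up off the per-model cost.

Usage: python milp_solver.py input.json output.json
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import coo_matrix

INF_SENTINEL = 1e29  # values at or beyond this magnitude mean +/-inf


def _arr(x, dtype=float):
    a = np.asarray(x, dtype=dtype)
    return np.atleast_1d(a)


def _definf(a):
    a = a.copy()
    a[a >= INF_SENTINEL] = np.inf
    a[a <= -INF_SENTINEL] = -np.inf
    return a


def _sparse(block, ncol):
    i = _arr(block["i"], int) - 1  # 1-based from R
    j = _arr(block["j"], int) - 1
    x = _arr(block["x"])
    return coo_matrix((x, (i, j)), shape=(int(block["nrow"]), ncol)).tocsc()


def solve_one(prob, options):
    n = int(prob["n"])
    c = _arr(prob["obj"])
    constraints = []
    if prob.get("A_ub") and int(prob["A_ub"]["nrow"]) > 0:
        A = _sparse(prob["A_ub"], n)
        constraints.append(LinearConstraint(A, -np.inf, _arr(prob["b_ub"])))
    if prob.get("A_eq") and int(prob["A_eq"]["nrow"]) > 0:
        A = _sparse(prob["A_eq"], n)
        b = _arr(prob["b_eq"])
        constraints.append(LinearConstraint(A, b, b))
    bounds = Bounds(_definf(_arr(prob["lb"])), _definf(_arr(prob["ub"])))
    res = milp(
        c,
        constraints=constraints,
        bounds=bounds,
        integrality=_arr(prob["integrality"]),
        options=dict(
            time_limit=float(options.get("time_limit", 200.0)),
            mip_rel_gap=float(options.get("mip_rel_gap", 0.0)),
            disp=False,
        ),
    )
    out = {
        "status": int(res.status),
        "message": str(res.message),
        "objective": None if res.fun is None else float(res.fun),
        "x": None if res.x is None else [float(v) for v in res.x],
    }
    gap = getattr(res, "mip_gap", None)
    out["mip_gap"] = None if gap is None else float(gap)
    return out


def main(argv):
    with open(argv[1]) as fh:
        payload = json.load(fh)
    options = payload.get("options", {})
    results = [solve_one(p, options) for p in payload["problems"]]
    with open(argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv)
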