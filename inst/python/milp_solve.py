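#!/usr/bin/env python
"""Batch MILP worker around scipy.optimize.milp (HiGHS).

Protocol: one JSON object per line on stdin, one JSON object per line on
stdout. Request: {"problems": [problem, ...]} or {"ping": 1} or {"quit": 1}.

problem = {
  "obj":  [...],            primary objective (minimized)
  "obj2": [...], "obj3":    optional lexicographic tie-break objectives
  "lb", "ub":   variable bounds (|x| >= 1e29 means infinite)
  "vtype":      list of "C"/"I"/"B"
  "ai","aj","ax": constraint triplets, 1-based rows/cols
  "rlb","rub":  row bounds
  "time_limit": seconds (optional)
}

Response: {"solutions": [{"status": s, "objective": v, "x": [...],
                          "incumbent": bool}]}

Usage: milp_solve.py            (worker mode, stdin/stdout)
       milp_solve.py IN OUT     (one-shot batch: read IN, write OUT)
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF_SENTINEL = 1e29
TOL = 1e-6


def _inf(v):
    a = np.asarray(v, dtype=float)
    a[a >= INF_SENTINEL] = np.inf
    a[a <= -INF_SENTINEL] = -np.inf
    return a


def solve_one(prob):
    obj = np.asarray(prob["obj"], dtype=float)
    nv = obj.size
    lb = _inf(prob["lb"])
    ub = _inf(prob["ub"])
    integrality = np.array(
        [1 if t in ("I", "B") else 0 for t in prob["vtype"]], dtype=int)
    ai = np.asarray(prob.get("ai", []), dtype=int) - 1
    aj = np.asarray(prob.get("aj", []), dtype=int) - 1
    ax = np.asarray(prob.get("ax", []), dtype=float)
    nrow = int(ai.max()) + 1 if ai.size else 0
    rlb = _inf(prob.get("rlb", []))
    rub = _inf(prob.get("rub", []))
    opts = {"presolve": True, "mip_rel_gap": 0.0}
    if prob.get("time_limit"):
        opts["time_limit"] = float(prob["time_limit"])

    def run(c, extra_rows):
        rows = [sparse.coo_matrix((ax, (ai, aj)), shape=(nrow, nv))] \
            if nrow else []
        lo, hi = [rlb], [rub]
        for (cvec, cap) in extra_rows:
            rows.append(sparse.coo_matrix(np.asarray(cvec)[None, :]))
            lo.append([-np.inf])
            hi.append([cap])
        cons = []
        if rows:
            A = sparse.vstack(rows).tocsc()
            cons = [LinearConstraint(A, np.concatenate(lo),
                                     np.concatenate(hi))]
        res = milp(c=c, constraints=cons, integrality=integrality,
                   bounds=Bounds(lb, ub), options=opts)
        if res.status == 4:
            # HiGHS presolve occasionally errors on valid models; retry raw
            res = milp(c=c, constraints=cons, integrality=integrality,
                       bounds=Bounds(lb, ub),
                       options={**opts, "presolve": False})
        return res

    res = run(obj, [])
    if res.status == 2:
        return {"status": "infeasible", "objective": None, "x": None,
                "incumbent": False}
    if res.x is None:
        return {"status": "failed", "objective": None, "x": None,
                "incumbent": False}
    incumbent = res.status == 1
    v1 = float(obj @ res.x)
    x = res.x
    extra = [(obj, v1 + TOL)]
    for key in ("obj2", "obj3"):
        if key in prob and prob[key] is not None and not incumbent:
            c2 = np.asarray(prob[key], dtype=float)
            if not np.any(c2):
                continue
            r2 = run(c2, extra)
            if r2.x is None:
                break
            x = r2.x
            extra.append((c2, float(c2 @ r2.x) + TOL))
    return {"status": "incumbent" if incumbent else "optimal",
            "objective": v1, "x": [float(v) for v in x],
            "incumbent": incumbent}


def handle(req):
    if "ping" in req:
        return {"pong": 1}
    return {"solutions": [solve_one(p) for p in req.get("problems", [])]}


def main():
    if len(sys.argv) == 3:
        with open(sys.argv[1]) as fh:
            req = json.load(fh)
        with open(sys.argv[2], "w") as fh:
            json.dump(handle(req), fh)
        return
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        req = json.loads(line)
        if "quit" in req:
            break
        sys.stdout.write(json.dumps(handle(req)) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
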