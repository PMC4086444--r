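"""Solve a sparse LP exchanged as plain text; called by deidlp::solve_lp.

Problem:  min c'x  s.t.  A_eq x = 1,  A_ge x >= 0,  x >= 0.
Input dir: meta.json {n_var, n_eq, n_ge}; c.txt (one coefficient per line);
eq.csv / ge.csv (1-based row,col,val triplets).  Output: result.json with
status and objective, x.txt with the solution on success.
"""
import json
import sys

import numpy as np
import scipy.sparse as sp
from scipy.optimize import linprog

STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
          3: "unbounded", 4: "numeric_failure"}


def load_triplets(path, shape):
    try:
        t = np.loadtxt(path, delimiter=",", ndmin=2)
    except ValueError:
        t = np.empty((0, 3))
    if t.size == 0:
        return sp.csc_matrix(shape)
    return sp.csc_matrix(
        (t[:, 2], (t[:, 0].astype(int) - 1, t[:, 1].astype(int) - 1)),
        shape=shape)


def main(d):
    with open(f"{d}/meta.json") as fh:
        meta = json.load(fh)
    n, n_eq, n_ge = meta["n_var"], meta["n_eq"], meta["n_ge"]
    c = np.loadtxt(f"{d}/c.txt", ndmin=1)
    A_eq = load_triplets(f"{d}/eq.csv", (n_eq, n))
    A_ge = load_triplets(f"{d}/ge.csv", (n_ge, n))
    kw = {}
    if n_ge > 0:
        kw.update(A_ub=-A_ge, b_ub=np.zeros(n_ge))
    # interior point with crossover: proves infeasibility of near-degenerate
    # risk systems orders of magnitude faster than dual simplex while still
    # returning a basic optimal solution; serial and deterministic
    res = linprog(c, A_eq=A_eq, b_eq=np.ones(n_eq), bounds=(0, None),
                  method="highs-ipm", **kw)
    status = STATUS.get(res.status, "numeric_failure")
    out = {"status": status,
           "objective": float(res.fun) if res.status == 0 else None}
    if res.status == 0:
        np.savetxt(f"{d}/x.txt", res.x, fmt="%.17g")
    with open(f"{d}/result.json", "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1])
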