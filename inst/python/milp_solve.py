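"""Batch (MI)LP solver backend.

Reads a JSON array of problems, each with fields:
  obj          objective coefficients (length nvar)
  Ai, Aj, Av   equality-constraint matrix in 1-based triplet form
  rhs          equality right-hand sides
  lb, ub       variable bounds
  integrality  per-variable 0 (continuous) / 1 (integer)
and writes a JSON array of {status, success, fun, x} results.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def solve(prob):
    c = np.asarray(prob["obj"], dtype=float)
    n = c.size
    rhs = np.atleast_1d(np.asarray(prob["rhs"], dtype=float))
    ai = np.atleast_1d(np.asarray(prob["Ai"], dtype=int)) - 1
    aj = np.atleast_1d(np.asarray(prob["Aj"], dtype=int)) - 1
    av = np.atleast_1d(np.asarray(prob["Av"], dtype=float))
    A = sparse.csc_matrix((av, (ai, aj)), shape=(rhs.size, n))
    res = milp(
        c,
        constraints=LinearConstraint(A, rhs, rhs),
        integrality=np.atleast_1d(np.asarray(prob["integrality"], dtype=int)),
        bounds=Bounds(
            np.atleast_1d(np.asarray(prob["lb"], dtype=float)),
            np.atleast_1d(np.asarray(prob["ub"], dtype=float)),
        ),
    )
    return {
        "status": int(res.status),
        "success": bool(res.success),
        "message": str(res.message),
        "fun": None if res.fun is None else float(res.fun),
        "x": [] if res.x is None else [float(v) for v in res.x],
    }


def main():
    infile, outfile = sys.argv[1], sys.argv[2]
    with open(infile) as fh:
        problems = json.load(fh)
    with open(outfile, "w") as fh:
        json.dump([solve(p) for p in problems], fh)


if __name__ == "__main__":
    main()
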