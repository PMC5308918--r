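#!/usr/bin/env python
"""Linear-programming oracle for 1-D optimal transport between histograms.

Reads a JSON file {"pairs": [{"support_a": [...], "weights_a": [...],
"support_b": [...], "weights_b": [...]}, ...]} and writes a JSON array with
the minimal transport cost of each pair, solving

    min sum_{j,k} g(j,k) |s_a(j) - s_b(k)|
    s.t. sum_k g(j,k) = w_a(j)  for all j
         sum_j g(j,k) = w_b(k)  for all k
         g(j,k) >= 0

directly as a linear program (scipy HiGHS). Independent of the package's
cumulative-sweep implementation.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog
from scipy.sparse import lil_matrix


def transport_cost(sa, wa, sb, wb):
    sa = np.asarray(sa, dtype=float)
    sb = np.asarray(sb, dtype=float)
    wa = np.asarray(wa, dtype=float)
    wb = np.asarray(wb, dtype=float)
    na, nb = len(sa), len(sb)
    cost = np.abs(sa[:, None] - sb[None, :]).ravel()
    A = lil_matrix((na + nb, na * nb))
    for j in range(na):
        A[j, j * nb:(j + 1) * nb] = 1.0
    for k in range(nb):
        A[na + k, k::nb] = 1.0
    rhs = np.concatenate([wa, wb])
    res = linprog(cost, A_eq=A.tocsr(), b_eq=rhs, bounds=(0, None),
                  method="highs")
    if res.status != 0:
        raise RuntimeError("LP failed: %s" % res.message)
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        spec = json.load(fh)
    out = [transport_cost(p["support_a"], p["weights_a"],
                          p["support_b"], p["weights_b"])
           for p in spec["pairs"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
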