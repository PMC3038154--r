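#!/usr/bin/env python
"""Solve a CPLEX-LP-format problem with scipy's HiGHS interface.

Usage: solve_lp.py problem.lp solution.txt [time_limit_seconds]

Reads the LP-file subset written by the R side (explicit coefficients,
one constraint per line, Bounds/Binary sections) and writes a plain
solution file:

    status OPTIMAL
    objective 3.25
    x1 0.5
    ...
"""
import re
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix

TOKEN = re.compile(
    r"[0-9.]+(?:[eE][+-]?[0-9]+)?|[A-Za-z_][A-Za-z0-9_]*|[+-]")


def parse_lp(path):
    sections = {}
    current = None
    with open(path) as fh:
        for raw in fh:
            line = raw.strip()
            if not line or line.startswith("\\"):
                continue
            key = line.lower()
            if key in ("maximize", "minimize", "subject to", "bounds",
                       "binary", "general", "end"):
                current = key
                sections[current] = []
                continue
            sections.setdefault(current, []).append(line)
    sense = 1 if "minimize" in sections else -1
    obj_lines = sections.get("maximize", sections.get("minimize", []))
    objective = parse_terms(" ".join(obj_lines).split(":", 1)[1])
    constraints = []
    for line in sections.get("subject to", []):
        name, rest = line.split(":", 1)
        m = re.search(r"(<=|>=|=)\s*([-+0-9.eE]+)\s*$", rest)
        rel, rhs = m.group(1), float(m.group(2))
        constraints.append((name.strip(), parse_terms(rest[: m.start()]), rel, rhs))
    bounds = {}
    for line in sections.get("bounds", []):
        if line.endswith(" free"):
            bounds[line.split()[0]] = (-np.inf, np.inf)
            continue
        toks = line.split()
        if toks[1] == "=":
            bounds[toks[0]] = (float(toks[2]), float(toks[2]))
        elif toks[1] == ">=":
            bounds[toks[0]] = (float(toks[2]), np.inf)
        elif toks[1] == "<=" and len(toks) == 3:
            bounds[toks[0]] = (-np.inf, float(toks[2]))
        else:  # lo <= x <= hi
            bounds[toks[2]] = (float(toks[0]), float(toks[4]))
    binaries = set()
    for line in sections.get("binary", []):
        binaries.update(line.split())
    return sense, objective, constraints, bounds, binaries


def parse_terms(text):
    terms = {}
    sign, coeff = 1.0, None
    for tok in TOKEN.findall(text):
        if tok == "+":
            sign, coeff = 1.0, None
        elif tok == "-":
            sign, coeff = -1.0, None
        elif tok[0].isdigit() or tok[0] == ".":
            coeff = float(tok)
        else:
            terms[tok] = terms.get(tok, 0.0) + sign * (
                1.0 if coeff is None else coeff)
            sign, coeff = 1.0, None
    return terms


def main():
    lp_path, out_path = sys.argv[1], sys.argv[2]
    time_limit = float(sys.argv[3]) if len(sys.argv) > 3 else 600.0
    sense, objective, constraints, bounds, binaries = parse_lp(lp_path)
    names = []
    seen = set()
    for source in ([objective] + [c[1] for c in constraints]):
        for nm in source:
            if nm not in seen:
                seen.add(nm)
                names.append(nm)
    for nm in list(bounds) + sorted(binaries):
        if nm not in seen:
            seen.add(nm)
            names.append(nm)
    idx = {nm: i for i, nm in enumerate(names)}
    n = len(names)
    c = np.zeros(n)
    for nm, co in objective.items():
        c[idx[nm]] = sense * co
    lo = np.zeros(n)
    hi = np.full(n, np.inf)
    integrality = np.zeros(n)
    for nm in names:
        i = idx[nm]
        if nm in binaries:
            lo[i], hi[i], integrality[i] = 0.0, 1.0, 1
        elif nm in bounds:
            lo[i], hi[i] = bounds[nm]
    rows, cols, vals, clo, chi = [], [], [], [], []
    for k, (_, terms, rel, rhs) in enumerate(constraints):
        for nm, co in terms.items():
            rows.append(k)
            cols.append(idx[nm])
            vals.append(co)
        clo.append(rhs if rel in (">=", "=") else -np.inf)
        chi.append(rhs if rel in ("<=", "=") else np.inf)
    A = csr_matrix((vals, (rows, cols)), shape=(len(constraints), n))
    lc = LinearConstraint(A, np.array(clo), np.array(chi))
    res = milp(c=c, constraints=lc, integrality=integrality,
               bounds=Bounds(lo, hi), options={"time_limit": time_limit})
    status = {0: "OPTIMAL", 2: "INFEASIBLE", 3: "UNBOUNDED"}.get(res.status)
    if status is None:
        sys.stderr.write("solver status %s: %s\n" % (res.status, res.message))
        sys.exit(3)
    with open(out_path, "w") as fh:
        if status == "OPTIMAL":
            fh.write("status OPTIMAL\n")
            fh.write("objective %.12g\n" % (sense * res.fun))
            for nm in names:
                fh.write("%s %.12g\n" % (nm, res.x[idx[nm]]))
        else:
            fh.write("status %s\nobjective nan\n" % status)


if __name__ == "__main__":
    main()
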