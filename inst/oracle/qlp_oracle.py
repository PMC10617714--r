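#!/usr/bin/env python
"""Independent convex-optimization oracle for the allocation problems.

Reads a JSON list of {model, problem} bundles on the path given as argv[1]
and writes a JSON list of {status, objective} to argv[2].  The model is the
package's native toy-model JSON (assumed irreversible, condition bounds
already applied); the problem names a variant and its parameters.  The
formulation here is written from scratch against scipy (HiGHS for LPs,
trust-constr for convex QPs) and shares no code with the R implementation.

Variables are x = [v (fluxes), E (abundances)] plus nonnegative auxiliary
variables for absolute-value terms.  Constraints: S v = 0; per-enzyme
capacity sum_j v_j / kcat_ij <= E_i; optional total-enzyme row
(equality or upper bound); flux and abundance bounds.

Objectives (matching the package's reporting conventions):
  LP1  sum_i |Eref_i/Ereftot - E_i/Estot|        over reference enzymes
  QP1  sum_i (Eref_i/Ereftot - E_i/Estot)^2
  LP2  LP1 + lambda * sum_j |vref_j - v_j|
  QP2  QP1 + lambda * sum_j (vref_j - v_j)^2
  PFBA sum_j v_j                  ESKCAT sum_ij E_i * kcat_ij
  BASELINE1 sum_i E_i             BASELINE2 sum_i E_i^2
  FBA  max v_bio (objective reported as the maximum)
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog, minimize, LinearConstraint, Bounds


def build(model):
    mets = list(model["metabolites"])
    rxns = [r["id"] for r in model["reactions"]]
    nr, nm = len(rxns), len(mets)
    S = np.zeros((nm, nr))
    lb = np.zeros(nr)
    ub = np.zeros(nr)
    for j, r in enumerate(model["reactions"]):
        lb[j], ub[j] = r["lb"], r["ub"]
        for met, coef in (r.get("stoich") or {}).items():
            S[mets.index(met), j] = coef
    enz = [e["id"] for e in model["enzymes"]]
    ne = len(enz)
    kcat = np.zeros((ne, nr))
    eub = np.full(ne, np.inf)
    for i, e in enumerate(model["enzymes"]):
        for rxn, k in (e.get("kcats") or {}).items():
            kcat[i, rxns.index(rxn)] = k
        if "ub" in e and e["ub"] is not None:
            eub[i] = e["ub"]
    return dict(S=S, lb=lb, ub=ub, rxns=rxns, enz=enz, kcat=kcat,
                eub=eub, bio=rxns.index(model["biomass"]))


def base_constraints(m, estot=None, pool_sense="le"):
    nr, ne = len(m["rxns"]), len(m["enz"])
    n = nr + ne
    A_eq = np.hstack([m["S"], np.zeros((m["S"].shape[0], ne))])
    b_eq = np.zeros(m["S"].shape[0])
    rows = []
    for i in range(ne):
        mask = m["kcat"][i] > 0
        if mask.any():
            row = np.zeros(n)
            row[:nr][mask] = 1.0 / m["kcat"][i][mask]
            row[nr + i] = -1.0
            rows.append(row)
    A_ub = np.array(rows) if rows else np.zeros((0, n))
    b_ub = np.zeros(len(rows))
    if estot is not None and np.isfinite(estot):
        row = np.concatenate([np.zeros(nr), np.ones(ne)])
        if pool_sense == "eq":
            A_eq = np.vstack([A_eq, row])
            b_eq = np.append(b_eq, estot)
        else:
            A_ub = np.vstack([A_ub, row])
            b_ub = np.append(b_ub, estot)
    lo = np.concatenate([m["lb"], np.zeros(ne)])
    hi = np.concatenate([m["ub"], m["eub"]])
    return A_eq, b_eq, A_ub, b_ub, lo, hi


def solve_lp(c, A_eq, b_eq, A_ub, b_ub, lo, hi):
    res = linprog(c, A_ub=A_ub if len(A_ub) else None,
                  b_ub=b_ub if len(b_ub) else None,
                  A_eq=A_eq if len(A_eq) else None,
                  b_eq=b_eq if len(b_eq) else None,
                  bounds=list(zip(lo, hi)), method="highs")
    return res


def _trust_constr(P, q, A_eq, b_eq, A_ub, b_ub, lo, hi, x0):
    cons = []
    if len(A_eq):
        cons.append(LinearConstraint(A_eq, b_eq, b_eq))
    if len(A_ub):
        cons.append(LinearConstraint(A_ub, -np.inf, b_ub))
    hi2 = np.where(np.isfinite(hi), hi, 1e9)
    fun = lambda x: 0.5 * np.sum(P * x * x) + q @ x
    return minimize(fun, x0, jac=lambda x: P * x + q,
                    hess=lambda x: np.diag(P),
                    method="trust-constr", constraints=cons,
                    bounds=Bounds(lo, hi2),
                    options=dict(gtol=1e-12, xtol=1e-14, maxiter=3000))


def solve_qp(P, q, A_eq, b_eq, A_ub, b_ub, lo, hi):
    """min 0.5 x'Px + q'x; P diagonal (vector)."""
    n = len(q)
    # feasible start from an LP
    res0 = solve_lp(np.zeros(n), A_eq, b_eq, A_ub, b_ub, lo, hi)
    if not res0.success:
        return None
    fun = lambda x: 0.5 * np.sum(P * x * x) + q @ x
    res = _trust_constr(P, q, A_eq, b_eq, A_ub, b_ub, lo, hi, res0.x)
    if not res.success:
        return res
    ## re-solve in variables scaled to O(1) magnitudes (tightens the
    ## solver tolerances on problems with tiny abundances), keep the
    ## better of the two optima
    s = np.maximum(np.abs(res.x), 1e-3 * (np.abs(res.x).max() + 1e-30))
    rs = _trust_constr(P * s * s, q * s,
                       A_eq * s if len(A_eq) else A_eq, b_eq,
                       A_ub * s if len(A_ub) else A_ub, b_ub,
                       lo / s, hi / s, res.x / s)
    if rs.success and fun(rs.x * s) < fun(res.x):
        res.x = rs.x * s
        res.fun = fun(res.x)
    ## active-set KKT polish: re-solve the equality-constrained QP on the
    ## constraints active at the approximate optimum (machine accuracy)
    x = res.x
    tol = lambda b: 1e-6 * (1.0 + abs(b))
    act = [A_eq[i] for i in range(len(A_eq))] if len(A_eq) else []
    rhs = list(b_eq) if len(b_eq) else []
    for i in range(len(A_ub)):
        if b_ub[i] - A_ub[i] @ x < tol(b_ub[i]):
            act.append(A_ub[i]); rhs.append(b_ub[i])
    for i in range(n):
        e = np.zeros(n)
        if np.isfinite(lo[i]) and x[i] - lo[i] < tol(lo[i]):
            e[i] = 1.0; act.append(e.copy()); rhs.append(lo[i])
        elif np.isfinite(hi[i]) and hi[i] - x[i] < tol(hi[i]):
            e[i] = 1.0; act.append(e.copy()); rhs.append(hi[i])
    if act:
        A = np.array(act); b = np.array(rhs)
        K = np.block([[np.diag(P), A.T],
                      [A, np.zeros((len(b), len(b)))]])
        r = np.concatenate([-q, b])
        sol, *_ = np.linalg.lstsq(K, r, rcond=None)
        xp = sol[:n]
        feas = (np.all(xp >= lo - 1e-8) and np.all(xp <= hi + 1e-8)
                and (not len(A_eq)
                     or np.abs(A_eq @ xp - b_eq).max() < 1e-8)
                and (not len(A_ub)
                     or (A_ub @ xp - b_ub).max() < 1e-8))
        if feas and fun(xp) <= fun(x) + 1e-9:
            res.x = xp
            res.fun = fun(xp)
    return res


def run(bundle):
    m = build(bundle["model"])
    pb = bundle["problem"]
    variant = pb["variant"]
    nr, ne = len(m["rxns"]), len(m["enz"])
    estot = pb.get("estot")
    mu_int = pb.get("mu_interval")
    if mu_int:
        m["lb"][m["bio"]] = max(m["lb"][m["bio"]], mu_int[0])
        m["ub"][m["bio"]] = min(m["ub"][m["bio"]], mu_int[1])

    if variant in ("PFBA", "ESKCAT", "BASELINE1", "FBA"):
        A_eq, b_eq, A_ub, b_ub, lo, hi = base_constraints(
            m, estot, pb.get("pool_sense", "le"))
        c = np.zeros(nr + ne)
        if variant == "PFBA":
            c[:nr] = 1.0
        elif variant == "ESKCAT":
            c[nr:] = m["kcat"].sum(axis=1)
        elif variant == "BASELINE1":
            c[nr:] = 1.0
        else:
            c[m["bio"]] = -1.0
        res = solve_lp(c, A_eq, b_eq, A_ub, b_ub, lo, hi)
        if not res.success:
            return dict(status="infeasible", objective=None)
        obj = -res.fun if variant == "FBA" else res.fun
        return dict(status="optimal", objective=obj)

    if variant == "BASELINE2":
        A_eq, b_eq, A_ub, b_ub, lo, hi = base_constraints(
            m, estot, pb.get("pool_sense", "le"))
        P = np.zeros(nr + ne)
        P[nr:] = 2.0
        res = solve_qp(P, np.zeros(nr + ne), A_eq, b_eq, A_ub, b_ub,
                       lo, hi)
        if res is None or not res.success:
            return dict(status="infeasible", objective=None)
        x = res.x
        return dict(status="optimal", objective=float(np.sum(x[nr:] ** 2)))

    # distance variants
    eref = pb["eref"]
    ereftot = pb["ereftot"]
    lam = pb.get("lambda", 0.0) or 0.0
    sup = [m["enz"].index(e) for e in eref]
    a = np.array([eref[e] for e in eref]) / ereftot
    vref = np.zeros(nr)
    for r, val in (pb.get("vref") or {}).items():
        if r in m["rxns"]:
            vref[m["rxns"].index(r)] = val
    A_eq, b_eq, A_ub, b_ub, lo, hi = base_constraints(m, estot, "eq")
    n0 = nr + ne

    if variant in ("LP1", "LP2"):
        k = len(sup)
        naux = k + (nr if lam > 0 else 0)
        n = n0 + naux
        pad = lambda A: np.hstack([A, np.zeros((A.shape[0], naux))])
        A_eq2, A_ub2 = pad(A_eq), pad(A_ub)
        rows, rhs = [], []
        for t, i in enumerate(sup):      # |a_t - E_i/estot| <= aux_t
            row = np.zeros(n)
            row[nr + i] = 1.0 / estot
            row[n0 + t] = -1.0
            rows.append(row); rhs.append(a[t])
            rows.append(-row - 2 * np.eye(n)[n0 + t]); rhs.append(-a[t])
        if lam > 0:
            for j in range(nr):
                row = np.zeros(n)
                row[j] = 1.0
                row[n0 + k + j] = -1.0
                rows.append(row); rhs.append(vref[j])
                rows.append(-row - 2 * np.eye(n)[n0 + k + j])
                rhs.append(-vref[j])
        A_ub2 = np.vstack([A_ub2, np.array(rows)])
        b_ub2 = np.concatenate([b_ub, np.array(rhs)])
        c = np.zeros(n)
        c[n0:n0 + k] = 1.0
        if lam > 0:
            c[n0 + k:] = lam
        res = solve_lp(c, A_eq2, b_eq, A_ub2, b_ub2,
                       np.concatenate([lo, np.zeros(naux)]),
                       np.concatenate([hi, np.full(naux, np.inf)]))
        if not res.success:
            return dict(status="infeasible", objective=None)
        return dict(status="optimal", objective=res.fun)

    # QP1 / QP2
    P = np.zeros(n0)
    q = np.zeros(n0)
    const = float(np.sum(a ** 2))
    for t, i in enumerate(sup):
        P[nr + i] += 2.0 / estot ** 2
        q[nr + i] += -2.0 * a[t] / estot
    if variant == "QP2" and lam > 0:
        P[:nr] += 2.0 * lam
        q[:nr] += -2.0 * lam * vref
        const += lam * float(np.sum(vref ** 2))
    res = solve_qp(P, q, A_eq, b_eq, A_ub, b_ub, lo, hi)
    if res is None or not res.success:
        return dict(status="infeasible", objective=None)
    return dict(status="optimal", objective=float(res.fun) + const)


def main():
    bundles = json.load(open(sys.argv[1]))
    out = [run(b) for b in bundles]
    json.dump(out, open(sys.argv[2], "w"))


if __name__ == "__main__":
    main()
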