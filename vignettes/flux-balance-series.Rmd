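---
title: "Flux-balance computation series: models, algorithms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-balance computation series: models, algorithms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxseries)
```

## The model class

All computations in this package operate on a stoichiometric metabolic
network: a set of metabolites, a set of reactions with signed stoichiometric
coefficients (negative = substrate), and per-reaction flux bounds. The core
assumption is steady state: internal metabolite concentrations do not change,
so the flux vector $v$ satisfies

$$ S\,v = 0,\qquad lb \le v \le ub, $$

where $S$ is the stoichiometric matrix over *internal* (non-boundary)
metabolites. Boundary metabolites — and reactions crossing the system
boundary (exchanges) — are exempt from mass balance; they model the
environment. Flux units are arbitrary but must be consistent; bounds missing
from an input model are replaced by a finite surrogate of $\pm 10^5$, because
every big-M indicator construction below needs finite bounds to be sound.

A reaction is treated as an exchange if it involves a boundary metabolite
*or* if all its coefficients share one sign (a one-sided stoichiometry such
as $\varnothing \to A$). Published SBML models mark boundaries
inconsistently, so the structural rule acts as a fallback; the flag can also
be set explicitly when constructing a network in code, which takes
precedence (relevant for deliberately mass-unbalanced internal reactions
such as the `make_leaky()` fixture's $A \to 2A$).

## The single-problem layer

Each function of the basic layer formulates one linear (or mixed-integer
linear) program, hands it to an external solver through files, and
interprets the answer. `INFEASIBLE` and `UNBOUNDED` are first-class results,
not errors: a batch that *expects* infeasibility (e.g. "this metabolite must
not be producible in the absence of oxygen") passes exactly when the solver
proves non-existence.

* **`fba_maximize`** — maximize $c \cdot v$; biomass maximization is the
  special case of a singleton $c$.
* **`flux_minimization`** — among vectors meeting the demands, minimize
  $\sum_i w_i |v_i|$. Absolute values are linearized by the split
  $v = p - n$, $p, n \ge 0$, objective $\sum w_i (p_i + n_i)$; at any
  optimum with $w_i > 0$ one part of each pair is zero, so the objective
  equals the weighted flux sum.
* **`moma_l1`** — minimize $\sum_i |v_i - v^{ref}_i|$, the minimization of
  metabolic adjustment after a perturbation. The classical method uses a
  quadratic distance; this package deliberately implements the L1 variant so
  that the entire solver contract stays LP/MILP and every free backend
  works. QP-MOMA is out of scope by design.
* **`room`** — minimize the *count* of reactions whose flux leaves the
  window $v^{ref}_i \pm (\delta |v^{ref}_i| + \epsilon)$, via one binary per
  reaction. The big-M coupling is derived per reaction and per side as the
  distance from the window edge to the bound
  ($M^u_i = \max(0,\, ub_i - v^{ref}_i - d_i)$ and symmetrically below).
  This is the tightest sound relaxation, and it remains correct when the
  reference lies outside the post-knockout bounds — a plain window-width
  big-M would silently cut feasible flux there.
* **`fitness_maximization`** — enzymopathy simulation: each partially
  inhibited reaction is capped at $|v_i| \le \alpha_i\,\mathrm{cap}_i$
  ($\mathrm{cap}_i$ = magnitude of its normal bound), and the objective is
  $F = \sum_k \omega_k f_k$ with auxiliaries $0 \le f_k \le 1$,
  $f_k \le v_k / v^{ref}_k$, and weights normalized to sum 1, so
  $F \in [0,1]$ measures the achievable fraction of the reference target
  rates. The literature names this method but prints no closed formula; the
  capped, normalized linear form here is this package's operationalization
  and is flagged as such.
* **`expression_match`** — two-stage MILP: stage 1 maximizes the number of
  discretized expression states the flux pattern agrees with (HIGH:
  $|v| \ge$ `activity_eps`; LOW: $|v| \le$ `zero_tol`), stage 2 fixes that
  agreement and minimizes the weighted flux sum among agreement-optimal
  solutions. HIGH agreement on a reversible reaction needs an auxiliary
  direction binary, because $|v| \ge \epsilon$ is a disjunction. HIGH and
  LOW agreements are weighted equally.
* **`mfa_fit`** — fit a complete steady-state distribution to measured
  rates by minimizing the weighted L1 residual.

### The thermodynamic feasibility constraint

`compute_fba_t_c` augments an LP formulation (linear maximization, flux
minimization, L1-MOMA or MFA fitting) with concentration-based
thermodynamics, which can only be realized as a MILP. Each internal
metabolite gets a variable $\ln c_m$ within its allowed range; each internal
reaction has an actual Gibbs energy

$$ \Delta G'_r = \Delta G^{0\prime}_r + RT \sum_m n_{mr} \ln c_m , $$

and direction binaries enforce: forward flux above `zero_tol` requires
$\Delta G'_r \le -\varepsilon_G$, backward flux the mirror image, *for one
common witness concentration vector*. Exchange reactions are exempt —
boundary reactions have no defined reaction Gibbs energy in an open system.
With all $\Delta G^{0\prime} = 0$ (the default) the constraint reduces
exactly to the loop law: around any internal cycle the $\Delta G'$ sum
telescopes to zero, so all steps cannot be simultaneously exergonic, and no
internal directed cycle can carry flux. The `margin` parameter
$\varepsilon_G$ is a strict-inequality surrogate: LP solvers know only
non-strict inequalities, so "$< 0$" is implemented as
"$\le -\varepsilon_G$" with $\varepsilon_G = 10^{-3}$ kJ/mol, far below any
physically meaningful energy difference yet far above solver tolerance.

Fluxes of magnitude up to `zero_tol` are exempt from the direction
constraints (a reaction carrying numerically-zero flux imposes no
thermodynamic requirement); consequently a "maximize cycle flux" query on a
loop returns an optimum of at most `zero_tol` rather than exactly zero.

`post_check` independently re-verifies any OPTIMAL solution: mass balance
row by row, bounds and constraint-set satisfaction, and — when a
thermodynamic configuration is supplied — a pure LP over the
$\ln c$ variables with the solution's flux signs fixed, i.e. a further
optimization that asks whether a witness concentration vector exists.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `zero_tol` | $10^{-6}$ | flux | threshold below which a flux counts as zero (support detection, LOW states, thermo exemption) |
| `room_delta` | 0.03 | – | relative half-width of the ROOM tolerance window |
| `room_epsilon` | 0.001 | flux | absolute half-width of the ROOM window |
| `activity_eps` | 0.1 | flux | minimum activity for a HIGH expression match |
| `fva_gamma` | 1 | – | fraction of the base optimum retained during FVA |
| `rt` | 2.577 | kJ/mol | $RT$ at 310 K (body temperature) |
| `default_lnc` | $[\ln 10^{-5}, \ln 10^{-2}]$ | ln(mol/l) | concentration window, 10 µM–10 mM, a typical physiological span |
| `margin` | $10^{-3}$ | kJ/mol | strict-inequality surrogate for $\Delta G' < 0$ |
| `big_m_G` | $10^4$ | kJ/mol | big-M for the energy couplings (generously above any $|\Delta G'|$ reachable inside the concentration window) |

The zero-flux tolerance and the infinite-bound surrogate are this package's
choices; the methods it implements leave them open.

## The upper layer

`run_batch` iterates the single-problem functions over a list of simulation
specifications, each carrying an identifier, an optional objective override,
a constraint set (fixes, ranges, knockouts, partial inhibitions), a
feasibility expectation, and evaluation expressions such as
`R1 > 0 and abs(EX_A) <= 1.5`. Evaluation uses exact solver values with no
tolerance snapping — if a check should be robust, the tolerance belongs in
the expression itself. Failures of individual solves are recorded per row
and never abort a series. Reports are TSV; solutions are written as one
`val` file (reaction-id TAB flux, 6 significant digits, no header) per
simulation plus a combined table, the format downstream network-visualization
tools consume.

The canonical simulation-file grammar (`SIMULATION … END` blocks) is this
package's own; the description-file concept it implements specifies the four
content categories (identifiers, objectives, constraints, evaluation
expressions) but not a syntax. A second, tolerant `fasimu-native` reader
accepts paragraph-per-record files from the original distribution's
examples; since that format's manual is not bundled here, the reader is
best-effort: it recovers record identifiers and counts, and preserves
unrecognized content as comments.

Curation operations built on batches of solves:

* **`fva`** — per-reaction flux minima/maxima, optionally restricted to
  solutions retaining a $\gamma$-fraction of a base objective
  ($2|R| + 1$ LPs).
* **`leak_analysis`** — close *all* exchanges, then for each internal
  metabolite add a drain and maximize it; anything producible from nothing
  marks a stoichiometric inconsistency. The symmetric consumption probe is
  available behind a mode flag but off by default, since mass creation is
  the error class curation hunts first.
* **`prune_network`** — restrict to the functional subnetwork: collect the
  union of flux-minimal supports over all specs, then verify and repair —
  any spec infeasible on the restriction is re-solved on the full network
  with weights biased 1000:1 against not-yet-retained reactions, and its
  support is added. The repair loop terminates because the retained set
  grows monotonically. The published pruning idea is cited, not printed, in
  the sources this package follows; this support-union-with-repair variant
  reproduces its contract (every spec stays feasible, with its flux-min
  objective preserved) but alternate optima mean retained-set *sizes* can
  differ between implementations and solvers. All cross-implementation
  comparisons therefore use objectives and feasibility, never flux vectors
  or exact support sizes.

## Solver interchange

The expensive part — solving the LP/MILP — is delegated to specialized
external software through human-readable files: a CPLEX-LP-format problem
file out, a solution file back. The default backend is GLPK's `glpsol`
(invoked with its presolver disabled, because the presolver collapses the
INFEASIBLE/UNBOUNDED distinction into UNDEFINED; the machine-readable
solution format is used for full-precision values). A second backend drives
scipy's HiGHS interface through a bundled Python script that independently
parses the same LP file; the two backends cross-validate each other in the
test suite. Variable names are sanitized to `x1..xn` in solver files with a
reversible map kept on the problem object, so arbitrary reaction identifiers
survive the round trip. Binary variables are rounded to exact 0/1 on read.
Tie-breaking among alternate optima follows the deterministic variable
order, which makes results stable per solver but *not* across solvers.

## What the synthetic fixtures do and do not show

The fixture library (`make_chain`, `make_parallel`, `make_loop`,
`make_leaky`, `make_random_network`) is designed so that every algorithm has
at least one instance whose exact answer is known by construction or
computable by brute force. The random generator emulates the *structural*
features the algorithms are sensitive to — sparse signed stoichiometry,
mixed reversibility, exchanges, infeasible and degenerate cases — at sizes
(≤ 8 reactions) where the flux polytope's vertex set can be enumerated
exhaustively and objectives verified by inspection. The test suite checks
flux-minimization, MOMA and ROOM objectives against such enumeration on 50+
seeded networks, and the FVA bounds against 1000 sampled feasible points per
fixture.

What passing these tests does *not* show: behavior at genome scale
(thousands of reactions), where solver numerics, degeneracy and MILP
hardness dominate; biological realism of any fixture; or agreement of
retained-set sizes under pruning with other implementations (see above).
The SBML reader targets level 2 versions 1–4 with the kinetic-law
`LOWER_BOUND`/`UPPER_BOUND` parameter convention; level 3 `fbc` bounds are
not interpreted.

## Degenerate inputs and edge cases

Empty networks yield 0×0 matrices, empty reports and no leaks. A constraint
set whose intersection with the bounds is empty returns INFEASIBLE without
calling the solver. Zero-variable problems are answered in-process. Fixes
override ranges; knockouts override everything. Duplicate sink probes and
probes on boundary metabolites are rejected. `write_val` normalizes negative
zero. All emitted files are byte-deterministic given the same inputs.
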