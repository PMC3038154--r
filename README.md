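# fluxseries

Constraint-based analysis of stoichiometric metabolic networks, organized
around **batch series of heterogeneous flux-balance optimizations** — the
workflow used when curating genome-scale reconstructions, where hundreds of
defined metabolic functions ("produce C at rate 1 from this medium", "must
*not* produce X anaerobically") are verified on the fly against a model as
it evolves.

It is aimed at systems-biology practitioners who want, from R or from a
shell:

* the standard single-problem algorithms — biomass maximization, **weighted
  flux minimization**, L1-MOMA and ROOM knockout simulation, **fitness
  maximization under partial enzyme inhibition**, expression-profile
  matching, MFA-style flux fitting;
* a **concentration-based thermodynamic feasibility constraint** as a MILP:
  a reaction may only carry flux in a direction along which
  ΔG′ = ΔG°′ + RT·Σ n·ln c can be made negative for some metabolite
  concentrations within physiological ranges — which, with all ΔG°′ = 0,
  is exactly the loop law forbidding internal cycle fluxes;
* batch execution of a concise simulation description file with automatic
  evaluation (feasibility expectations and flux checks), plus the curation
  operations built on batches of solves: flux variability analysis, leak
  analysis, and pruning to the functional subnetwork.

All computations solve

```
optimize f(v)   subject to   S v = 0,   lb ≤ v ≤ ub,   (constraint set)
```

with S the stoichiometric matrix over internal metabolites. Absolute values
are linearized with nonnegative splits and indicator logic uses big-M
couplings, so everything stays LP/MILP. Problems are exchanged with external
solvers through human-readable files (CPLEX LP format out, solution text
back); the default backend is GLPK's `glpsol`, with a scipy/HiGHS backend as
a cross-check. `INFEASIBLE` is a first-class result: simulations may
*expect* it.

## Worked example

Two routes lead from A to B: directly (`R1`), or in two steps through X
(`R2a`, `R2b`). Demanding one unit of output and minimizing total flux picks
the direct route:

```r
library(fluxseries)

net <- make_parallel()
sol <- flux_minimization(net, constraint_set(fixes = c(EX_B = 1)))
print(sol)
#> <flux_distribution> status OPTIMAL, objective 3, 5 fluxes
round(sol$fluxes, 4)
#> EX_A   R1  R2a  R2b EX_B
#>    1    1    0    0    1
```

The objective 3 is the minimal total flux (uptake + conversion + export);
the two-step route would cost 4. Knocking out `R1` and asking for the
closest feasible flux pattern (L1-MOMA) reroutes through X at distance 3
(R1 loses 1, R2a and R2b gain 1 each):

```r
moma_l1(net, sol, constraint_set(knockouts = "R1"))$objective_value
#> [1] 3
```

Thermodynamics: a closed 3-cycle can carry arbitrary flux under plain FBA,
but no thermodynamically realizable concentration assignment supports it —
the loop law:

```r
loop <- make_loop()
fba_maximize(loop, c(R1 = 1))$objective_value
#> [1] 10
compute_fba_t_c(loop, list(kind = "max_linear",
                           coefficients = c(R1 = 1)))$objective_value
#> [1] 1e-06     # only numerically-zero cycle flux remains admissible
```

Batch simulation from a description file:

```r
demo <- tempfile(); write_demo_simulations(demo)
out <- run_batch(make_chain(3), parse_simulations(demo), "flux-min")
out$report[, c("sim_id", "status", "objective", "expected", "passed")]
#>        sim_id     status objective   expected passed
#> 1   produce_C    OPTIMAL         4   FEASIBLE   TRUE
#> 2  overload_C INFEASIBLE        NA INFEASIBLE   TRUE
#> 3 ko_blocks_C INFEASIBLE        NA INFEASIBLE   TRUE
```

`overload_C` and `ko_blocks_C` pass *because* they are infeasible, as their
specifications expect. Models are read and written as SBML level 2 or a
plain-text flat dialect (`read_sbml`, `read_flat`, …); solutions export as
SBML annotations or `val` flux tables for network visualization tools.

A thin command-line front end covers the same operations:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fluxseries.R",package="fluxseries"))')" \
  simulate --model model.sbml --simulations tests.sim --call flux-min --out results/
```

See `vignettes/flux-balance-series.Rmd` for the formulations, parameter
semantics, and design notes.

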