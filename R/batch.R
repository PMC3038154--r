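# Upper layer: iterate the single-problem functions over a simulation series,
# evaluate each outcome against its expectation and checks, and support the
# network-curation operations built on batches of solves (FVA, leak analysis,
# pruning).

OPTIMIZATION_CALLS <- c("flux-min", "fba-max", "moma", "room", "fitness",
                        "expression", "compute-FBA-T-c")

run_one_spec <- function(net, spec, optimization_call, thermo, params,
                         reference, backend) {
  obj <- spec$objective
  call_kind <- optimization_call
  if (!is.null(obj) && obj$kind == "max_linear" &&
      call_kind %in% c("flux-min", "fba-max"))
    call_kind <- "fba-max"
  switch(call_kind,
    "flux-min" = flux_minimization(net, spec$constraints, params,
                                   backend = backend),
    "fba-max" = {
      if (is.null(obj) || obj$kind != "max_linear")
        stop("fba-max needs a 'max' objective in the simulation spec",
             call. = FALSE)
      fba_maximize(net, obj$coefficients, spec$constraints, params,
                   backend = backend)
    },
    "moma" = {
      if (is.null(reference)) stop("moma needs a reference flux distribution",
                                   call. = FALSE)
      moma_l1(net, reference, spec$constraints, params, backend = backend)
    },
    "room" = {
      if (is.null(reference)) stop("room needs a reference flux distribution",
                                   call. = FALSE)
      room(net, reference, spec$constraints, params, backend = backend)
    },
    "fitness" = {
      if (is.null(obj) || is.null(obj$targets))
        stop("fitness needs an objective with targets", call. = FALSE)
      fitness_maximization(net, obj$targets,
                           constraints = spec$constraints, params = params,
                           backend = backend)
    },
    "expression" = {
      if (is.null(obj) || is.null(obj$expression_states))
        stop("expression needs an objective with expression_states",
             call. = FALSE)
      expression_match(net, obj$expression_states, spec$constraints,
                       params, backend = backend)$solution
    },
    "compute-FBA-T-c" = compute_fba_t_c(
      net, if (is.null(obj)) list(kind = "flux_min") else obj,
      spec$constraints, if (is.null(thermo)) thermo_config() else thermo,
      params, backend = backend),
    stop(sprintf("unknown optimization_call '%s'", call_kind), call. = FALSE))
}

#' Run a batch of simulations
#'
#' Runs each specification independently through the chosen single-problem
#' routine (a spec-level objective overrides the call default), evaluates the
#' outcome against the spec's feasibility expectation and check expressions,
#' and assembles the evaluation report. An INFEASIBLE result is a PASS when
#' the spec expects INFEASIBLE; an unexpected UNBOUNDED outcome is always a
#' FAIL. Individual solver failures are recorded per row and never abort the
#' batch.
#'
#' @inheritParams fba_maximize
#' @param specs List of [simulation_spec()] objects.
#' @param optimization_call Default routine, one of `"flux-min"`, `"fba-max"`,
#'   `"moma"`, `"room"`, `"fitness"`, `"expression"`, `"compute-FBA-T-c"`.
#' @param thermo Optional [thermo_config()] (used by `compute-FBA-T-c`).
#' @param reference Optional reference [flux_distribution()] for MOMA/ROOM.
#' @param out_dir Optional output directory: writes `report.tsv`, one
#'   `<sim_id>.val` per optimal solution, and a combined `solutions.tsv`.
#' @return List with `report` (data.frame: sim_id, status, objective,
#'   expected, passed, checks_failed; attribute `"summary"`) and `solutions`
#'   (named list of [flux_distribution()]).
#' @export
run_batch <- function(net, specs, optimization_call = "flux-min",
                      thermo = NULL, params = algorithm_params(),
                      reference = NULL, out_dir = NULL,
                      backend = getOption("fluxseries.solver", "glpk")) {
  optimization_call <- match.arg(optimization_call, OPTIMIZATION_CALLS)
  stop_if_invalid(net)
  rows <- vector("list", length(specs))
  solutions <- stats::setNames(vector("list", length(specs)),
                               vapply(specs, `[[`, character(1), "sim_id"))
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    t0 <- proc.time()[["elapsed"]]
    sol <- tryCatch(
      run_one_spec(net, spec, optimization_call, thermo, params, reference,
                   backend),
      error = function(e) structure(list(status = "ERROR",
                                         message = conditionMessage(e)),
                                    class = "flux_error"))
    elapsed <- proc.time()[["elapsed"]] - t0
    status <- sol$status
    objective <- if (status == "OPTIMAL") sol$objective_value else NA_real_
    checks_failed <- character()
    if (status == "OPTIMAL") {
      for (ch in spec$checks)
        if (!isTRUE(tryCatch(evaluate_expression(ch, sol),
                             error = function(e) FALSE)))
          checks_failed <- c(checks_failed, ch)
      feas_ok <- spec$expect == "FEASIBLE"
    } else if (status == "INFEASIBLE") {
      feas_ok <- spec$expect == "INFEASIBLE"
    } else {
      feas_ok <- FALSE  # UNBOUNDED or ERROR never passes
    }
    passed <- feas_ok && length(checks_failed) == 0
    message(sprintf("[%s] %s: %s obj=%s %s (%.2f s)", optimization_call,
                    spec$sim_id, status, format(objective),
                    if (passed) "PASS" else "FAIL", elapsed))
    rows[[k]] <- data.frame(
      sim_id = spec$sim_id, status = status, objective = objective,
      expected = spec$expect, passed = passed,
      checks_failed = paste(checks_failed, collapse = "; "),
      stringsAsFactors = FALSE)
    if (inherits(sol, "flux_distribution")) solutions[[k]] <- sol
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sim_id = character(), status = character(),
               objective = numeric(), expected = character(),
               passed = logical(), checks_failed = character(),
               stringsAsFactors = FALSE)
  attr(report, "summary") <- c(n = nrow(report), passed = sum(report$passed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_batch_report(report, file.path(out_dir, "report.tsv"))
    combined <- data.frame(reaction = net$reactions$id,
                           stringsAsFactors = FALSE)
    for (id in names(solutions)) {
      s <- solutions[[id]]
      if (!is.null(s) && s$status == "OPTIMAL") {
        write_val(s, net, file.path(out_dir, paste0(id, ".val")))
        combined[[id]] <- unname(s$fluxes[net$reactions$id])
      }
    }
    utils::write.table(combined, file.path(out_dir, "solutions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(report = report, solutions = solutions)
}

#' Write an evaluation report as TSV
#'
#' @param report The report data.frame from [run_batch()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_batch_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum steady-state flux consistent
#' with the constraint set — and, when a base objective is given, with
#' retaining at least the fraction `fva_gamma` of its optimum
#' (`c . v >= gamma * opt`). Solves 2 LPs per reaction (+1 for the base).
#'
#' @inheritParams fba_maximize
#' @param base_objective Optional named coefficient vector; must be feasible.
#' @return data.frame (`reaction`, `min`, `max`) with attributes `"gamma"`
#'   and `"base_objective"`.
#' @export
fva <- function(net, constraints = constraint_set(), base_objective = NULL,
                params = algorithm_params(),
                backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  eb <- effective_bounds(net, constraints)
  if (eb$conflict) stop("constraints are inconsistent with reaction bounds",
                        call. = FALSE)
  base_opt <- NA_real_
  extra_con <- NULL
  if (!is.null(base_objective)) {
    base <- fba_maximize(net, base_objective, constraints, params,
                         backend = backend)
    if (base$status != "OPTIMAL")
      stop("base objective is ", base$status, "; cannot run the sweep",
           call. = FALSE)
    base_opt <- base$objective_value
    extra_con <- list(name = "fva_base",
                      terms = stats::setNames(unname(base_objective),
                                              vn("v", names(base_objective))),
                      rel = ">=", rhs = params$fva_gamma * base_opt)
  }
  ids <- net$reactions$id
  mins <- maxs <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    for (sense in c("min", "max")) {
      b <- new_lp_builder(sense)
      add_flux_system(b, net, eb)
      if (!is.null(extra_con))
        lp_add_con(b, extra_con$name, extra_con$terms, extra_con$rel,
                   extra_con$rhs)
      lp_set_objective(b, stats::setNames(1, vn("v", id)))
      sol <- solve_lp(lp_finalize(b), backend)
      if (sol$status != "OPTIMAL")
        stop(sprintf("FVA subproblem for '%s' (%s) returned %s", id, sense,
                     sol$status), call. = FALSE)
      if (sense == "min") mins[id] <- sol$objective else maxs[id] <- sol$objective
    }
  }
  out <- data.frame(reaction = ids, min = unname(mins), max = unname(maxs),
                    stringsAsFactors = FALSE)
  attr(out, "gamma") <- params$fva_gamma
  attr(out, "base_objective") <- base_opt
  out
}

#' Leak analysis
#'
#' Closes every exchange reaction in both directions and asks, for each
#' internal metabolite, whether it can still be produced at positive rate —
#' i.e. created from nothing. Any such metabolite marks a stoichiometric
#' inconsistency. With `mode = "consumption"` the symmetric
#' degradable-to-nothing probe is run instead.
#'
#' @inheritParams fba_maximize
#' @param mode `"production"` (default) or `"consumption"`.
#' @return data.frame (`metabolite`, `rate`) of leaks with rate above
#'   `zero_tol`, sorted by metabolite id.
#' @export
leak_analysis <- function(net, params = algorithm_params(),
                          mode = c("production", "consumption"),
                          backend = getOption("fluxseries.solver", "glpk")) {
  mode <- match.arg(mode)
  stop_if_invalid(net)
  closed <- close_boundary(net, "all")
  internal <- closed$metabolites$id[!closed$metabolites$boundary]
  leaks <- list()
  for (m in internal) {
    probe <- if (mode == "production") add_sink(closed, m) else {
      pid <- paste0("SRC_", m)
      n2 <- closed
      n2$reactions <- rbind(n2$reactions, data.frame(
        id = pid, name = pid, lb = 0, ub = INF_BOUND, reversible = FALSE,
        weight = 1, exchange = TRUE, stringsAsFactors = FALSE))
      n2$stoichiometry[[pid]] <- stats::setNames(1, m)
      list(net = n2, sink_id = pid)
    }
    sol <- fba_maximize(probe$net,
                        stats::setNames(1, probe$sink_id),
                        params = params, backend = backend)
    rate <- if (sol$status == "OPTIMAL") sol$objective_value else
      if (sol$status == "UNBOUNDED") Inf else 0
    if (rate > params$zero_tol)
      leaks[[length(leaks) + 1]] <- data.frame(metabolite = m, rate = rate,
                                               stringsAsFactors = FALSE)
  }
  out <- if (length(leaks)) do.call(rbind, leaks) else
    data.frame(metabolite = character(), rate = numeric(),
               stringsAsFactors = FALSE)
  out[order(out$metabolite), , drop = FALSE]
}

#' Restrict a network to a reaction subset
#'
#' Keeps the given reactions (in network order) and the metabolites they
#' reference.
#'
#' @param net A valid [flux_network()].
#' @param rxn_ids Character vector of reaction ids to keep.
#' @return A [flux_network()].
#' @export
subnetwork <- function(net, rxn_ids) {
  keep <- net$reactions$id %in% rxn_ids
  rxns <- net$reactions[keep, , drop = FALSE]
  rownames(rxns) <- NULL
  stoich <- net$stoichiometry[rxns$id]
  used <- unique(unlist(lapply(stoich, names)))
  mets <- net$metabolites[net$metabolites$id %in% used, , drop = FALSE]
  rownames(mets) <- NULL
  structure(list(metabolites = mets, reactions = rxns, stoichiometry = stoich),
            class = "flux_network")
}

# Drop constraint-set entries that reference reactions outside the kept set,
# but only when the dropped entry admits zero flux; otherwise the spec cannot
# hold on the subnetwork at all.
restrict_constraints <- function(cs, kept) {
  impossible <- FALSE
  fx <- cs$fixes[names(cs$fixes) %in% kept]
  gone <- cs$fixes[!names(cs$fixes) %in% kept]
  if (any(gone != 0)) impossible <- TRUE
  rg <- cs$ranges[names(cs$ranges) %in% kept]
  gone_rg <- cs$ranges[!names(cs$ranges) %in% kept]
  for (b in gone_rg) if (b[1] > 0 || b[2] < 0) impossible <- TRUE
  list(cs = constraint_set(fx, rg,
                           intersect(cs$knockouts, kept),
                           cs$inhibitions[names(cs$inhibitions) %in% kept]),
       impossible = impossible)
}

#' Prune a network to its functional subnetwork
#'
#' Phase 1 computes, for every simulation spec, the flux-minimal solution and
#' collects the union U of reactions carrying flux above `zero_tol`. Phase 2
#' restricts the network to U, re-verifies every spec, and repairs: a spec
#' that became infeasible is re-solved on the full network with weights
#' biased 1000:1 against reactions outside U, and its support is added to U.
#' This repeats until every spec is feasible on the retained set. Specs
#' infeasible on the full network are reported and skipped with a warning.
#'
#' @inheritParams fba_maximize
#' @param specs List of [simulation_spec()] objects (at least one).
#' @return List with `net` (the pruned [flux_network()]), `kept` and
#'   `removed` reaction id vectors, and `log` (a data.frame of per-spec
#'   outcomes and repair rounds).
#' @export
prune_network <- function(net, specs, params = algorithm_params(),
                          backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  if (!length(specs)) stop("at least one simulation spec is required",
                           call. = FALSE)
  log <- list()
  note <- function(sim_id, phase, detail)
    log[[length(log) + 1]] <<- data.frame(sim_id = sim_id, phase = phase,
                                          detail = detail,
                                          stringsAsFactors = FALSE)
  support <- character()
  usable <- list()
  for (spec in specs) {
    sol <- flux_minimization(net, spec$constraints, params, backend = backend)
    if (sol$status != "OPTIMAL") {
      warning(sprintf("spec '%s' is %s on the full network; skipped",
                      spec$sim_id, sol$status), call. = FALSE)
      note(spec$sim_id, "collect", paste("skipped:", sol$status))
      next
    }
    supp <- names(sol$fluxes)[abs(sol$fluxes) > params$zero_tol]
    support <- union(support, supp)
    usable[[length(usable) + 1]] <- spec
    note(spec$sim_id, "collect", sprintf("support %d reactions", length(supp)))
  }
  repeat {
    sub <- subnetwork(net, support)
    grew <- FALSE
    for (spec in usable) {
      rc <- restrict_constraints(spec$constraints, support)
      ok <- !rc$impossible
      if (ok) {
        sol <- flux_minimization(sub, rc$cs, params, backend = backend)
        ok <- sol$status == "OPTIMAL"
      }
      if (!ok) {
        # bias the repair solve 1000:1 against reactions not yet retained
        w <- stats::setNames(ifelse(net$reactions$id %in% support, 1, 1000) *
                               net$reactions$weight, net$reactions$id)
        sol <- flux_minimization(net, spec$constraints, params, weights = w,
                                 backend = backend)
        if (sol$status != "OPTIMAL") {
          note(spec$sim_id, "repair", paste("unrepairable:", sol$status))
          next
        }
        supp <- names(sol$fluxes)[abs(sol$fluxes) > params$zero_tol]
        add <- setdiff(supp, support)
        if (length(add)) {
          support <- union(support, supp)
          grew <- TRUE
          note(spec$sim_id, "repair", sprintf("added %d reactions", length(add)))
        }
      }
    }
    if (!grew) break
  }
  pruned <- subnetwork(net, support)
  kept <- pruned$reactions$id
  list(net = pruned, kept = kept,
       removed = setdiff(net$reactions$id, kept),
       log = if (length(log)) do.call(rbind, log) else
         data.frame(sim_id = character(), phase = character(),
                    detail = character(), stringsAsFactors = FALSE))
}
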