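# Basic layer: each function formulates and solves ONE constraint-based
# optimization over a stoichiometric network. All absolute values are
# linearized with nonnegative split variables; indicator logic uses big-M
# couplings, so every problem stays LP/MILP and every backend stays usable.

vn <- function(prefix, id) paste0(prefix, ":", id)

# Apply a constraint set to the reaction bounds. Order of precedence:
# ranges and inhibitions intersect, fixes override, knockouts always win.
effective_bounds <- function(net, constraints) {
  check_constraint_refs(net, constraints)
  lb <- stats::setNames(net$reactions$lb, net$reactions$id)
  ub <- stats::setNames(net$reactions$ub, net$reactions$id)
  for (id in names(constraints$ranges)) {
    rg <- constraints$ranges[[id]]
    lb[id] <- max(lb[id], rg[1]); ub[id] <- min(ub[id], rg[2])
  }
  for (id in names(constraints$inhibitions)) {
    cap <- max(abs(net$reactions$lb[net$reactions$id == id]),
               abs(net$reactions$ub[net$reactions$id == id]))
    a <- constraints$inhibitions[[id]]
    lb[id] <- max(lb[id], -a * cap); ub[id] <- min(ub[id], a * cap)
  }
  for (id in names(constraints$fixes)) {
    lb[id] <- constraints$fixes[[id]]; ub[id] <- constraints$fixes[[id]]
  }
  for (id in constraints$knockouts) { lb[id] <- 0; ub[id] <- 0 }
  list(lb = lb, ub = ub, conflict = any(lb > ub + 1e-12))
}

# Flux variables plus the steady-state rows S v = 0 over internal metabolites.
add_flux_system <- function(b, net, eb) {
  ids <- net$reactions$id
  for (id in ids) lp_add_var(b, vn("v", id), eb$lb[[id]], eb$ub[[id]])
  internal <- net$metabolites$id[!net$metabolites$boundary]
  acc <- stats::setNames(vector("list", length(internal)), internal)
  for (id in ids) {
    s <- net$stoichiometry[[id]]
    for (m in names(s)) {
      if (!is.null(acc[[m]]) || m %in% internal)
        acc[[m]] <- c(acc[[m]], stats::setNames(s[[m]], vn("v", id)))
    }
  }
  for (m in internal) {
    if (length(acc[[m]]))
      lp_add_con(b, vn("mb", m), acc[[m]], "=", 0)
  }
  invisible(ids)
}

# Nonnegative split of v into positive/negative parts for L1 objectives.
add_split_vars <- function(b, net, eb, prefix_p = "p", prefix_n = "n",
                           center = NULL) {
  ids <- net$reactions$id
  if (is.null(center)) center <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    up <- max(eb$ub[[id]] - center[[id]], 0)
    dn <- max(center[[id]] - eb$lb[[id]], 0)
    lp_add_var(b, vn(prefix_p, id), 0, up)
    lp_add_var(b, vn(prefix_n, id), 0, dn)
    lp_add_con(b, vn("split", id),
               stats::setNames(c(1, -1, 1),
                               c(vn("v", id), vn(prefix_p, id),
                                 vn(prefix_n, id))),
               "=", center[[id]])
  }
  invisible(ids)
}

as_reference_vector <- function(net, reference) {
  if (inherits(reference, "flux_distribution")) {
    if (reference$status != "OPTIMAL")
      stop("reference flux distribution is not OPTIMAL", call. = FALSE)
    reference <- reference$fluxes
  }
  ref <- stats::setNames(numeric(nrow(net$reactions)), net$reactions$id)
  known <- intersect(names(reference), names(ref))
  unknown <- setdiff(names(reference), names(ref))
  if (length(unknown))
    stop("reference names unknown reactions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ref[known] <- reference[known]
  ref
}

extract_solution <- function(sol, net, objective_value = sol$objective,
                             lnc_mets = NULL) {
  if (sol$status != "OPTIMAL")
    return(flux_distribution(sol$status))
  ids <- net$reactions$id
  fluxes <- stats::setNames(unname(sol$values[vn("v", ids)]), ids)
  lnc <- NULL
  if (length(lnc_mets))
    lnc <- stats::setNames(unname(sol$values[vn("lnc", lnc_mets)]), lnc_mets)
  flux_distribution("OPTIMAL", fluxes, objective_value, lnc)
}

#' Flux-balance maximization of a linear objective
#'
#' Maximizes `c . v` subject to steady state `S v = 0`, the reaction bounds,
#' and the constraint set. Biomass maximization is the special case where `c`
#' selects the biomass reaction.
#'
#' @param net A valid [flux_network()].
#' @param coefficients Named numeric vector, reaction id -> objective
#'   coefficient.
#' @param constraints A [constraint_set()].
#' @param params [algorithm_params()].
#' @param backend Solver backend (see [solve_lp()]).
#' @return A [flux_distribution()]; status `INFEASIBLE` or `UNBOUNDED` is a
#'   first-class outcome, not an error.
#' @export
fba_maximize <- function(net, coefficients, constraints = constraint_set(),
                         params = algorithm_params(),
                         backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  unknown <- setdiff(names(coefficients), net$reactions$id)
  if (length(unknown))
    stop("objective references unknown reactions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  eb <- effective_bounds(net, constraints)
  if (eb$conflict) return(flux_distribution("INFEASIBLE"))
  b <- new_lp_builder("max")
  add_flux_system(b, net, eb)
  lp_set_objective(b, stats::setNames(unname(coefficients),
                                      vn("v", names(coefficients))))
  sol <- solve_lp(lp_finalize(b), backend)
  extract_solution(sol, net)
}

#' Weighted flux minimization
#'
#' Among all steady-state flux vectors meeting the constraint set (typically
#' target demands on exchange rates), finds the one minimizing the weighted
#' sum of absolute fluxes `sum_i w_i |v_i|`, with the weights taken from the
#' reactions' `weight` column (optionally overridden). Absolute values are
#' linearized by splitting `v = p - n` with `p, n >= 0`.
#'
#' An INFEASIBLE status is the producibility-test outcome ("can the network
#' perform this function at all?"), not an error.
#'
#' @inheritParams fba_maximize
#' @param weights Optional named numeric vector overriding reaction weights.
#' @return A [flux_distribution()]; `objective_value` is the weighted flux sum.
#' @export
flux_minimization <- function(net, constraints = constraint_set(),
                              params = algorithm_params(), weights = NULL,
                              backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  eb <- effective_bounds(net, constraints)
  if (eb$conflict) return(flux_distribution("INFEASIBLE"))
  w <- stats::setNames(net$reactions$weight, net$reactions$id)
  if (!is.null(weights)) w[names(weights)] <- weights
  b <- new_lp_builder("min")
  add_flux_system(b, net, eb)
  add_split_vars(b, net, eb)
  ids <- net$reactions$id
  obj <- stats::setNames(rep(unname(w[ids]), each = 2),
                         as.vector(rbind(vn("p", ids), vn("n", ids))))
  lp_set_objective(b, obj)
  sol <- solve_lp(lp_finalize(b), backend)
  extract_solution(sol, net)
}

#' Minimization of metabolic adjustment (L1 MOMA)
#'
#' Finds the feasible flux vector closest (in L1 distance) to a reference
#' (wild-type) distribution, subject to the constraint set — typically a
#' knockout. The original method uses a quadratic distance; the L1 variant
#' keeps the problem linear so that any LP backend applies.
#'
#' @inheritParams fba_maximize
#' @param reference A [flux_distribution()] or named numeric vector of
#'   reference fluxes; reactions not named are taken as 0.
#' @return A [flux_distribution()]; `objective_value` is the L1 distance to
#'   the reference.
#' @export
moma_l1 <- function(net, reference, constraints = constraint_set(),
                    params = algorithm_params(),
                    backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  ref <- as_reference_vector(net, reference)
  eb <- effective_bounds(net, constraints)
  if (eb$conflict) return(flux_distribution("INFEASIBLE"))
  b <- new_lp_builder("min")
  add_flux_system(b, net, eb)
  add_split_vars(b, net, eb, center = ref)
  ids <- net$reactions$id
  obj <- stats::setNames(rep(1, 2 * length(ids)),
                         as.vector(rbind(vn("p", ids), vn("n", ids))))
  lp_set_objective(b, obj)
  sol <- solve_lp(lp_finalize(b), backend)
  extract_solution(sol, net)
}

#' Regulatory on/off minimization (ROOM)
#'
#' MILP minimizing the number of reactions whose flux leaves the tolerance
#' window `[v_ref - d_i, v_ref + d_i]` around the reference, with
#' `d_i = room_delta * |v_ref,i| + room_epsilon`. A binary `y_i = 0` pins the
#' flux inside its window; `y_i = 1` relaxes it to the reaction bounds through
#' a big-M derived per reaction from its finite bounds.
#'
#' @inheritParams moma_l1
#' @return A [flux_distribution()]; `objective_value` is the number of
#'   significantly changed fluxes.
#' @export
room <- function(net, reference, constraints = constraint_set(),
                 params = algorithm_params(),
                 backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  ref <- as_reference_vector(net, reference)
  eb <- effective_bounds(net, constraints)
  if (eb$conflict) return(flux_distribution("INFEASIBLE"))
  b <- new_lp_builder("min")
  add_flux_system(b, net, eb)
  ids <- net$reactions$id
  for (id in ids) {
    d <- params$room_delta * abs(ref[[id]]) + params$room_epsilon
    # per-side big-M: distance from the window edge to the bound, so y = 1
    # relaxes exactly to the reaction bounds even when the reference lies
    # outside them (e.g. after a knockout)
    mu <- max(0, eb$ub[[id]] - (ref[[id]] + d))
    ml <- max(0, (ref[[id]] - d) - eb$lb[[id]])
    lp_add_var(b, vn("y", id), 0, 1, "binary")
    lp_add_con(b, vn("roomu", id),
               stats::setNames(c(1, -mu), c(vn("v", id), vn("y", id))),
               "<=", ref[[id]] + d)
    lp_add_con(b, vn("rooml", id),
               stats::setNames(c(1, ml), c(vn("v", id), vn("y", id))),
               ">=", ref[[id]] - d)
  }
  lp_set_objective(b, stats::setNames(rep(1, length(ids)), vn("y", ids)))
  sol <- solve_lp(lp_finalize(b), backend)
  out <- extract_solution(sol, net)
  if (out$status == "OPTIMAL")
    out$objective_value <- round(sol$objective)
  out
}

#' Fitness maximization under partial enzyme inhibition
#'
#' Models enzymopathies: each inhibited reaction's capacity is scaled to
#' `|v_i| <= alpha_i * cap_i` (cap = magnitude of its normal bound), and the
#' achievable fraction of a set of reference target rates is maximized.
#' Each target k contributes an auxiliary satisfaction `f_k` in `[0, 1]` with
#' `f_k <= v_k / ref_k`; the fitness is `F = sum_k weight_k f_k` with weights
#' normalized to sum 1, so `F` lies in `[0, 1]` (1 = all target functions at
#' full reference rate).
#'
#' @inheritParams fba_maximize
#' @param targets Named list, reaction id -> `c(weight, ref)` with `ref != 0`.
#' @param inhibitions Named numeric vector, reaction id -> alpha in `[0, 1]`.
#' @return A [flux_distribution()]; `objective_value` is the fitness F.
#' @export
fitness_maximization <- function(net, targets, inhibitions = numeric(),
                                 constraints = constraint_set(),
                                 params = algorithm_params(),
                                 backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  if (!length(targets)) stop("at least one target is required", call. = FALSE)
  tw <- vapply(targets, `[[`, numeric(1), 1)
  tr <- vapply(targets, `[[`, numeric(1), 2)
  if (any(tr == 0)) stop("target reference rates must be nonzero",
                         call. = FALSE)
  if (any(tw < 0)) stop("target weights must be nonnegative", call. = FALSE)
  if (length(inhibitions) && (any(inhibitions < 0) || any(inhibitions > 1)))
    stop("inhibition factors must lie in [0, 1]", call. = FALSE)
  tw <- tw / sum(tw)
  constraints$inhibitions <- c(constraints$inhibitions, inhibitions)
  eb <- effective_bounds(net, constraints)
  if (eb$conflict) return(flux_distribution("INFEASIBLE"))
  b <- new_lp_builder("max")
  add_flux_system(b, net, eb)
  for (id in names(targets)) {
    lp_add_var(b, vn("f", id), 0, 1)
    r <- tr[[id]]
    # f <= v / r, linearized sign-aware: r > 0 : r f - v <= 0 ; r < 0 : r f - v >= 0
    lp_add_con(b, vn("fit", id),
               stats::setNames(c(r, -1), c(vn("f", id), vn("v", id))),
               if (r > 0) "<=" else ">=", 0)
  }
  lp_set_objective(b, stats::setNames(unname(tw), vn("f", names(targets))))
  sol <- solve_lp(lp_finalize(b), backend)
  extract_solution(sol, net)
}

#' Expression-profile matching
#'
#' Infers an active subnetwork consistent with discretized expression states.
#' Stage 1 (MILP) maximizes the agreement count A: a HIGH reaction agrees when
#' it carries flux with `|v| >= activity_eps`, a LOW reaction when
#' `|v| <= zero_tol`. Stage 2 fixes A at its optimum and minimizes the
#' weighted flux sum among agreement-optimal solutions.
#'
#' @inheritParams fba_maximize
#' @param expression_states Named character vector, reaction id -> `"HIGH"` or
#'   `"LOW"`.
#' @return List with `solution` (a [flux_distribution()], objective = stage-2
#'   weighted flux sum) and `agreement` (integer A).
#' @export
expression_match <- function(net, expression_states,
                             constraints = constraint_set(),
                             params = algorithm_params(),
                             backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  states <- toupper(expression_states)
  unknown <- setdiff(names(states), net$reactions$id)
  if (length(unknown))
    stop("expression states reference unknown reactions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(states) && !all(states %in% c("HIGH", "LOW")))
    stop("expression states must be HIGH or LOW", call. = FALSE)
  eb <- effective_bounds(net, constraints)
  if (eb$conflict)
    return(list(solution = flux_distribution("INFEASIBLE"), agreement = NA))

  build <- function(stage2 = FALSE, a_opt = NULL) {
    b <- new_lp_builder(if (stage2) "min" else "max")
    add_flux_system(b, net, eb)
    agree <- character()
    for (id in names(states)) {
      m <- eb$ub[[id]] - eb$lb[[id]] + params$activity_eps + 1
      if (states[[id]] == "HIGH") {
        lp_add_var(b, vn("yp", id), 0, 1, "binary")
        agree <- c(agree, vn("yp", id))
        if (eb$lb[[id]] >= 0) {
          # irreversible: yp = 1 forces v >= activity_eps
          lp_add_con(b, vn("hi", id),
                     stats::setNames(c(1, -m), c(vn("v", id), vn("yp", id))),
                     ">=", params$activity_eps - m)
        } else {
          # direction binary s: s = 1 means agreement via forward flux
          lp_add_var(b, vn("s", id), 0, 1, "binary")
          lp_add_con(b, vn("hif", id),
                     stats::setNames(c(1, -m, -m),
                                     c(vn("v", id), vn("yp", id), vn("s", id))),
                     ">=", params$activity_eps - 2 * m)
          lp_add_con(b, vn("hib", id),
                     stats::setNames(c(1, m, -m),
                                     c(vn("v", id), vn("yp", id), vn("s", id))),
                     "<=", -params$activity_eps + m)
        }
      } else {
        lp_add_var(b, vn("yn", id), 0, 1, "binary")
        agree <- c(agree, vn("yn", id))
        lp_add_con(b, vn("lou", id),
                   stats::setNames(c(1, m), c(vn("v", id), vn("yn", id))),
                   "<=", params$zero_tol + m)
        lp_add_con(b, vn("lol", id),
                   stats::setNames(c(1, -m), c(vn("v", id), vn("yn", id))),
                   ">=", -params$zero_tol - m)
      }
    }
    if (stage2) {
      if (length(agree))
        lp_add_con(b, "agreement", stats::setNames(rep(1, length(agree)), agree),
                   ">=", a_opt - 1e-6)
      add_split_vars(b, net, eb)
      ids <- net$reactions$id
      w <- stats::setNames(net$reactions$weight, ids)
      lp_set_objective(b, stats::setNames(
        rep(unname(w[ids]), each = 2),
        as.vector(rbind(vn("p", ids), vn("n", ids)))))
    } else {
      lp_set_objective(b, stats::setNames(rep(1, length(agree)), agree))
    }
    b
  }

  if (!length(states)) {
    sol <- flux_minimization(net, constraints, params, backend = backend)
    return(list(solution = sol, agreement = 0L))
  }
  sol1 <- solve_lp(lp_finalize(build()), backend)
  if (sol1$status != "OPTIMAL")
    return(list(solution = flux_distribution(sol1$status), agreement = NA))
  a_opt <- round(sol1$objective)
  sol2 <- solve_lp(lp_finalize(build(stage2 = TRUE, a_opt = a_opt)), backend)
  list(solution = extract_solution(sol2, net), agreement = as.integer(a_opt))
}

#' Metabolic flux analysis fit
#'
#' Fits a complete steady-state flux distribution to a set of measured rates
#' by minimizing the weighted L1 residual `sum_k w_k |v_k - measured_k|`.
#'
#' @inheritParams fba_maximize
#' @param measurements Named list, reaction id -> `c(value, weight)`.
#' @return A [flux_distribution()]; `objective_value` is the residual.
#' @export
mfa_fit <- function(net, measurements, constraints = constraint_set(),
                    params = algorithm_params(),
                    backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  if (!length(measurements))
    stop("at least one measurement is required", call. = FALSE)
  unknown <- setdiff(names(measurements), net$reactions$id)
  if (length(unknown))
    stop("measurements reference unknown reactions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  mv <- vapply(measurements, `[[`, numeric(1), 1)
  mw <- vapply(measurements, `[[`, numeric(1), 2)
  eb <- effective_bounds(net, constraints)
  if (eb$conflict) return(flux_distribution("INFEASIBLE"))
  b <- new_lp_builder("min")
  add_flux_system(b, net, eb)
  for (id in names(measurements)) {
    span <- eb$ub[[id]] - eb$lb[[id]] + abs(mv[[id]])
    lp_add_var(b, vn("dp", id), 0, span)
    lp_add_var(b, vn("dn", id), 0, span)
    lp_add_con(b, vn("meas", id),
               stats::setNames(c(1, -1, 1),
                               c(vn("v", id), vn("dp", id), vn("dn", id))),
               "=", mv[[id]])
  }
  lp_set_objective(b, stats::setNames(
    rep(unname(mw), each = 2),
    as.vector(rbind(vn("dp", names(measurements)),
                    vn("dn", names(measurements))))))
  sol <- solve_lp(lp_finalize(b), backend)
  extract_solution(sol, net)
}
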