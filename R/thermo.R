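# Concentration-based thermodynamic feasibility. A reaction may only carry
# flux in a direction along which its actual Gibbs energy
#   dG'_r = dG0'_r + RT * sum_m n_{m,r} ln(c_m)
# is strictly negative for some admissible concentration vector. Realized as
# a MILP: per-metabolite ln-concentration variables, per-internal-reaction
# direction binaries, big-M couplings. With all dG0' = 0 this is exactly the
# loop law — no internal directed cycle can carry flux.

thermo_lnc_bounds <- function(thermo, met) {
  b <- thermo$lnc_bounds[[met]]
  if (is.null(b)) thermo$default_lnc else b
}

thermo_dg0 <- function(thermo, rxn) {
  v <- thermo$dg0[rxn]
  ifelse(is.na(v), 0, unname(v))
}

# Adds lnc variables and the direction/energy couplings to a builder that
# already carries the flux system. Returns the metabolite ids holding lnc
# variables. Exchange reactions are exempt: boundary reactions have no
# defined reaction Gibbs energy in an open system.
add_thermo_system <- function(b, net, eb, thermo, params) {
  internal_mets <- net$metabolites$id[!net$metabolites$boundary]
  for (m in internal_mets) {
    lb <- thermo_lnc_bounds(thermo, m)
    lp_add_var(b, vn("lnc", m), lb[1], lb[2])
  }
  rxns <- net$reactions
  for (i in which(!rxns$exchange)) {
    id <- rxns$id[i]
    s <- net$stoichiometry[[id]]
    s <- s[names(s) %in% internal_mets]
    dg0 <- thermo_dg0(thermo, id)
    mv <- max(abs(eb$lb[[id]]), abs(eb$ub[[id]]), 1)
    mg <- thermo$big_m_G
    lp_add_var(b, vn("tp", id), 0, 1, "binary")
    lp_add_var(b, vn("tn", id), 0, 1, "binary")
    # flux couplings: v > zero_tol forces tp = 1; v < -zero_tol forces tn = 1
    lp_add_con(b, vn("tfu", id),
               stats::setNames(c(1, -mv), c(vn("v", id), vn("tp", id))),
               "<=", params$zero_tol)
    lp_add_con(b, vn("tfl", id),
               stats::setNames(c(1, mv), c(vn("v", id), vn("tn", id))),
               ">=", -params$zero_tol)
    if (length(s)) {
      en <- stats::setNames(thermo$rt * unname(s), vn("lnc", names(s)))
      # tp = 1 forces dG' <= -margin ; tn = 1 forces dG' >= +margin
      lp_add_con(b, vn("teu", id),
                 c(en, stats::setNames(mg, vn("tp", id))),
                 "<=", mg - thermo$margin - dg0)
      lp_add_con(b, vn("tel", id),
                 c(en, stats::setNames(-mg, vn("tn", id))),
                 ">=", thermo$margin - mg - dg0)
    }
  }
  internal_mets
}

#' Flux-balance analysis under the thermodynamic feasibility constraint
#'
#' Augments an LP flux-balance formulation with concentration-based
#' thermodynamics (a MILP): every internal reaction carrying forward flux must
#' admit `dG' <= -margin`, every one carrying backward flux `dG' >= +margin`,
#' for a single witness vector of metabolite ln-concentrations within their
#' allowed ranges. Exchange reactions are exempt. An INFEASIBLE status means
#' no thermodynamically realizable flux distribution meets the objective and
#' constraints — a first-class result used for tests on the non-existence of
#' solutions.
#'
#' @inheritParams fba_maximize
#' @param objective Objective descriptor: `list(kind = "max_linear",
#'   coefficients = ...)`, `list(kind = "flux_min")` (the default),
#'   `list(kind = "moma_l1", reference = ...)`, or `list(kind = "mfa_fit",
#'   measurements = ...)`.
#' @param thermo A [thermo_config()].
#' @return A [flux_distribution()] whose `log_concentrations` component holds
#'   the witness ln-concentration vector when OPTIMAL.
#' @export
compute_fba_t_c <- function(net, objective = list(kind = "flux_min"),
                            constraints = constraint_set(),
                            thermo = thermo_config(),
                            params = algorithm_params(),
                            backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  eb <- effective_bounds(net, constraints)
  if (eb$conflict) return(flux_distribution("INFEASIBLE"))
  kind <- match.arg(objective$kind,
                    c("flux_min", "max_linear", "moma_l1", "mfa_fit"))
  ids <- net$reactions$id
  b <- new_lp_builder(if (kind == "max_linear") "max" else "min")
  add_flux_system(b, net, eb)
  if (kind == "max_linear") {
    co <- objective$coefficients
    unknown <- setdiff(names(co), ids)
    if (length(unknown))
      stop("objective references unknown reactions: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    lp_set_objective(b, stats::setNames(unname(co), vn("v", names(co))))
  } else if (kind == "flux_min") {
    add_split_vars(b, net, eb)
    w <- stats::setNames(net$reactions$weight, ids)
    lp_set_objective(b, stats::setNames(
      rep(unname(w[ids]), each = 2),
      as.vector(rbind(vn("p", ids), vn("n", ids)))))
  } else if (kind == "moma_l1") {
    ref <- as_reference_vector(net, objective$reference)
    add_split_vars(b, net, eb, center = ref)
    lp_set_objective(b, stats::setNames(
      rep(1, 2 * length(ids)),
      as.vector(rbind(vn("p", ids), vn("n", ids)))))
  } else {
    ms <- objective$measurements
    if (!length(ms)) stop("mfa_fit objective needs measurements",
                          call. = FALSE)
    for (id in names(ms)) {
      span <- eb$ub[[id]] - eb$lb[[id]] + abs(ms[[id]][1])
      lp_add_var(b, vn("dp", id), 0, span)
      lp_add_var(b, vn("dn", id), 0, span)
      lp_add_con(b, vn("meas", id),
                 stats::setNames(c(1, -1, 1),
                                 c(vn("v", id), vn("dp", id), vn("dn", id))),
                 "=", ms[[id]][1])
    }
    lp_set_objective(b, stats::setNames(
      rep(vapply(ms, `[[`, numeric(1), 2), each = 2),
      as.vector(rbind(vn("dp", names(ms)), vn("dn", names(ms))))))
  }
  lnc_mets <- add_thermo_system(b, net, eb, thermo, params)
  sol <- solve_lp(lp_finalize(b), backend)
  extract_solution(sol, net, lnc_mets = lnc_mets)
}

#' Independent verification of a computed flux distribution
#'
#' Re-checks a solution from first principles, without re-using any machinery
#' of the solve that produced it: mass balance row by row, reaction bounds,
#' every element of the constraint set, and — if a thermodynamic
#' configuration is given — whether a witness concentration vector exists for
#' the solution's flux directions (a further optimization, as a pure LP over
#' the ln-concentrations).
#'
#' @inheritParams fba_maximize
#' @param solution An OPTIMAL [flux_distribution()].
#' @param thermo Optional [thermo_config()].
#' @param tol Numerical tolerance (default 1e-6).
#' @return A data.frame with columns `item`, `pass`, `detail`; the attribute
#'   `"passed"` (also returned by `all(out$pass)`) summarizes it.
#' @export
post_check <- function(net, solution, constraints = constraint_set(),
                       thermo = NULL, params = algorithm_params(),
                       tol = 1e-6,
                       backend = getOption("fluxseries.solver", "glpk")) {
  stop_if_invalid(net)
  if (!inherits(solution, "flux_distribution") ||
      solution$status != "OPTIMAL")
    stop("post_check requires an OPTIMAL flux distribution", call. = FALSE)
  v <- solution$fluxes[net$reactions$id]
  rows <- list()
  add <- function(item, pass, detail = "")
    rows[[length(rows) + 1]] <<- data.frame(item = item, pass = pass,
                                            detail = detail,
                                            stringsAsFactors = FALSE)
  S <- stoichiometry_matrix(net)
  imbalance <- as.numeric(S %*% v)
  bad <- which(abs(imbalance) > tol)
  add("mass_balance", length(bad) == 0,
      if (length(bad)) paste("unbalanced:",
                             paste(rownames(S)[bad], collapse = ", ")) else "")
  eb <- effective_bounds(net, constraints)
  badb <- which(v < eb$lb - tol | v > eb$ub + tol)
  add("bounds_and_constraints", length(badb) == 0,
      if (length(badb)) paste("out of bounds:",
                              paste(names(v)[badb], collapse = ", ")) else "")
  if (!is.null(thermo)) {
    active_f <- names(v)[v > params$zero_tol & !net$reactions$exchange]
    active_b <- names(v)[v < -params$zero_tol & !net$reactions$exchange]
    internal_mets <- net$metabolites$id[!net$metabolites$boundary]
    b <- new_lp_builder("min")
    for (m in internal_mets) {
      lb <- thermo_lnc_bounds(thermo, m)
      lp_add_var(b, vn("lnc", m), lb[1], lb[2])
    }
    feas_con <- function(id, forward) {
      s <- net$stoichiometry[[id]]
      s <- s[names(s) %in% internal_mets]
      dg0 <- thermo_dg0(thermo, id)
      if (!length(s)) {
        # concentration-independent: feasible iff dg0 already has the sign
        ok <- if (forward) dg0 <= -thermo$margin else dg0 >= thermo$margin
        if (!ok) lp_add_con(b, vn("bad", id),
                            stats::setNames(0, vn("lnc", internal_mets[1])),
                            ">=", 1)
        return(invisible(NULL))
      }
      en <- stats::setNames(thermo$rt * unname(s), vn("lnc", names(s)))
      if (forward) lp_add_con(b, vn("tf", id), en, "<=",
                              -thermo$margin - dg0)
      else lp_add_con(b, vn("tb", id), en, ">=", thermo$margin - dg0)
    }
    for (id in active_f) feas_con(id, TRUE)
    for (id in active_b) feas_con(id, FALSE)
    if (length(internal_mets) && (length(active_f) || length(active_b))) {
      lp_set_objective(b, stats::setNames(0, vn("lnc", internal_mets[1])))
      tsol <- solve_lp(lp_finalize(b), backend)
      add("thermodynamic_feasibility", tsol$status == "OPTIMAL",
          if (tsol$status != "OPTIMAL")
            paste("no admissible concentrations for active reactions:",
                  paste(c(active_f, active_b), collapse = ", ")) else "")
    } else {
      add("thermodynamic_feasibility", TRUE, "no active internal reactions")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "passed") <- all(out$pass)
  out
}
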