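#' Algorithm parameters
#'
#' Tolerances and constants shared by the single-problem algorithms.
#'
#' @param zero_tol Fluxes with absolute value below this are treated as zero
#'   (default 1e-6).
#' @param room_delta Relative ROOM tolerance delta (default 0.03): a flux
#'   counts as unchanged while it stays within `delta * |v_ref| + epsilon` of
#'   the reference.
#' @param room_epsilon Absolute ROOM tolerance epsilon (default 0.001).
#' @param activity_eps Minimum absolute flux for a reaction to count as active
#'   in expression-profile matching (default 0.1).
#' @param fva_gamma Optimality fraction gamma in `[0, 1]` for flux variability
#'   analysis (default 1): the sweep is restricted to solutions achieving at
#'   least `gamma` times the base objective.
#' @param big_m Big-M constant for indicator couplings, chosen beyond the
#'   surrogate flux bound (default 1000 beyond it).
#' @return List of class `"algorithm_params"`.
#' @export
algorithm_params <- function(zero_tol = 1e-6, room_delta = 0.03,
                             room_epsilon = 0.001, activity_eps = 0.1,
                             fva_gamma = 1, big_m = INF_BOUND + 1000) {
  stopifnot(zero_tol >= 0, room_delta >= 0, room_epsilon >= 0,
            activity_eps >= 0, fva_gamma >= 0, fva_gamma <= 1, big_m > 0)
  structure(list(zero_tol = zero_tol, room_delta = room_delta,
                 room_epsilon = room_epsilon, activity_eps = activity_eps,
                 fva_gamma = fva_gamma, big_m = big_m),
            class = "algorithm_params")
}

#' Constraint set for a single simulation
#'
#' @param fixes Named numeric vector: reaction id -> fixed flux value.
#' @param ranges Named list: reaction id -> `c(lo, hi)` flux range (intersected
#'   with the reaction's bounds).
#' @param knockouts Character vector of reaction ids whose bounds are forced
#'   to zero.
#' @param inhibitions Named numeric vector: reaction id -> alpha in `[0, 1]`;
#'   the reaction's capacity is scaled so that `|v| <= alpha * cap`, where
#'   `cap` is the magnitude of its normal bound. Models partially inhibited
#'   enzymes (enzymopathies).
#' @return List of class `"constraint_set"`.
#' @export
constraint_set <- function(fixes = numeric(), ranges = list(),
                           knockouts = character(), inhibitions = numeric()) {
  if (length(inhibitions) &&
      (any(inhibitions < 0) || any(inhibitions > 1)))
    stop("inhibition factors must lie in [0, 1]", call. = FALSE)
  for (id in names(ranges)) {
    rg <- ranges[[id]]
    if (length(rg) != 2 || rg[1] > rg[2])
      stop(sprintf("range for '%s' must be c(lo, hi) with lo <= hi", id),
           call. = FALSE)
  }
  structure(list(fixes = fixes, ranges = ranges,
                 knockouts = as.character(knockouts),
                 inhibitions = inhibitions),
            class = "constraint_set")
}

check_constraint_refs <- function(net, constraints) {
  ids <- unique(c(names(constraints$fixes), names(constraints$ranges),
                  constraints$knockouts, names(constraints$inhibitions)))
  unknown <- setdiff(ids, net$reactions$id)
  if (length(unknown))
    stop("constraints reference unknown reactions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Thermodynamic configuration
#'
#' Data for the concentration-based thermodynamic feasibility constraint. A
#' reaction may only carry forward flux if its actual Gibbs energy
#' `dG' = dG0' + RT * sum(n_m * ln c_m)` can be made strictly negative for
#' some metabolite concentrations within the allowed ranges (and symmetrically
#' for backward flux). With all `dG0' = 0` the constraint reduces to the
#' loop law: no internal directed cycle can carry flux.
#'
#' @param rt RT in kJ/mol (default 2.577, i.e. R * 310 K, body temperature).
#' @param dg0 Named numeric vector: reaction id -> standard transformed Gibbs
#'   energy dG0' in kJ/mol. Reactions without an entry default to 0
#'   (loop-law-only mode).
#' @param lnc_bounds Named list: metabolite id -> `c(ln c_min, ln c_max)`,
#'   natural logs of concentrations in mol/l. Metabolites without an entry use
#'   `default_lnc`.
#' @param default_lnc Default ln-concentration window,
#'   `c(log(1e-5), log(1e-2))` — 10 uM to 10 mM, a typical physiological span.
#' @param margin Strict-inequality surrogate epsilon_G > 0 in kJ/mol
#'   (default 1e-3): active reactions must achieve `dG' <= -margin`.
#' @param big_m_G Big-M for the energy indicator couplings in kJ/mol
#'   (default 1e4).
#' @return List of class `"thermo_config"`.
#' @export
thermo_config <- function(rt = 2.577, dg0 = numeric(), lnc_bounds = list(),
                          default_lnc = c(log(1e-5), log(1e-2)),
                          margin = 1e-3, big_m_G = 1e4) {
  stopifnot(rt > 0, margin > 0, big_m_G > 0,
            length(default_lnc) == 2, default_lnc[1] <= default_lnc[2])
  for (id in names(lnc_bounds)) {
    b <- lnc_bounds[[id]]
    if (length(b) != 2 || b[1] > b[2])
      stop(sprintf("lnc bounds for '%s' must be c(lo, hi) with lo <= hi", id),
           call. = FALSE)
  }
  structure(list(rt = rt, dg0 = dg0, lnc_bounds = lnc_bounds,
                 default_lnc = default_lnc, margin = margin,
                 big_m_G = big_m_G),
            class = "thermo_config")
}
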