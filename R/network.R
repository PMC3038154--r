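# Surrogate for a missing/infinite flux bound. Big-M formulations (ROOM,
# expression matching, thermodynamics) need every bound finite.
INF_BOUND <- 1e5

#' Define a reaction
#'
#' A reaction is a signed stoichiometry over metabolite ids (negative =
#' substrate, positive = product) together with flux bounds, a reversibility
#' flag, and a nonnegative weight used by weighted flux minimization.
#'
#' @param id Unique reaction identifier (nonempty string).
#' @param stoich Named numeric vector, metabolite id -> signed coefficient.
#'   Zero coefficients are not allowed.
#' @param lb,ub Flux bounds. Defaults: `[0, 1e5]` for irreversible reactions,
#'   `[-1e5, 1e5]` for reversible ones. Units are arbitrary but must be
#'   consistent across the network.
#' @param reversible Logical; when `NULL`, inferred as `lb < 0`. The flag only
#'   sets the default lower-bound sign — direction is encoded purely by bounds.
#' @param name Free-text name; defaults to `id`.
#' @param weight Nonnegative flux-minimization weight (default 1).
#' @param exchange Logical or `NULL`; when `NULL` it is inferred when the
#'   reaction is placed into a network (a reaction is an exchange iff it
#'   involves a boundary metabolite or all its coefficients share one sign).
#' @return An object of class `"flux_reaction"`.
#' @export
reaction <- function(id, stoich, lb = NULL, ub = NULL, reversible = NULL,
                     name = id, weight = 1, exchange = NULL) {
  if (is.null(reversible)) reversible <- if (is.null(lb)) FALSE else lb < 0
  if (is.null(lb)) lb <- if (reversible) -INF_BOUND else 0
  if (is.null(ub)) ub <- INF_BOUND
  structure(list(id = as.character(id), name = as.character(name),
                 stoich = stoich, lb = as.numeric(lb), ub = as.numeric(ub),
                 reversible = isTRUE(reversible), weight = as.numeric(weight),
                 exchange = exchange),
            class = "flux_reaction")
}

#' Define a metabolite table
#'
#' @param id Character vector of unique metabolite ids.
#' @param name Free-text names (default `id`).
#' @param compartment Compartment tokens (default `"default"`).
#' @param boundary Logical; boundary metabolites are exempt from mass balance.
#' @return A data.frame with one row per metabolite.
#' @export
metabolites <- function(id, name = id, compartment = "default",
                        boundary = FALSE) {
  data.frame(id = as.character(id), name = as.character(name),
             compartment = rep_len(as.character(compartment), length(id)),
             boundary = rep_len(as.logical(boundary), length(id)),
             stringsAsFactors = FALSE)
}

#' Assemble a stoichiometric network
#'
#' Builds the constraint system S v = 0, lb <= v <= ub from a metabolite table
#' and a list of [reaction()] objects. Iteration order is insertion order
#' everywhere, so downstream solver files and reports are reproducible
#' byte-for-byte.
#'
#' @param mets Metabolite table as returned by [metabolites()].
#' @param reactions List of [reaction()] objects.
#' @return An object of class `"flux_network"` with components `metabolites`
#'   (data.frame), `reactions` (data.frame with columns id, name, lb, ub,
#'   reversible, weight, exchange) and `stoichiometry` (named list of named
#'   numeric vectors, one per reaction).
#' @export
flux_network <- function(mets, reactions = list()) {
  stopifnot(is.data.frame(mets),
            all(c("id", "compartment", "boundary") %in% names(mets)))
  if (!"name" %in% names(mets)) mets$name <- mets$id
  mets <- mets[, c("id", "name", "compartment", "boundary")]
  if (inherits(reactions, "flux_reaction")) reactions <- list(reactions)
  bnd <- mets$id[mets$boundary]
  stoich <- list()
  rows <- vector("list", length(reactions))
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    stopifnot(inherits(r, "flux_reaction"))
    ex <- r$exchange
    if (is.null(ex)) {
      s <- r$stoich
      ex <- any(names(s) %in% bnd) || all(s > 0) || all(s < 0)
    }
    rows[[i]] <- data.frame(id = r$id, name = r$name, lb = r$lb, ub = r$ub,
                            reversible = r$reversible, weight = r$weight,
                            exchange = ex, stringsAsFactors = FALSE)
    stoich[[r$id]] <- r$stoich
  }
  rxns <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), name = character(), lb = numeric(),
               ub = numeric(), reversible = logical(), weight = numeric(),
               exchange = logical(), stringsAsFactors = FALSE)
  rownames(rxns) <- NULL
  structure(list(metabolites = mets, reactions = rxns, stoichiometry = stoich),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network> %d metabolites (%d boundary), %d reactions (%d exchange)\n",
              nrow(x$metabolites), sum(x$metabolites$boundary),
              nrow(x$reactions), sum(x$reactions$exchange)))
  invisible(x)
}

#' Validate a network against its structural invariants
#'
#' Checks id uniqueness and nonemptiness, compartment presence, bound ordering,
#' reversibility/bound consistency, nonnegative weights, nonempty stoichiometries
#' without zero coefficients, and that every referenced metabolite exists.
#' Violations are returned as data, not raised as errors.
#'
#' @param net A [flux_network()].
#' @return Character vector of human-readable violation descriptions; empty
#'   when the network is well-formed.
#' @export
validate_network <- function(net) {
  v <- character()
  m <- net$metabolites; r <- net$reactions
  if (any(!nzchar(m$id))) v <- c(v, "metabolite with empty id")
  d <- m$id[duplicated(m$id)]
  for (id in unique(d)) v <- c(v, sprintf("duplicate metabolite id '%s'", id))
  bad <- m$id[!nzchar(m$compartment)]
  for (id in bad) v <- c(v, sprintf("metabolite '%s': empty compartment", id))
  if (any(!nzchar(r$id))) v <- c(v, "reaction with empty id")
  d <- r$id[duplicated(r$id)]
  for (id in unique(d)) v <- c(v, sprintf("duplicate reaction id '%s'", id))
  for (i in seq_len(nrow(r))) {
    id <- r$id[i]
    if (r$lb[i] > r$ub[i])
      v <- c(v, sprintf("reaction '%s': lower bound %g exceeds upper bound %g",
                        id, r$lb[i], r$ub[i]))
    if (!r$reversible[i] && r$lb[i] < 0)
      v <- c(v, sprintf("reaction '%s': irreversible but lower bound %g < 0",
                        id, r$lb[i]))
    if (r$weight[i] < 0)
      v <- c(v, sprintf("reaction '%s': negative weight %g", id, r$weight[i]))
    s <- net$stoichiometry[[id]]
    if (length(s) == 0)
      v <- c(v, sprintf("reaction '%s': empty stoichiometry", id))
    if (any(s == 0))
      v <- c(v, sprintf("reaction '%s': zero stoichiometric coefficient", id))
    unknown <- setdiff(names(s), m$id)
    for (u in unknown)
      v <- c(v, sprintf("reaction '%s': unknown metabolite '%s'", id, u))
  }
  v
}

stop_if_invalid <- function(net) {
  v <- validate_network(net)
  if (length(v))
    stop("invalid network: ", paste(v, collapse = "; "), call. = FALSE)
  invisible(net)
}

#' Stoichiometric matrix
#'
#' Sparse matrix S with one row per non-boundary metabolite and one column per
#' reaction, in network order. Entry (m, r) is the signed coefficient of m in
#' r, 0 if m does not participate. Boundary metabolites are excluded because
#' they are exempt from mass balance.
#'
#' @param net A valid [flux_network()].
#' @return A `Matrix::sparseMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometry_matrix <- function(net) {
  stop_if_invalid(net)
  mets <- net$metabolites$id[!net$metabolites$boundary]
  rxns <- net$reactions$id
  ii <- integer(); jj <- integer(); xx <- numeric()
  midx <- stats::setNames(seq_along(mets), mets)
  for (j in seq_along(rxns)) {
    s <- net$stoichiometry[[rxns[j]]]
    keep <- names(s) %in% mets
    if (any(keep)) {
      ii <- c(ii, midx[names(s)[keep]])
      jj <- c(jj, rep(j, sum(keep)))
      xx <- c(xx, unname(s[keep]))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Close the system boundary
#'
#' Returns a copy of the network in which exchange reactions are closed: with
#' `mode = "all"` both directions are blocked (bounds `[0, 0]`); with
#' `mode = "uptake"` only the direction importing matter into the system is
#' blocked. Used by leak analysis, which asks what is producible from nothing.
#'
#' @param net A valid [flux_network()].
#' @param mode `"all"` or `"uptake"`.
#' @return A modified copy; the input is untouched.
#' @export
close_boundary <- function(net, mode = c("all", "uptake")) {
  mode <- match.arg(mode)
  stop_if_invalid(net)
  internal <- net$metabolites$id[!net$metabolites$boundary]
  for (i in which(net$reactions$exchange)) {
    if (mode == "all") {
      net$reactions$lb[i] <- 0
      net$reactions$ub[i] <- 0
    } else {
      s <- net$stoichiometry[[net$reactions$id[i]]]
      net_internal <- sum(s[names(s) %in% internal])
      if (net_internal > 0) {          # forward flux imports matter
        net$reactions$ub[i] <- min(net$reactions$ub[i], 0)
        net$reactions$reversible[i] <- TRUE  # lb may still be < 0
      } else if (net_internal < 0) {   # backward flux imports matter
        net$reactions$lb[i] <- max(net$reactions$lb[i], 0)
      }
    }
  }
  net
}

#' Add a sink (drain) reaction for one metabolite
#'
#' Appends an irreversible reaction `SINK_<metabolite-id>` consuming one unit
#' of the metabolite with bounds `[0, 1e5]`. Used as a producibility probe by
#' leak analysis.
#'
#' @param net A valid [flux_network()].
#' @param met Metabolite id; must exist, must not be a boundary metabolite.
#' @return List with components `net` (the extended copy) and `sink_id`.
#' @export
add_sink <- function(net, met) {
  stop_if_invalid(net)
  row <- match(met, net$metabolites$id)
  if (is.na(row)) stop(sprintf("unknown metabolite '%s'", met), call. = FALSE)
  if (net$metabolites$boundary[row])
    stop(sprintf("metabolite '%s' is a boundary metabolite; a sink probe is meaningless", met),
         call. = FALSE)
  sink_id <- paste0("SINK_", met)
  if (sink_id %in% net$reactions$id)
    stop(sprintf("sink '%s' already present", sink_id), call. = FALSE)
  net$reactions <- rbind(net$reactions, data.frame(
    id = sink_id, name = sink_id, lb = 0, ub = INF_BOUND, reversible = FALSE,
    weight = 1, exchange = TRUE, stringsAsFactors = FALSE))
  net$stoichiometry[[sink_id]] <- stats::setNames(-1, met)
  list(net = net, sink_id = sink_id)
}

#' A solved flux distribution
#'
#' @param status One of `"OPTIMAL"`, `"INFEASIBLE"`, `"UNBOUNDED"`.
#' @param fluxes Named numeric vector, reaction id -> flux; empty unless
#'   `status == "OPTIMAL"`.
#' @param objective_value Objective value of the solve (NA if not optimal).
#' @param log_concentrations Optional named numeric vector of ln-concentration
#'   witnesses (thermodynamic solves only).
#' @return Object of class `"flux_distribution"`.
#' @export
flux_distribution <- function(status, fluxes = numeric(),
                              objective_value = NA_real_,
                              log_concentrations = NULL) {
  stopifnot(status %in% c("OPTIMAL", "INFEASIBLE", "UNBOUNDED"))
  if (status != "OPTIMAL") fluxes <- numeric()
  structure(list(status = status, fluxes = fluxes,
                 objective_value = objective_value,
                 log_concentrations = log_concentrations),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status %s, objective %s, %d fluxes\n",
              x$status, format(x$objective_value), length(x$fluxes)))
  invisible(x)
}
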