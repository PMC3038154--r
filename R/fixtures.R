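# Deterministic synthetic networks exercising every algorithm without any
# model download. Ids and bounds are fixed; random networks are
# seed-deterministic.

#' Linear chain fixture
#'
#' `EX_A` imports M1, `R1..R(n-1)` convert `Mi -> Mi+1`, `EX_Z` drains `Mn`.
#' All bounds `[0, 10]`, unit weights. For n = 3 the metabolites are named
#' A, B, C for readability.
#'
#' @param n Number of metabolites (>= 1).
#' @return A [flux_network()] with `n + 1` reactions.
#' @export
make_chain <- function(n = 3) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  ids <- if (n <= 26) LETTERS[seq_len(n)] else paste0("M", seq_len(n))
  mets <- metabolites(ids, compartment = "c")
  rxns <- list(reaction("EX_A", stats::setNames(1, ids[1]), lb = 0, ub = 10))
  if (n > 1)
    for (i in seq_len(n - 1))
      rxns <- c(rxns, list(reaction(
        paste0("R", i),
        stats::setNames(c(-1, 1), ids[c(i, i + 1)]), lb = 0, ub = 10)))
  rxns <- c(rxns, list(reaction("EX_Z", stats::setNames(-1, ids[n]),
                                lb = 0, ub = 10)))
  flux_network(mets, rxns)
}

#' Parallel-pathway fixture
#'
#' Two routes from A to B: directly via `R1`, or in two steps via `R2a`
#' (A -> X) and `R2b` (X -> B). Flux minimization with a unit demand on
#' `EX_B` must pick the one-step route (total flux 3 versus 4) unless `R1`
#' is penalized.
#'
#' @return A [flux_network()] with 5 reactions.
#' @export
make_parallel <- function() {
  mets <- metabolites(c("A", "B", "X"), compartment = "c")
  flux_network(mets, list(
    reaction("EX_A", c(A = 1), lb = 0, ub = 10),
    reaction("R1", c(A = -1, B = 1), lb = 0, ub = 10),
    reaction("R2a", c(A = -1, X = 1), lb = 0, ub = 10),
    reaction("R2b", c(X = -1, B = 1), lb = 0, ub = 10),
    reaction("EX_B", c(B = -1), lb = 0, ub = 10)))
}

#' Directed three-cycle fixture
#'
#' `R1: A -> B`, `R2: B -> C`, `R3: C -> A`, all bounds `[0, 10]`, no
#' exchange reactions. Under plain FBA the cycle can carry any flux in
#' `[0, 10]` (the null space of S contains (1,1,1)); under the thermodynamic
#' constraint only zero flux is admissible — the loop law.
#'
#' @return A [flux_network()] with 3 reactions.
#' @export
make_loop <- function() {
  mets <- metabolites(c("A", "B", "C"), compartment = "c")
  flux_network(mets, list(
    reaction("R1", c(A = -1, B = 1), lb = 0, ub = 10),
    reaction("R2", c(B = -1, C = 1), lb = 0, ub = 10),
    reaction("R3", c(C = -1, A = 1), lb = 0, ub = 10)))
}

#' Leaky fixture
#'
#' The 3-chain plus a mass-creating reaction `R_bad: A -> 2 A`. With all
#' exchanges closed, cycling `R_bad` produces A (and everything downstream)
#' from nothing — the signature of a stoichiometric inconsistency.
#'
#' @return A [flux_network()] with 5 reactions.
#' @export
make_leaky <- function() {
  net <- make_chain(3)
  net$reactions <- rbind(net$reactions, data.frame(
    id = "R_bad", name = "R_bad", lb = 0, ub = 10, reversible = FALSE,
    weight = 1, exchange = FALSE, stringsAsFactors = FALSE))
  net$stoichiometry[["R_bad"]] <- c(A = 1)  # net: A -> 2 A
  net
}

#' Seed-deterministic random sparse network
#'
#' Test bed for oracle-equivalence checks: small networks with coefficients
#' in {-2, -1, 1, 2}, about 20% exchange reactions (one-sided stoichiometry),
#' and bounds `[-2, 2]` (reversible) or `[0, 2]`. Such networks may be
#' infeasible or unbounded for some objectives — status handling is itself
#' under test, so callers filter by status rather than by construction.
#'
#' @param n_mets,n_rxns Network size.
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A [flux_network()].
#' @export
make_random_network <- function(n_mets, n_rxns, seed) {
  set.seed(seed)
  ids <- paste0("M", seq_len(n_mets))
  mets <- metabolites(ids, compartment = "c")
  rxns <- vector("list", n_rxns)
  for (j in seq_len(n_rxns)) {
    exchange <- stats::runif(1) < 0.2
    if (exchange || n_mets == 1) {
      m <- sample(ids, 1)
      coef <- sample(c(-2, -1, 1, 2), 1)
      s <- stats::setNames(coef, m)
    } else {
      k <- if (n_mets >= 3) sample(2:3, 1) else 2
      ms <- sample(ids, k)
      nsub <- sample(seq_len(k - 1), 1)
      coefs <- sample(c(1, 2), k, replace = TRUE)
      coefs[seq_len(nsub)] <- -coefs[seq_len(nsub)]
      s <- stats::setNames(coefs, ms)
    }
    rev <- stats::runif(1) < 0.5
    rxns[[j]] <- reaction(paste0("R", j), s,
                          lb = if (rev) -2 else 0, ub = 2,
                          reversible = rev)
  }
  flux_network(mets, rxns)
}

#' Write the demo simulation file
#'
#' Emits a canonical-dialect simulation file with three specifications
#' against [make_chain()] (n = 3): a feasible production demand with checks,
#' a demand expected to be infeasible under a capped uptake, and a knockout
#' expected infeasible. Byte-deterministic.
#'
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_demo_simulations <- function(path) {
  writeLines(c(
    "# demo simulation series for the 3-chain fixture",
    "SIMULATION produce_C",
    "  COMMENT C is producible at unit rate",
    "  CONSTRAINT EX_Z = 1",
    "  EXPECT FEASIBLE",
    "  CHECK R1 > 0 and EX_Z >= 1",
    "  CHECK abs(EX_A) <= 1.5",
    "END",
    "SIMULATION overload_C",
    "  COMMENT demand beyond the uptake cap cannot be met",
    "  CONSTRAINT EX_Z in [5, 10]",
    "  CONSTRAINT EX_A in [0, 2]",
    "  EXPECT INFEASIBLE",
    "END",
    "SIMULATION ko_blocks_C",
    "  COMMENT knocking out the only route blocks production",
    "  KNOCKOUT R1",
    "  CONSTRAINT EX_Z = 1",
    "  EXPECT INFEASIBLE",
    "END"), path)
  invisible(path)
}
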