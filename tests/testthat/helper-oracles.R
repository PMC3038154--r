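# Brute-force oracles, independent of the LP machinery under test.
#
# The flux polytope P = {v : S v = 0, lb <= v <= ub} is bounded (all fixture
# bounds are finite), so its vertices are exactly the points where the rows of
# S plus a set of tight bound hyperplanes have full column rank. A convex
# piecewise-linear objective sum w_i |v_i - c_i| attains its minimum over P at
# a vertex of the arrangement of P with the kink hyperplanes v_i = c_i, so
# enumerating candidate active sets over {lb_i, ub_i, c_i} and filtering for
# feasibility yields the exact optimum by inspection.

enum_candidate_points <- function(S, lb, ub, extra = NULL, tol = 1e-7) {
  n <- length(lb)
  S <- as.matrix(S)
  rankS <- if (nrow(S)) qr(S)$rank else 0L
  k <- n - rankS
  vals <- lapply(seq_len(n), function(i)
    unique(c(lb[i], ub[i], if (!is.null(extra)) extra[[i]])))
  pts <- list()
  push <- function(v) {
    if (all(v >= lb - tol & v <= ub + tol)) pts[[length(pts) + 1]] <<- v
  }
  if (k <= 0) {
    v <- rep(0, n)  # S has full column rank: v = 0 is the only solution
    push(v)
    return(do.call(rbind, pts))
  }
  combs <- utils::combn(n, k)
  for (ci in seq_len(ncol(combs))) {
    sel <- combs[, ci, drop = TRUE]
    E <- matrix(0, k, n)
    E[cbind(seq_len(k), sel)] <- 1
    A <- rbind(S, E)
    qa <- qr(A)
    if (qa$rank < n) next  # dependent active set, no isolated point
    grid <- expand.grid(vals[sel], KEEP.OUT.ATTRS = FALSE)
    for (g in seq_len(nrow(grid))) {
      b <- c(rep(0, nrow(S)), as.numeric(grid[g, ]))
      v <- qr.coef(qa, b)
      if (max(abs(A %*% v - b)) > 1e-6) next  # inconsistent active set
      push(as.numeric(v))
    }
  }
  if (length(pts)) do.call(rbind, pts) else NULL
}

# exact minimum of sum(w * |v - center|) over the polytope; NULL if empty
oracle_min_weighted_abs <- function(S, lb, ub, w, center = rep(0, length(lb))) {
  pts <- enum_candidate_points(S, lb, ub, extra = as.list(center))
  if (is.null(pts)) return(NULL)
  min(apply(pts, 1, function(v) sum(w * abs(v - center))))
}

oracle_polytope_nonempty <- function(S, lb, ub) {
  !is.null(enum_candidate_points(S, lb, ub))
}

# exact ROOM optimum by exhausting all binary change patterns (small n only):
# y_i = 0 pins v_i into [ref - d, ref + d] intersected with the bounds
oracle_room_min_changed <- function(S, lb, ub, ref, delta, epsilon) {
  n <- length(lb)
  d <- delta * abs(ref) + epsilon
  best <- NULL
  for (count in 0:n) {
    sets <- utils::combn(n, count)
    for (ci in seq_len(ncol(sets))) {
      changed <- rep(FALSE, n)
      if (count > 0) changed[sets[, ci]] <- TRUE
      l2 <- ifelse(changed, lb, pmax(lb, ref - d))
      u2 <- ifelse(changed, ub, pmin(ub, ref + d))
      if (any(l2 > u2 + 1e-9)) next
      if (oracle_polytope_nonempty(S, l2, u2)) { best <- count; break }
    }
    if (!is.null(best)) break
  }
  best
}

# apply fixes to the bound vectors (re-done here so the oracle does not share
# the package's constraint bookkeeping)
apply_fix <- function(lb, ub, ids, fix_id, value) {
  i <- match(fix_id, ids)
  lb[i] <- value; ub[i] <- value
  list(lb = lb, ub = ub)
}

# uniform-ish samples from the polytope: random convex combinations of its
# enumerated vertices (all such points are feasible by convexity)
sample_feasible_points <- function(S, lb, ub, n_samples, seed = 1) {
  pts <- enum_candidate_points(S, lb, ub)
  if (is.null(pts)) return(NULL)
  pts <- unique(round(pts, 9))
  set.seed(seed)
  out <- matrix(0, n_samples, ncol(pts))
  for (i in seq_len(n_samples)) {
    wts <- stats::rexp(nrow(pts))
    out[i, ] <- colSums(pts * (wts / sum(wts)))
  }
  out
}

net_matrices <- function(net) {
  S <- as.matrix(stoichiometry_matrix(net))
  list(S = S, lb = net$reactions$lb, ub = net$reactions$ub,
       ids = net$reactions$id, w = net$reactions$weight)
}
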