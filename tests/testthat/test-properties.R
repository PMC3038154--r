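# Property-style checks on seeded random networks, verified against the
# brute-force polytope oracles in helper-oracles.R.

random_case <- function(seed, n_mets = 3, n_rxns = 5) {
  net <- make_random_network(n_mets, n_rxns, seed = seed)
  nm <- net_matrices(net)
  target <- nm$ids[1 + (seed %% n_rxns)]
  list(net = net, nm = nm, target = target,
       cs = constraint_set(fixes = stats::setNames(0.5, target)))
}

test_that("flux minimization matches the brute-force polytope optimum", {
  for (seed in 1:20) {
    cc <- random_case(seed)
    fx <- apply_fix(cc$nm$lb, cc$nm$ub, cc$nm$ids, cc$target, 0.5)
    orc <- oracle_min_weighted_abs(cc$nm$S, fx$lb, fx$ub, cc$nm$w)
    got <- flux_minimization(cc$net, cc$cs)
    if (is.null(orc)) {
      expect_identical(got$status, "INFEASIBLE")
    } else {
      expect_identical(got$status, "OPTIMAL")
      expect_equal(got$objective_value, orc, tolerance = 1e-5)
    }
  }
})

test_that("L1 MOMA matches the brute-force optimum around a nonzero reference", {
  for (seed in 1:15) {
    cc <- random_case(seed)
    set.seed(seed + 1000)
    ref <- stats::setNames(round(stats::runif(length(cc$nm$ids), -1, 1), 2),
                           cc$nm$ids)
    fx <- apply_fix(cc$nm$lb, cc$nm$ub, cc$nm$ids, cc$target, 0.5)
    orc <- oracle_min_weighted_abs(cc$nm$S, fx$lb, fx$ub,
                                   rep(1, length(cc$nm$ids)), unname(ref))
    got <- moma_l1(cc$net, ref, cc$cs)
    if (is.null(orc)) expect_identical(got$status, "INFEASIBLE")
    else expect_equal(got$objective_value, orc, tolerance = 1e-5)
  }
})

test_that("ROOM matches exhaustive enumeration of change patterns", {
  for (seed in 1:12) {
    cc <- random_case(seed, n_mets = 3, n_rxns = 5)
    set.seed(seed + 2000)
    ref <- stats::setNames(round(stats::runif(length(cc$nm$ids), -1, 1), 2),
                           cc$nm$ids)
    fx <- apply_fix(cc$nm$lb, cc$nm$ub, cc$nm$ids, cc$target, 0.5)
    orc <- oracle_room_min_changed(cc$nm$S, fx$lb, fx$ub, unname(ref),
                                   0.03, 0.001)
    got <- room(cc$net, ref, cc$cs)
    if (is.null(orc)) expect_identical(got$status, "INFEASIBLE")
    else expect_equal(got$objective_value, orc)
  }
})

test_that("the flux-min objective never increases when a weight decreases", {
  par <- make_parallel()
  cs <- constraint_set(fixes = c(EX_B = 1))
  base <- flux_minimization(par, cs, weights = c(R1 = 5))$objective_value
  for (w in c(3, 1, 0.5, 0)) {
    lower <- flux_minimization(par, cs, weights = c(R1 = w))$objective_value
    expect_lte(lower, base + 1e-9)
    base <- lower
  }
})

test_that("MOMA from a zero reference equals unit-weight flux minimization", {
  for (seed in 1:10) {
    cc <- random_case(seed)
    m <- moma_l1(cc$net, numeric(), cc$cs)
    f <- flux_minimization(cc$net, cc$cs,
                           weights = stats::setNames(rep(1, length(cc$nm$ids)),
                                                     cc$nm$ids))
    expect_identical(m$status, f$status)
    if (m$status == "OPTIMAL")
      expect_equal(m$objective_value, f$objective_value, tolerance = 1e-6)
  }
})

test_that("fitness is anti-monotone in the inhibition factor", {
  net <- make_chain(3)
  prev <- Inf
  for (a in c(1, 0.8, 0.05, 0.02, 0)) {
    f <- fitness_maximization(net, targets = list(EX_Z = c(1, 1)),
                              inhibitions = c(R1 = a))$objective_value
    expect_lte(f, prev + 1e-9)
    prev <- f
  }
})

test_that("FVA brackets sampled feasible points (sandwich property)", {
  for (fix in list(list(net = make_parallel(),
                        cs = constraint_set(ranges = list(EX_B = c(0, 5)))),
                   list(net = make_loop(), cs = constraint_set()))) {
    eb_lb <- fix$net$reactions$lb; eb_ub <- fix$net$reactions$ub
    for (id in names(fix$cs$ranges)) {
      i <- match(id, fix$net$reactions$id)
      eb_lb[i] <- max(eb_lb[i], fix$cs$ranges[[id]][1])
      eb_ub[i] <- min(eb_ub[i], fix$cs$ranges[[id]][2])
    }
    S <- as.matrix(stoichiometry_matrix(fix$net))
    pts <- sample_feasible_points(S, eb_lb, eb_ub, 250, seed = 99)
    res <- fva(fix$net, fix$cs)
    for (j in seq_along(res$reaction)) {
      expect_true(all(pts[, j] >= res$min[j] - 1e-6))
      expect_true(all(pts[, j] <= res$max[j] + 1e-6))
    }
  }
})

test_that("every OPTIMAL solve passes the independent post check", {
  net <- make_parallel()
  cs <- constraint_set(fixes = c(EX_B = 1))
  sols <- list(
    flux_minimization(net, cs),
    fba_maximize(net, c(EX_B = 1)),
    moma_l1(net, c(EX_A = 1, R1 = 1, EX_B = 1), cs),
    room(net, c(EX_A = 1, R1 = 1, EX_B = 1), cs),
    mfa_fit(net, list(EX_B = c(1, 1))))
  for (s in sols) {
    expect_identical(s$status, "OPTIMAL")
    fit_cs <- if (abs(s$fluxes[["EX_B"]] - 1) < 1e-9) cs else constraint_set()
    expect_true(attr(post_check(net, s, fit_cs), "passed"))
  }
  # and mass balance holds numerically for solves on random networks
  for (seed in 1:10) {
    cc <- random_case(seed)
    got <- flux_minimization(cc$net, cc$cs)
    if (got$status == "OPTIMAL") {
      S <- stoichiometry_matrix(cc$net)
      expect_lt(max(abs(as.numeric(S %*% got$fluxes[colnames(S)]))), 1e-6)
      expect_true(all(got$fluxes >= cc$nm$lb - 1e-6 &
                        got$fluxes <= cc$nm$ub + 1e-6))
    }
  }
})

test_that("pruning is sound and monotone in the spec list", {
  par <- make_parallel()
  s1 <- simulation_spec("one", constraints = constraint_set(fixes = c(EX_B = 1)))
  s2 <- simulation_spec("two", constraints = constraint_set(fixes = c(EX_B = 1),
                                                            knockouts = "R1"))
  pr1 <- prune_network(par, list(s1))
  # soundness: the spec keeps its flux-min objective on the pruned network
  full_obj <- flux_minimization(par, s1$constraints)$objective_value
  sub_obj <- flux_minimization(pr1$net, s1$constraints)$objective_value
  expect_equal(sub_obj, full_obj, tolerance = 1e-5)
  # monotonicity: adding a spec never shrinks the retained set
  pr2 <- prune_network(par, list(s1, s2))
  expect_true(all(pr1$kept %in% pr2$kept))
})

test_that("solver artifacts are byte-deterministic across repeated runs", {
  net <- make_parallel()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sol <- flux_minimization(net, constraint_set(fixes = c(EX_B = 1)))
    write_val(sol, net, file.path(d, "out.val"))
    write_flat(net, file.path(d, "model.flat"))
  }
  expect_identical(readLines(file.path(d1, "out.val")),
                   readLines(file.path(d2, "out.val")))
  expect_identical(readLines(file.path(d1, "model.flat")),
                   readLines(file.path(d2, "model.flat")))
})
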