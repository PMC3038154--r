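test_that("canonical simulation files parse block by block with line-numbered errors", {
  p <- withr::local_tempfile(lines = c(
    "# two simulations",
    "SIMULATION one",
    "  CONSTRAINT EX_Z = 1",
    "  EXPECT FEASIBLE",
    "END",
    "SIMULATION two",
    "  OBJECTIVE max EX_Z",
    "  KNOCKOUT R1 R2",
    "  INHIBIT EX_A 0.5",
    "  EXPECT INFEASIBLE",
    "END"))
  specs <- parse_simulations(p)
  expect_length(specs, 2)
  expect_identical(vapply(specs, `[[`, character(1), "sim_id"), c("one", "two"))
  expect_equal(specs[[1]]$constraints$fixes, c(EX_Z = 1))
  expect_identical(specs[[2]]$objective$kind, "max_linear")
  expect_identical(specs[[2]]$constraints$knockouts, c("R1", "R2"))
  expect_equal(specs[[2]]$constraints$inhibitions, c(EX_A = 0.5))

  missing_end <- withr::local_tempfile(lines = c("SIMULATION x",
                                                 "  EXPECT FEASIBLE"))
  expect_error(parse_simulations(missing_end), "line 1.*missing END")

  dup <- withr::local_tempfile(lines = c("SIMULATION a", "END",
                                         "SIMULATION a", "END"))
  expect_error(parse_simulations(dup), "duplicate")

  bad_check <- withr::local_tempfile(lines = c("SIMULATION a",
                                               "  CHECK R1 >", "END"))
  expect_error(parse_simulations(bad_check), "line 2")
})

test_that("the fasimu-native reader counts one spec per paragraph record", {
  p <- withr::local_tempfile(lines = c(
    "# header comment",
    "sim_alpha target: X",
    "more detail",
    "",
    "sim_beta target: Y",
    "",
    "",
    "sim_gamma"))
  specs <- parse_simulations(p, dialect = "fasimu-native")
  expect_length(specs, 3)
  expect_identical(vapply(specs, `[[`, character(1), "sim_id"),
                   c("sim_alpha", "sim_beta", "sim_gamma"))
  expect_match(specs[[1]]$comment, "more detail")
})

test_that("evaluation expressions follow standard boolean semantics", {
  net <- make_chain(3)
  sol <- flux_minimization(net, constraint_set(fixes = c(EX_Z = 1)))
  expect_true(evaluate_expression("R1 > 0", sol))
  expect_false(evaluate_expression("abs(EX_A) <= 0.5", sol))
  expect_true(evaluate_expression("R1 > 0 and EX_Z >= 1", sol))
  expect_true(evaluate_expression("(R1 > 5 or R2 <= 1) and EX_A == 1", sol))
  expect_false(evaluate_expression("R1 > 5 or R2 > 5", sol))
  expect_error(evaluate_expression("NOPE > 0", sol), "unknown reaction")
  expect_error(parse_eval_expression("R1 >"), "number")
  expect_error(parse_eval_expression("R1 5"), "comparison")
})

test_that("batch runs evaluate expectations, including expected infeasibility", {
  net <- make_chain(3)
  specs <- list(
    simulation_spec("can_make_C",
                    constraints = constraint_set(ranges = list(EX_Z = c(1, 10))),
                    checks = "EX_Z >= 1"),
    simulation_spec("cannot_overproduce",
                    constraints = constraint_set(ranges = list(EX_Z = c(100, 200),
                                                               EX_A = c(0, 10))),
                    expect = "INFEASIBLE"))
  out <- suppressMessages(run_batch(net, specs, "flux-min"))
  expect_equal(nrow(out$report), 2)
  expect_true(all(out$report$passed))
  expect_equal(attr(out$report, "summary")[["passed"]], 2)

  # an expectation that fails to hold is a FAIL row, not an error
  flipped <- specs
  flipped[[2]]$expect <- "FEASIBLE"
  out2 <- suppressMessages(run_batch(net, flipped, "flux-min"))
  expect_identical(out2$report$passed, c(TRUE, FALSE))

  empty <- suppressMessages(run_batch(net, list(), "flux-min"))
  expect_equal(nrow(empty$report), 0)
  expect_equal(attr(empty$report, "summary")[["n"]], 0)
})

test_that("batch rows survive per-simulation errors and spec-level overrides", {
  net <- make_chain(3)
  specs <- list(
    simulation_spec("max_drain", objective = list(kind = "max_linear",
                                                  coefficients = c(EX_Z = 1))),
    simulation_spec("broken", constraints = constraint_set()))
  # 'moma' without a reference errors for every row that needs it
  out <- suppressMessages(run_batch(net, specs, "moma"))
  expect_equal(nrow(out$report), 2)
  expect_true(all(out$report$status == "ERROR"))
  expect_false(any(out$report$passed))

  # the spec-level max objective overrides the flux-min default
  out2 <- suppressMessages(run_batch(net, specs[1], "flux-min"))
  expect_equal(out2$report$objective, 10)
  expect_error(suppressMessages(run_batch(net, specs, "no-such-call")),
               "should be one of")
})

test_that("batch output directory carries report, val files and combined table", {
  net <- make_chain(3)
  dir <- withr::local_tempdir()
  demo <- file.path(dir, "demo.sim")
  write_demo_simulations(demo)
  specs <- parse_simulations(demo)
  out <- suppressMessages(run_batch(net, specs, "flux-min", out_dir = dir))
  expect_true(file.exists(file.path(dir, "report.tsv")))
  expect_true(file.exists(file.path(dir, "produce_C.val")))
  rep <- utils::read.delim(file.path(dir, "report.tsv"))
  expect_identical(names(rep), c("sim_id", "status", "objective", "expected",
                                 "passed", "checks_failed"))
  comb <- utils::read.delim(file.path(dir, "solutions.tsv"))
  expect_identical(comb$reaction, net$reactions$id)
  expect_true("produce_C" %in% names(comb))
})

test_that("FVA brackets every reaction, with pathway trade-offs visible", {
  net <- make_chain(3)
  res <- fva(net, constraint_set(fixes = c(EX_Z = 1)))
  expect_equal(res$min, rep(1, 4))
  expect_equal(res$max, rep(1, 4))

  par <- make_parallel()
  res2 <- fva(par, constraint_set(fixes = c(EX_B = 1)))
  r1 <- res2[res2$reaction == "R1", ]
  expect_equal(c(r1$min, r1$max), c(0, 1))

  loop <- make_loop()
  res3 <- fva(loop)
  expect_equal(res3$min, rep(0, 3))
  expect_equal(res3$max, rep(10, 3))  # internal cycles are steady-state legal
})

test_that("FVA with a base objective restricts to near-optimal solutions", {
  par <- make_parallel()
  res <- fva(par, base_objective = c(EX_B = 1),
             params = algorithm_params(fva_gamma = 1))
  expect_equal(attr(res, "base_objective"), 10)
  ex <- res[res$reaction == "EX_B", ]
  expect_equal(c(ex$min, ex$max), c(10, 10))
  expect_error(fva(make_chain(3), constraint_set(fixes = c(EX_Z = 1), knockouts = "R1"),
                   base_objective = c(EX_Z = 1)),
               "INFEASIBLE")
})

test_that("leak analysis flags mass creation and clears balanced networks", {
  leaks <- leak_analysis(make_leaky())
  expect_identical(leaks$metabolite, c("A", "B", "C"))
  expect_true(all(leaks$rate > 0))

  expect_equal(nrow(leak_analysis(make_chain(3))), 0)
  expect_equal(nrow(leak_analysis(make_loop())), 0)
  empty <- flux_network(metabolites(character(0)), list())
  expect_equal(nrow(leak_analysis(empty)), 0)

  # removing the offending reaction heals the network
  healed <- subnetwork(make_leaky(), c("EX_A", "R1", "R2", "EX_Z"))
  expect_equal(nrow(leak_analysis(healed)), 0)
})

test_that("pruning keeps exactly the functional subnetwork", {
  net <- make_chain(3)
  net$reactions <- rbind(net$reactions, data.frame(
    id = "DEAD", name = "DEAD", lb = 0, ub = 10, reversible = FALSE,
    weight = 1, exchange = FALSE, stringsAsFactors = FALSE))
  net$metabolites <- rbind(net$metabolites, data.frame(
    id = "D", name = "D", compartment = "c", boundary = FALSE,
    stringsAsFactors = FALSE))
  net$stoichiometry[["DEAD"]] <- c(C = -1, D = 1)

  spec <- simulation_spec("produce_C",
                          constraints = constraint_set(fixes = c(EX_Z = 1)))
  pr <- prune_network(net, list(spec))
  expect_setequal(pr$kept, c("EX_A", "R1", "R2", "EX_Z"))
  expect_identical(pr$removed, "DEAD")
  expect_false("D" %in% pr$net$metabolites$id)

  # fixed point: specs covering every reaction keep the network whole
  par <- make_parallel()
  specs <- list(
    simulation_spec("via_R1",
                    constraints = constraint_set(fixes = c(EX_B = 1),
                                                 knockouts = "R2a")),
    simulation_spec("via_R2",
                    constraints = constraint_set(fixes = c(EX_B = 1),
                                                 knockouts = "R1")))
  pr2 <- prune_network(par, specs)
  expect_setequal(pr2$kept, par$reactions$id)

  expect_error(prune_network(par, list()), "at least one")
  # infeasible specs are skipped with a warning
  bad <- simulation_spec("impossible",
                         constraints = constraint_set(fixes = c(EX_B = 1),
                                                      knockouts = c("R1", "R2a")))
  expect_warning(prune_network(par, list(spec_ok = specs[[1]], bad = bad)),
                 "skipped")
})
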