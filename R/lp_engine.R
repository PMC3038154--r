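# Solver-neutral LP/MILP layer. Problems are exchanged with external solvers
# through files: a CPLEX LP file out, a solution text file back. This keeps
# every step human-readable and lets backends be swapped behind one contract.

#' Construct a linear (or mixed-integer linear) problem
#'
#' @param sense `"max"` or `"min"`.
#' @param objective Named numeric vector: variable name -> coefficient.
#' @param variables data.frame with columns `name`, `kind` ("continuous" or
#'   "binary"), `lower`, `upper`.
#' @param constraints List of constraints, each a list with `name`,
#'   `terms` (named numeric), `rel` (one of "<=", "=", ">="), `rhs`.
#' @return Object of class `"linear_problem"`.
#' @export
linear_problem <- function(sense, objective, variables, constraints = list()) {
  sense <- match.arg(sense, c("max", "min"))
  stopifnot(is.data.frame(variables),
            all(c("name", "kind", "lower", "upper") %in% names(variables)))
  if (anyDuplicated(variables$name))
    stop("duplicate variable names", call. = FALSE)
  bad <- variables$kind == "binary" &
    (variables$lower < 0 | variables$upper > 1)
  if (any(bad)) stop("binary variables must have bounds within [0, 1]",
                     call. = FALSE)
  if (any(variables$lower > variables$upper))
    stop("variable with lower bound above upper bound", call. = FALSE)
  known <- variables$name
  if (length(objective) && !all(names(objective) %in% known))
    stop("objective references undeclared variables", call. = FALSE)
  cnames <- vapply(constraints, function(cc) cc$name, character(1))
  if (anyDuplicated(cnames)) stop("duplicate constraint names", call. = FALSE)
  for (cc in constraints) {
    stopifnot(cc$rel %in% c("<=", "=", ">="), length(cc$terms) >= 1)
    if (!all(names(cc$terms) %in% known))
      stop(sprintf("constraint '%s' references undeclared variables", cc$name),
           call. = FALSE)
  }
  structure(list(sense = sense, objective = objective, variables = variables,
                 constraints = constraints),
            class = "linear_problem")
}

# Mutable builder: avoids quadratic list-append cost when formulations grow.
new_lp_builder <- function(sense = "max") {
  e <- new.env(parent = emptyenv())
  e$sense <- sense
  e$vars <- vector("list", 64L); e$nv <- 0L
  e$cons <- vector("list", 64L); e$nc <- 0L
  e$obj <- numeric()
  e
}

lp_add_var <- function(b, name, lower, upper, kind = "continuous") {
  b$nv <- b$nv + 1L
  if (b$nv > length(b$vars)) length(b$vars) <- 2L * length(b$vars)
  b$vars[[b$nv]] <- list(name = name, kind = kind,
                         lower = as.numeric(lower), upper = as.numeric(upper))
  invisible(name)
}

lp_add_con <- function(b, name, terms, rel, rhs) {
  b$nc <- b$nc + 1L
  if (b$nc > length(b$cons)) length(b$cons) <- 2L * length(b$cons)
  b$cons[[b$nc]] <- list(name = name, terms = terms, rel = rel,
                         rhs = as.numeric(rhs))
  invisible(name)
}

lp_set_objective <- function(b, terms) { b$obj <- terms; invisible(b) }

lp_finalize <- function(b) {
  vars <- b$vars[seq_len(b$nv)]
  vdf <- data.frame(
    name = vapply(vars, `[[`, character(1), "name"),
    kind = vapply(vars, `[[`, character(1), "kind"),
    lower = vapply(vars, `[[`, numeric(1), "lower"),
    upper = vapply(vars, `[[`, numeric(1), "upper"),
    stringsAsFactors = FALSE)
  linear_problem(b$sense, b$obj, vdf, b$cons[seq_len(b$nc)])
}

fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[out == "-0"] <- "0"
  out
}

lp_terms_string <- function(terms, sanitize) {
  nm <- sanitize[names(terms)]
  co <- unname(terms)
  parts <- character(length(terms))
  for (k in seq_along(terms)) {
    sign <- if (co[k] < 0) "- " else if (k == 1) "" else "+ "
    parts[k] <- sprintf("%s%s %s", sign, fmt_num(abs(co[k])), nm[k])
  }
  paste(parts, collapse = " ")
}

#' Write a problem in CPLEX LP format
#'
#' Emits the Maximize/Minimize, Subject To, Bounds, Binary and End sections in
#' deterministic order. Variable names are sanitized to `x1..xn` (a reversible
#' map is kept on the problem object), which keeps the file valid for every
#' backend regardless of the characters appearing in reaction ids.
#'
#' @param problem A [linear_problem()].
#' @param path Output file path.
#' @return Invisibly, the sanitization map (original name -> LP token).
#' @export
write_lp_file <- function(problem, path) {
  v <- problem$variables
  san <- stats::setNames(paste0("x", seq_len(nrow(v))), v$name)
  lines <- character(0)
  lines <- c(lines, if (problem$sense == "max") "Maximize" else "Minimize")
  obj <- problem$objective[problem$objective != 0]
  if (!length(obj)) obj <- stats::setNames(0, v$name[1])
  lines <- c(lines, paste0(" obj: ", lp_terms_string(obj, san)))
  lines <- c(lines, "Subject To")
  cons <- problem$constraints
  if (!length(cons))
    cons <- list(list(name = "free_row", terms = stats::setNames(1, v$name[1]),
                      rel = ">=", rhs = v$lower[1]))
  for (i in seq_along(cons)) {
    cc <- cons[[i]]
    lines <- c(lines, sprintf(" c%d: %s %s %s", i,
                              lp_terms_string(cc$terms, san),
                              cc$rel, fmt_num(cc$rhs)))
  }
  lines <- c(lines, "Bounds")
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "binary") next
    lo <- v$lower[i]; up <- v$upper[i]
    lines <- c(lines,
      if (is.infinite(lo) && is.infinite(up)) sprintf(" %s free", san[i])
      else if (is.infinite(up)) sprintf(" %s >= %s", san[i], fmt_num(lo))
      else if (is.infinite(lo)) sprintf(" %s <= %s", san[i], fmt_num(up))
      else if (lo == up) sprintf(" %s = %s", san[i], fmt_num(lo))
      else sprintf(" %s <= %s <= %s", fmt_num(lo), san[i], fmt_num(up)))
  }
  if (any(v$kind == "binary")) {
    lines <- c(lines, "Binary", paste0(" ", san[v$kind == "binary"]))
  }
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(san)
}

#' An LP/MILP solution
#' @keywords internal
lp_solution <- function(status, objective, values) {
  structure(list(status = status, objective = objective, values = values),
            class = "lp_solution")
}

# Column order glpsol assigns when reading our LP file: first appearance in
# objective, then constraints, then Bounds, then Binary. Mirrors
# write_lp_file exactly so index-based solution formats can be mapped back.
lp_var_order <- function(problem) {
  v <- problem$variables
  obj <- problem$objective[problem$objective != 0]
  if (!length(obj)) obj <- stats::setNames(0, v$name[1])
  seen <- names(obj)
  if (!length(problem$constraints))
    seen <- c(seen, v$name[1])
  for (cc in problem$constraints) seen <- c(seen, names(cc$terms))
  seen <- c(seen, v$name[v$kind != "binary"], v$name[v$kind == "binary"])
  unique(seen)
}

#' Parse a solver solution file
#'
#' Understands two dialects: the printable output of `glpsol --output` (both
#' its simplex and MIP table layouts) and the `status/objective/name value`
#' format written by the bundled scipy/HiGHS backend script. Sanitized
#' variable names are translated back using the problem's map.
#'
#' @param path Solution file path.
#' @param problem The [linear_problem()] the file answers (needed to invert
#'   the name sanitization and restore variable order).
#' @return An `lp_solution` with `status`, `objective`, `values`.
#' @export
read_solution_file <- function(path, problem) {
  if (!file.exists(path)) stop("solution file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  vnames <- problem$variables$name
  san <- paste0("x", seq_along(vnames))
  if (length(lines) && grepl("^status ", lines[1])) {
    status <- sub("^status ", "", lines[1])
    objective <- as.numeric(sub("^objective ", "", lines[2]))
    vals <- stats::setNames(rep(NA_real_, length(vnames)), vnames)
    if (status == "OPTIMAL") {
      for (ln in lines[-(1:2)]) {
        tok <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(tok) == 2) vals[match(tok[1], san)] <- as.numeric(tok[2])
      }
    }
    return(finish_solution(status, objective, vals, problem))
  }
  sline <- grep("^s (bas|mip) ", lines, value = TRUE)
  if (length(sline)) {
    # glpsol machine-readable solution (--write): full-precision values by
    # column index; indices map to names via the writer's appearance order
    s <- strsplit(sline[1], "\\s+")[[1]]
    ord <- lp_var_order(problem)
    vals <- stats::setNames(rep(NA_real_, length(vnames)), vnames)
    jlines <- grep("^j ", lines, value = TRUE)
    if (s[2] == "mip") {
      status <- switch(s[5], o = "OPTIMAL", f = "OPTIMAL",
                       n = "INFEASIBLE", "UNDEFINED")
      objective <- suppressWarnings(as.numeric(s[6]))
      for (jl in jlines) {
        t <- strsplit(jl, "\\s+")[[1]]
        vals[ord[as.integer(t[2])]] <- as.numeric(t[3])
      }
    } else {
      pst <- s[5]; dst <- s[6]
      status <- if (pst == "f" && dst == "f") "OPTIMAL"
        else if (pst == "n" || pst == "i") "INFEASIBLE"
        else if (dst == "n") "UNBOUNDED"
        else "UNDEFINED"
      objective <- suppressWarnings(as.numeric(s[7]))
      for (jl in jlines) {
        t <- strsplit(jl, "\\s+")[[1]]
        vals[ord[as.integer(t[2])]] <- as.numeric(t[4])
      }
    }
    return(finish_solution(status, objective, vals, problem))
  }
  status_line <- grep("^Status:", lines, value = TRUE)
  if (!length(status_line)) stop("unparseable solution file: ", path,
                                 call. = FALSE)
  st <- status_line[1]
  status <-
    if (grepl("OPTIMAL", st)) "OPTIMAL"
    else if (grepl("EMPTY|INFEASIBLE", st)) "INFEASIBLE"
    else if (grepl("UNBOUNDED", st)) "UNBOUNDED"
    else "UNDEFINED"
  objective <- NA_real_
  obj_line <- grep("^Objective:", lines, value = TRUE)
  if (length(obj_line))
    objective <- as.numeric(sub(".*=\\s*([-+0-9.eE]+)\\s*\\(.*", "\\1",
                                obj_line[1]))
  vals <- stats::setNames(rep(NA_real_, length(vnames)), vnames)
  if (status == "OPTIMAL") {
    start <- grep("^\\s*No\\. Column name", lines)
    if (!length(start)) stop("no column table in solution file", call. = FALSE)
    i <- start[1] + 2
    while (i <= length(lines) && nzchar(trimws(lines[i]))) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) == 2 && i + 1 <= length(lines)) {
        # long names wrap onto the next line; our sanitized names never do,
        # but tolerate it anyway
        tok <- c(tok, strsplit(trimws(lines[i + 1]), "\\s+")[[1]])
        i <- i + 1
      }
      name <- tok[2]
      rest <- tok[-(1:2)]
      rest <- rest[!rest %in% c("*", "B", "NL", "NU", "NF", "NS")]
      idx <- match(name, san)
      if (!is.na(idx)) vals[idx] <- as.numeric(rest[1])
      i <- i + 1
    }
  }
  finish_solution(status, objective, vals, problem)
}

finish_solution <- function(status, objective, vals, problem) {
  if (status == "OPTIMAL") {
    binv <- problem$variables$kind == "binary"
    vals[binv] <- round(vals[binv])  # exact 0/1 after solver tolerance
    if (anyNA(vals)) stop("solution file missing variable values",
                          call. = FALSE)
  } else {
    vals <- stats::setNames(numeric(0), character(0))
    objective <- NA_real_
  }
  lp_solution(status, objective, vals)
}

#' Solve an LP/MILP via an external backend
#'
#' Writes the problem as a CPLEX LP file, invokes the backend, and parses the
#' solution back. Backend `"glpk"` runs GLPK's `glpsol` (with the presolver
#' disabled so infeasible and unbounded outcomes are reported distinctly);
#' backend `"highs"` runs the bundled Python script using scipy's HiGHS
#' interface. The default backend can be set with
#' `options(fluxseries.solver = ...)`.
#'
#' @param problem A [linear_problem()].
#' @param backend `"glpk"` or `"highs"`.
#' @param time_limit MILP time limit in seconds (default 600).
#' @param keep_files Optional directory in which to keep the LP and solution
#'   files (for inspection); by default temporaries are removed.
#' @return An `lp_solution`.
#' @export
solve_lp <- function(problem,
                     backend = getOption("fluxseries.solver", "glpk"),
                     time_limit = 600, keep_files = NULL) {
  backend <- match.arg(backend, c("glpk", "highs"))
  if (nrow(problem$variables) == 0)
    return(lp_solution("OPTIMAL", 0, stats::setNames(numeric(0), character(0))))
  dir <- if (is.null(keep_files)) tempfile("lp") else keep_files
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  on.exit(if (is.null(keep_files)) unlink(dir, recursive = TRUE), add = TRUE)
  lp_path <- file.path(dir, "problem.lp")
  sol_path <- file.path(dir, "solution.txt")
  write_lp_file(problem, lp_path)
  if (backend == "glpk") {
    log <- suppressWarnings(system2(
      "glpsol", c("--nopresol", "--lp", shQuote(lp_path), "-w",
                  shQuote(sol_path), "--output",
                  shQuote(file.path(dir, "solution_pretty.txt")),
                  "--tmlim", as.integer(time_limit)),
      stdout = TRUE, stderr = TRUE))
    code <- attr(log, "status")
    if (!is.null(code) && code != 0)
      stop("glpsol failed (exit ", code, "):\n",
           paste(utils::tail(log, 10), collapse = "\n"), call. = FALSE)
    sol <- read_solution_file(sol_path, problem)
    if (sol$status == "UNDEFINED") {
      # MIP with dual-infeasible relaxation: unbounded (or vacuously empty)
      sol$status <- if (any(grepl("NO DUAL FEASIBLE", log)))
        "UNBOUNDED" else "INFEASIBLE"
    }
  } else {
    script <- system.file("python", "solve_lp.py", package = "fluxseries")
    if (!nzchar(script)) stop("bundled solver script not found", call. = FALSE)
    log <- suppressWarnings(system2(
      "python", c(shQuote(script), shQuote(lp_path), shQuote(sol_path),
                  as.integer(time_limit)),
      stdout = TRUE, stderr = TRUE))
    code <- attr(log, "status")
    if (!is.null(code) && code != 0)
      stop("highs backend failed (exit ", code, "):\n",
           paste(utils::tail(log, 10), collapse = "\n"), call. = FALSE)
    sol <- read_solution_file(sol_path, problem)
  }
  sol
}

#' Independently verify an LP solution against its problem
#'
#' Re-checks every variable bound and constraint of an OPTIMAL solution at the
#' given tolerance without consulting any solver.
#'
#' @param problem A [linear_problem()].
#' @param solution An `lp_solution` with status OPTIMAL.
#' @param tol Feasibility tolerance (default 1e-6).
#' @return Character vector of violation descriptions (empty if feasible).
#' @export
check_lp_solution <- function(problem, solution, tol = 1e-6) {
  stopifnot(solution$status == "OPTIMAL")
  v <- problem$variables
  x <- solution$values[v$name]
  out <- character()
  bad <- which(x < v$lower - tol | x > v$upper + tol)
  for (i in bad)
    out <- c(out, sprintf("variable '%s' = %g outside [%g, %g]",
                          v$name[i], x[i], v$lower[i], v$upper[i]))
  for (cc in problem$constraints) {
    lhs <- sum(cc$terms * x[names(cc$terms)])
    ok <- switch(cc$rel,
                 "<=" = lhs <= cc$rhs + tol,
                 "=" = abs(lhs - cc$rhs) <= tol,
                 ">=" = lhs >= cc$rhs - tol)
    if (!ok)
      out <- c(out, sprintf("constraint '%s': %g %s %g violated",
                            cc$name, lhs, cc$rel, cc$rhs))
  }
  out
}
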