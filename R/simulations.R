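# Simulation description files: the concise, user-editable protocol listing
# simulation identifiers, objectives, constraints, feasibility expectations
# and evaluation expressions.

#' A single simulation specification
#'
#' @param sim_id Unique identifier within a batch.
#' @param objective `NULL` (use the batch default) or a descriptor such as
#'   `list(kind = "flux_min")` or `list(kind = "max_linear", coefficients =
#'   c(R1 = 1))`.
#' @param constraints A [constraint_set()].
#' @param expect `"FEASIBLE"` or `"INFEASIBLE"` — an INFEASIBLE expectation
#'   turns non-existence of a solution into a passing test.
#' @param checks Character vector of evaluation expressions (see
#'   [evaluate_expression()]).
#' @param comment Free text.
#' @return Object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(sim_id, objective = NULL,
                            constraints = constraint_set(),
                            expect = c("FEASIBLE", "INFEASIBLE"),
                            checks = character(), comment = "") {
  expect <- match.arg(expect)
  for (ch in checks) parse_eval_expression(ch)  # must parse
  structure(list(sim_id = sim_id, objective = objective,
                 constraints = constraints, expect = expect,
                 checks = checks, comment = comment),
            class = "simulation_spec")
}

#' Parse a simulation description file
#'
#' The canonical dialect is a block grammar:
#' \preformatted{
#' SIMULATION <id>
#'   COMMENT <text>
#'   OBJECTIVE flux-min | max <reaction-id>
#'   CONSTRAINT <reaction-id> = <number>
#'   CONSTRAINT <reaction-id> in [<lo>, <hi>]
#'   KNOCKOUT <reaction-id> ...
#'   INHIBIT <reaction-id> <alpha>
#'   EXPECT FEASIBLE | INFEASIBLE
#'   CHECK <expression>
#' END
#' }
#' Lines starting with `#` are comments. The `fasimu-native` dialect is a
#' tolerant best-effort reader for the record-per-paragraph files shipped
#' with the original distribution: records are separated by blank lines, the
#' first token of a record is its identifier, and unrecognized content is
#' preserved as the record's comment.
#'
#' @param path Input file path.
#' @param dialect `"canonical"` or `"fasimu-native"`.
#' @return List of [simulation_spec()] objects.
#' @export
parse_simulations <- function(path, dialect = c("canonical", "fasimu-native")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "fasimu-native") return(parse_simulations_native(lines))
  specs <- list()
  cur <- NULL; cur_line <- NA_integer_
  oops <- function(i, msg) stop(sprintf("line %d: %s", i, msg), call. = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "\\s+")[[1]]
    kw <- toupper(tok[1])
    if (kw == "SIMULATION") {
      if (!is.null(cur)) oops(i, sprintf(
        "SIMULATION inside block started at line %d (missing END)", cur_line))
      if (length(tok) < 2) oops(i, "SIMULATION needs an identifier")
      cur <- list(sim_id = tok[2], objective = NULL, fixes = numeric(),
                  ranges = list(), knockouts = character(),
                  inhibitions = numeric(), expect = "FEASIBLE",
                  checks = character(), comment = "")
      cur_line <- i
      next
    }
    if (is.null(cur)) oops(i, sprintf("'%s' outside a SIMULATION block", tok[1]))
    if (kw == "END") {
      specs[[length(specs) + 1]] <- simulation_spec(
        cur$sim_id, cur$objective,
        constraint_set(cur$fixes, cur$ranges, cur$knockouts, cur$inhibitions),
        cur$expect, cur$checks, cur$comment)
      cur <- NULL
    } else if (kw == "COMMENT") {
      cur$comment <- trimws(sub("^\\S+\\s*", "", ln))
    } else if (kw == "OBJECTIVE") {
      if (length(tok) < 2) oops(i, "OBJECTIVE needs a kind")
      kind <- tolower(tok[2])
      if (kind == "flux-min") cur$objective <- list(kind = "flux_min")
      else if (kind == "max" && length(tok) >= 3)
        cur$objective <- list(kind = "max_linear",
                              coefficients = stats::setNames(1, tok[3]))
      else oops(i, sprintf("unknown objective '%s'", paste(tok[-1], collapse = " ")))
    } else if (kw == "CONSTRAINT") {
      body <- trimws(sub("^\\S+\\s*", "", ln))
      mm <- regmatches(body, regexec("^(\\S+)\\s+in\\s+\\[\\s*([-+0-9.eE]+)\\s*,\\s*([-+0-9.eE]+)\\s*\\]$", body))[[1]]
      eq <- regmatches(body, regexec("^(\\S+)\\s*=\\s*([-+0-9.eE]+)$", body))[[1]]
      if (length(eq)) {
        cur$fixes[eq[2]] <- as.numeric(eq[3])
      } else if (length(mm)) {
        cur$ranges[[mm[2]]] <- as.numeric(mm[3:4])
      } else oops(i, sprintf("cannot parse constraint '%s'", body))
    } else if (kw == "KNOCKOUT") {
      if (length(tok) < 2) oops(i, "KNOCKOUT needs reaction ids")
      cur$knockouts <- c(cur$knockouts, tok[-1])
    } else if (kw == "INHIBIT") {
      if (length(tok) != 3) oops(i, "INHIBIT needs '<reaction-id> <alpha>'")
      cur$inhibitions[tok[2]] <- as.numeric(tok[3])
    } else if (kw == "EXPECT") {
      ex <- toupper(tok[2])
      if (!ex %in% c("FEASIBLE", "INFEASIBLE"))
        oops(i, "EXPECT must be FEASIBLE or INFEASIBLE")
      cur$expect <- ex
    } else if (kw == "CHECK") {
      expr <- trimws(sub("^\\S+\\s*", "", ln))
      ok <- tryCatch({ parse_eval_expression(expr); TRUE },
                     error = function(e) e)
      if (!isTRUE(ok)) oops(i, conditionMessage(ok))
      cur$checks <- c(cur$checks, expr)
    } else {
      oops(i, sprintf("unknown keyword '%s'", tok[1]))
    }
  }
  if (!is.null(cur))
    stop(sprintf("line %d: SIMULATION '%s' missing END", cur_line, cur$sim_id),
         call. = FALSE)
  ids <- vapply(specs, `[[`, character(1), "sim_id")
  if (anyDuplicated(ids))
    stop("duplicate simulation ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  specs
}

parse_simulations_native <- function(lines) {
  # records separated by blank lines; "#" comment lines ignored
  keep <- !grepl("^\\s*#", lines)
  lines <- lines[keep]
  blank <- !nzchar(trimws(lines))
  specs <- list()
  rec <- character()
  flush <- function(rec) {
    if (!length(rec)) return(NULL)
    first <- strsplit(trimws(rec[1]), "\\s+")[[1]]
    simulation_spec(first[1], NULL, constraint_set(), "FEASIBLE",
                    character(), paste(rec, collapse = "\n"))
  }
  for (i in seq_along(lines)) {
    if (blank[i]) {
      s <- flush(rec); if (!is.null(s)) specs[[length(specs) + 1]] <- s
      rec <- character()
    } else rec <- c(rec, lines[i])
  }
  s <- flush(rec); if (!is.null(s)) specs[[length(specs) + 1]] <- s
  specs
}

## ---- evaluation expressions -------------------------------------------

tokenize_eval <- function(text) {
  pat <- "<=|>=|==|<|>|\\(|\\)|[^[:space:]()<>=]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("empty expression", call. = FALSE)
  regmatches(text, gregexpr(pat, text))[[1]]
}

#' Parse an evaluation expression
#'
#' Grammar: comparisons `<rxn-id> <op> <number>` or
#' `abs(<rxn-id>) <op> <number>` with `<op>` one of `<`, `<=`, `==`, `>=`,
#' `>`, combined with `and`, `or` and parentheses (`and` binds tighter).
#'
#' @param text Expression string.
#' @return A parse tree (nested lists), used by [evaluate_expression()].
#' @export
parse_eval_expression <- function(text) {
  toks <- tokenize_eval(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect_tok <- function(t) {
    got <- take()
    if (!identical(got, t))
      stop(sprintf("expected '%s' but found '%s'", t,
                   if (is.na(got)) "end of expression" else got),
           call. = FALSE)
  }
  parse_or <- function() {
    left <- parse_and()
    while (identical(tolower(peek()), "or")) {
      take(); left <- list(op = "or", left, parse_and())
    }
    left
  }
  parse_and <- function() {
    left <- parse_factor()
    while (identical(tolower(peek()), "and")) {
      take(); left <- list(op = "and", left, parse_factor())
    }
    left
  }
  parse_factor <- function() {
    if (identical(peek(), "(")) { take(); e <- parse_or(); expect_tok(")"); return(e) }
    is_abs <- FALSE
    id <- take()
    if (is.na(id)) stop("unexpected end of expression", call. = FALSE)
    if (tolower(id) == "abs") { is_abs <- TRUE; expect_tok("("); id <- take(); expect_tok(")") }
    op <- take()
    if (!op %in% c("<", "<=", "==", ">=", ">"))
      stop(sprintf("expected a comparison operator after '%s', found '%s'",
                   id, op), call. = FALSE)
    num <- suppressWarnings(as.numeric(take()))
    if (is.na(num)) stop(sprintf("expected a number in comparison on '%s'", id),
                         call. = FALSE)
    list(op = "cmp", id = id, abs = is_abs, rel = op, rhs = num)
  }
  out <- parse_or()
  if (!is.na(peek()))
    stop(sprintf("trailing input '%s'", peek()), call. = FALSE)
  out
}

#' Evaluate an expression against a flux distribution
#'
#' Comparisons use the exact solver values, with no zero-tolerance snapping.
#'
#' @param expr Expression string or a tree from [parse_eval_expression()].
#' @param solution An OPTIMAL [flux_distribution()].
#' @return Logical scalar.
#' @export
evaluate_expression <- function(expr, solution) {
  if (is.character(expr)) expr <- parse_eval_expression(expr)
  stopifnot(solution$status == "OPTIMAL")
  rec <- function(node) {
    if (node$op == "or") return(rec(node[[2]]) || rec(node[[3]]))
    if (node$op == "and") return(rec(node[[2]]) && rec(node[[3]]))
    if (!node$id %in% names(solution$fluxes))
      stop(sprintf("unknown reaction '%s' in expression", node$id),
           call. = FALSE)
    v <- solution$fluxes[[node$id]]
    if (node$abs) v <- abs(v)
    switch(node$rel,
           "<" = v < node$rhs, "<=" = v <= node$rhs,
           "==" = v == node$rhs, ">=" = v >= node$rhs, ">" = v > node$rhs)
  }
  rec(expr)
}
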