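# Model input/output: SBML level 2 (read v1-4, write v4), a plain-text flat
# reaction dialect, and val flux tables for CellNetAnalyzer/FluxViz-style
# visualization.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Read a stoichiometric model from SBML
#'
#' Accepts SBML level 2 versions 1-4 (level 3 is read leniently, with a
#' warning; the fbc package is not interpreted). Species become metabolites
#' with `boundaryCondition` honored; reactions collect their stoichiometry
#' from reactants and products, and flux bounds from kinetic-law parameters
#' named `LOWER_BOUND` / `UPPER_BOUND` (the COBRA convention), falling back
#' to reversibility defaults `[-1e5, 1e5]` / `[0, 1e5]`. A parameter named
#' `WEIGHT` sets the flux-minimization weight.
#'
#' @param path Path to an SBML file.
#' @return A [flux_network()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  level <- xml2::xml_attr(doc, "level")
  version <- xml2::xml_attr(doc, "version")
  if (identical(level, "3")) {
    warning("SBML level 3 read leniently (fbc bounds are not interpreted)",
            call. = FALSE)
  } else if (!identical(level, "2") || !(version %in% as.character(1:4))) {
    stop(sprintf("unsupported SBML level/version %s.%s (supported: 2.1-2.4, 3 leniently)",
                 level, version), call. = FALSE)
  }
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  attr_or <- function(nodes, a, default) {
    v <- xml2::xml_attr(nodes, a); ifelse(is.na(v), default, v)
  }
  ids <- xml2::xml_attr(sp, "id")
  mets <- metabolites(
    ids,
    name = attr_or(sp, "name", ids),
    compartment = attr_or(sp, "compartment", "default"),
    boundary = attr_or(sp, "boundaryCondition", "false") == "true")
  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- vector("list", length(rnodes))
  for (i in seq_along(rnodes)) {
    rn <- rnodes[[i]]
    rid <- xml2::xml_attr(rn, "id")
    if (length(xml2::xml_find_all(rn, ".//stoichiometryMath")))
      stop(sprintf("reaction '%s' uses stoichiometryMath, which is not supported",
                   rid), call. = FALSE)
    rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")  # SBML default: true
    side <- function(xp, sign) {
      refs <- xml2::xml_find_all(rn, xp)
      st <- xml2::xml_attr(refs, "stoichiometry")
      stats::setNames(sign * as.numeric(ifelse(is.na(st), "1", st)),
                      xml2::xml_attr(refs, "species"))
    }
    s <- c(side("./listOfReactants/speciesReference", -1),
           side("./listOfProducts/speciesReference", 1))
    if (anyDuplicated(names(s))) {
      s <- tapply(s, names(s), sum)[unique(names(s))]
      s <- s[s != 0]
    }
    pars <- xml2::xml_find_all(rn, "./kineticLaw/listOfParameters/parameter")
    pv <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
    lb <- if ("LOWER_BOUND" %in% names(pv)) max(pv[["LOWER_BOUND"]], -INF_BOUND)
          else if (rev) -INF_BOUND else 0
    ub <- if ("UPPER_BOUND" %in% names(pv)) min(pv[["UPPER_BOUND"]], INF_BOUND)
          else INF_BOUND
    w <- if ("WEIGHT" %in% names(pv)) pv[["WEIGHT"]] else 1
    rxns[[i]] <- reaction(rid, s, lb = lb, ub = ub,
                          reversible = rev || lb < 0,
                          name = attr_or(rn, "name", rid), weight = w)
  }
  net <- flux_network(mets, rxns)
  message(sprintf("read_sbml: %d species (%d boundary), %d reactions from %s",
                  nrow(net$metabolites), sum(net$metabolites$boundary),
                  nrow(net$reactions), basename(path)))
  if (nrow(net$reactions) != length(rnodes))
    stop("internal error: parsed reaction count does not match listOfReactions",
         call. = FALSE)
  net
}

#' Write a model (and optionally a solution) as SBML level 2 version 4
#'
#' Bounds and weights are stored as kinetic-law parameters (`LOWER_BOUND`,
#' `UPPER_BOUND`, `WEIGHT`); when a solution is given, each reaction
#' additionally carries a `FLUX_VALUE` parameter. Output is deterministic:
#' elements appear in network order.
#'
#' @param net A valid [flux_network()].
#' @param path Output file path.
#' @param solution Optional OPTIMAL [flux_distribution()].
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(net, path, solution = NULL) {
  stop_if_invalid(net)
  if (!is.null(solution) && solution$status != "OPTIMAL")
    stop("only OPTIMAL solutions can be embedded", call. = FALSE)
  L <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
         "<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" level=\"2\" version=\"4\">",
         "  <model id=\"model\">")
  comps <- unique(net$metabolites$compartment)
  if (!length(comps)) comps <- "default"
  L <- c(L, "    <listOfCompartments>",
         sprintf("      <compartment id=\"%s\" size=\"1\"/>", xml_escape(comps)),
         "    </listOfCompartments>")
  m <- net$metabolites
  L <- c(L, "    <listOfSpecies>",
         sprintf("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" boundaryCondition=\"%s\"/>",
                 xml_escape(m$id), xml_escape(m$name), xml_escape(m$compartment),
                 ifelse(m$boundary, "true", "false")),
         "    </listOfSpecies>")
  L <- c(L, "    <listOfReactions>")
  r <- net$reactions
  for (i in seq_len(nrow(r))) {
    id <- r$id[i]
    s <- net$stoichiometry[[id]]
    L <- c(L, sprintf("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\">",
                      xml_escape(id), xml_escape(r$name[i]),
                      if (r$reversible[i]) "true" else "false"))
    subs <- s[s < 0]; prods <- s[s > 0]
    if (length(subs))
      L <- c(L, "        <listOfReactants>",
             sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\"/>",
                     xml_escape(names(subs)), fmt_num(-unname(subs))),
             "        </listOfReactants>")
    if (length(prods))
      L <- c(L, "        <listOfProducts>",
             sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\"/>",
                     xml_escape(names(prods)), fmt_num(unname(prods))),
             "        </listOfProducts>")
    pars <- c(sprintf("          <parameter id=\"LOWER_BOUND\" value=\"%s\"/>",
                      fmt_num(r$lb[i])),
              sprintf("          <parameter id=\"UPPER_BOUND\" value=\"%s\"/>",
                      fmt_num(r$ub[i])),
              sprintf("          <parameter id=\"WEIGHT\" value=\"%s\"/>",
                      fmt_num(r$weight[i])))
    if (!is.null(solution))
      pars <- c(pars, sprintf("          <parameter id=\"FLUX_VALUE\" value=\"%s\"/>",
                              fmt_num(unname(solution$fluxes[[id]]))))
    L <- c(L, "        <kineticLaw>",
           "          <math xmlns=\"http://www.w3.org/1998/Math/MathML\"><ci> FLUX_VALUE </ci></math>",
           "          <listOfParameters>", pars, "          </listOfParameters>",
           "        </kineticLaw>", "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(L, path)
  invisible(path)
}

#' Read a model from the plain-text flat dialect
#'
#' One reaction per line:
#' `<id>: <coeff> <met> [+ <coeff> <met> ...] (->|<=>) <coeff> <met> ... [lb, ub]`.
#' Either side may be empty (exchange reactions). Lines starting with `#` are
#' comments; `-boundary <met>` declares a boundary metabolite. Defaults when
#' the bounds suffix is absent: `[0, 1e5]` for `->`, `[-1e5, 1e5]` for `<=>`.
#'
#' @param path Input file path.
#' @return A [flux_network()].
#' @export
read_flat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  boundary <- character()
  met_order <- character()
  rxns <- list()
  parse_side <- function(txt, lineno) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(stats::setNames(numeric(0), character(0)))
    parts <- strsplit(txt, "\\s*\\+\\s*")[[1]]
    out <- numeric(0)
    for (p in parts) {
      tok <- strsplit(trimws(p), "\\s+")[[1]]
      if (length(tok) == 1) tok <- c("1", tok)
      co <- suppressWarnings(as.numeric(tok[1]))
      if (length(tok) != 2 || is.na(co))
        stop(sprintf("line %d: cannot parse term '%s'", lineno, p),
             call. = FALSE)
      out[tok[2]] <- co
    }
    out
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "-boundary")) {
      boundary <- c(boundary, strsplit(ln, "\\s+")[[1]][-1])
      next
    }
    if (!grepl(":", ln, fixed = TRUE))
      stop(sprintf("line %d: expected '<id>: ...' but got '%s'", i, ln),
           call. = FALSE)
    id <- trimws(sub(":.*", "", ln))
    body <- trimws(sub("^[^:]*:", "", ln))
    bounds <- NULL
    bm <- regmatches(body, regexec("\\[\\s*([-+0-9.eE]+)\\s*,\\s*([-+0-9.eE]+)\\s*\\]\\s*$", body))[[1]]
    if (length(bm)) {
      bounds <- as.numeric(bm[2:3])
      body <- trimws(sub("\\[[^]]*\\]\\s*$", "", body))
    }
    rev <- grepl("<=>", body, fixed = TRUE)
    arrow <- if (rev) "<=>" else "->"
    if (!rev && !grepl("->", body, fixed = TRUE))
      stop(sprintf("line %d: missing arrow '->' or '<=>'", i), call. = FALSE)
    sides <- strsplit(body, arrow, fixed = TRUE)[[1]]
    if (length(sides) == 1) sides <- c(sides, "")
    lhs <- parse_side(sides[1], i)
    rhs <- parse_side(sides[2], i)
    s <- c(-lhs, rhs)
    if (!length(s))
      stop(sprintf("line %d: reaction '%s' has empty stoichiometry", i, id),
           call. = FALSE)
    if (anyDuplicated(names(s))) {
      s <- tapply(s, names(s), sum)[unique(names(s))]
      s <- s[s != 0]
    }
    met_order <- c(met_order, setdiff(names(s), met_order))
    lb <- if (!is.null(bounds)) bounds[1] else if (rev) -INF_BOUND else 0
    ub <- if (!is.null(bounds)) bounds[2] else INF_BOUND
    rxns[[length(rxns) + 1]] <- reaction(id, s, lb = lb, ub = ub,
                                         reversible = rev || lb < 0)
  }
  met_order <- c(met_order, setdiff(boundary, met_order))
  flux_network(metabolites(met_order, boundary = met_order %in% boundary),
               rxns)
}

#' Write a model in the flat dialect
#'
#' Inverse of [read_flat()]; `read_flat(write_flat(net))` reproduces ids,
#' stoichiometry, bounds and reversibility exactly. Names, compartments and
#' non-unit weights are not representable in this dialect.
#'
#' @param net A valid [flux_network()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_flat <- function(net, path) {
  stop_if_invalid(net)
  fmt_side <- function(s) paste(sprintf("%s %s", fmt_num(abs(unname(s))),
                                        names(s)), collapse = " + ")
  L <- character()
  bmets <- net$metabolites$id[net$metabolites$boundary]
  if (length(bmets)) L <- c(L, paste("-boundary", bmets))
  r <- net$reactions
  for (i in seq_len(nrow(r))) {
    s <- net$stoichiometry[[r$id[i]]]
    arrow <- if (r$reversible[i]) "<=>" else "->"
    L <- c(L, sprintf("%s: %s %s %s [%s, %s]", r$id[i], fmt_side(s[s < 0]),
                      arrow, fmt_side(s[s > 0]), fmt_num(r$lb[i]),
                      fmt_num(r$ub[i])))
  }
  writeLines(L, path)
  invisible(path)
}

#' Write a val flux table
#'
#' One line per reaction, `<reaction-id><TAB><flux>`, in network order, with
#' 6 significant digits — the plain-text convention consumed by
#' CellNetAnalyzer and FluxViz. No header unless `comment` is given.
#'
#' @param solution An OPTIMAL [flux_distribution()].
#' @param net The [flux_network()] providing reaction order.
#' @param path Output file path.
#' @param comment Optional single comment line, written prefixed with `"# "`.
#' @return Invisibly, `path`.
#' @export
write_val <- function(solution, net, path, comment = NULL) {
  if (!inherits(solution, "flux_distribution") ||
      solution$status != "OPTIMAL")
    stop("write_val requires an OPTIMAL flux distribution", call. = FALSE)
  ids <- net$reactions$id
  vals <- sprintf("%.6g", signif(unname(solution$fluxes[ids]), 6))
  vals[vals == "-0"] <- "0"
  L <- paste0(ids, "\t", vals)
  if (!is.null(comment)) L <- c(paste0("# ", comment), L)
  writeLines(L, path)
  invisible(path)
}
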