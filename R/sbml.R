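## SBML import/export on top of xml2.
##
## Output is SBML Level 3 Version 1 with the fbc (v2) package: explicit bound
## parameters, gene products and a flux objective. Input accepts that dialect
## plus the older Level 2 convention (reversible flag; optional bounds inside
## kineticLaw parameters named LOWER_BOUND/UPPER_BOUND). Where a file carries
## no bounds, the COBRA defaults (0 or -1000, +1000) are applied with a
## warning.

SBML_NS_L3 <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read an SBML model
#'
#' @param path path to an SBML file (Level 2, or Level 3 with/without fbc).
#' @return a `metabolic_model`; reversibility is encoded as a negative lower
#'   bound.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ## strip default namespace for painless xpath
  xml2::xml_ns_strip(doc)
  mod <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mod, "xml_missing")) stop("SBML parse failure: no <model> element")

  comp_nodes <- xml2::xml_find_all(mod, ".//listOfCompartments/compartment")
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp <- xml2::xml_find_all(mod, ".//listOfSpecies/species")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), "",
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = ifelse(is.na(xml2::xml_attr(sp, "chemicalFormula")), "",
                     xml2::xml_attr(sp, "chemicalFormula")),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp, "charge"))),
    stringsAsFactors = FALSE)
  mets <- mets[!boundary, , drop = FALSE]

  ## fbc bound parameters
  par_nodes <- xml2::xml_find_all(mod, ".//listOfParameters/parameter")
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(mod, ".//listOfReactions/reaction")
  n <- length(rx_nodes)
  rxn <- data.frame(id = character(n), name = character(n),
                    lower_bound = numeric(n), upper_bound = numeric(n),
                    gpr = character(n), subsystem = character(n),
                    stringsAsFactors = FALSE)
  stoich <- vector("list", n)
  missing_bounds <- FALSE
  for (k in seq_len(n)) {
    node <- rx_nodes[[k]]
    rid <- xml2::xml_attr(node, "id")
    rxn$id[k] <- rid
    nm <- xml2::xml_attr(node, "name")
    rxn$name[k] <- if (is.na(nm)) "" else nm
    rev <- !identical(xml2::xml_attr(node, "reversible"), "false")

    st <- numeric(0)
    for (sr in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      co <- xml2::xml_attr(sr, "stoichiometry")
      st[sid] <- (if (sid %in% names(st)) st[sid] else 0) -
        (if (is.na(co)) 1 else as.numeric(co))
    }
    for (sr in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      co <- xml2::xml_attr(sr, "stoichiometry")
      st[sid] <- (if (sid %in% names(st)) st[sid] else 0) +
        (if (is.na(co)) 1 else as.numeric(co))
    }
    st <- st[names(st) %in% mets$id]   # drop boundary species
    stoich[[k]] <- st

    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(pars)) {
      rxn$lower_bound[k] <- pars[[lbp]]
      rxn$upper_bound[k] <- pars[[ubp]]
    } else {
      kl <- xml2::xml_find_all(node, ".//kineticLaw//parameter")
      klv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                             xml2::xml_attr(kl, "id"))
      if ("LOWER_BOUND" %in% names(klv)) {
        rxn$lower_bound[k] <- klv[["LOWER_BOUND"]]
        rxn$upper_bound[k] <- if ("UPPER_BOUND" %in% names(klv))
          klv[["UPPER_BOUND"]] else DEFAULT_BOUND
      } else {
        missing_bounds <- TRUE
        rxn$lower_bound[k] <- if (rev) -DEFAULT_BOUND else 0
        rxn$upper_bound[k] <- DEFAULT_BOUND
      }
    }
    ga <- xml2::xml_find_first(node,
      "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing"))
      rxn$gpr[k] <- sbml_gpr_string(xml2::xml_child(ga))
  }
  if (missing_bounds)
    warning("some reactions carried no flux bounds; applied defaults ",
            "(0 or -", DEFAULT_BOUND, ", +", DEFAULT_BOUND, ")")

  ## objective (fbc)
  objective <- numeric(0)
  fo <- xml2::xml_find_all(mod, ".//*[local-name()='fluxObjective']")
  if (length(fo)) {
    objective <- stats::setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                                 xml2::xml_attr(fo, "reaction"))
  }

  metabolic_model(mets, rxn, stats::setNames(stoich, rxn$id),
                  objective = objective,
                  compartments = if (length(compartments)) compartments else NULL,
                  biomass = names(objective))
}

sbml_gpr_string <- function(node) {
  if (is.null(node) || inherits(node, "xml_missing")) return("")
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpr_string, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Write a model as SBML Level 3 + fbc
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', SBML_NS_L3, '" xmlns:fbc="', FBC_NS,
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="model" fbc:strict="true">')
  w('    <listOfCompartments>')
  for (cp in model$compartments)
    w('      <compartment id="', esc(cp), '" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    w('      <species id="', esc(mt$id), '" name="', esc(mt$name),
      '" compartment="', esc(mt$compartment),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
      if (!is.na(mt$formula) && nzchar(mt$formula))
        paste0(' fbc:chemicalFormula="', esc(mt$formula), '"') else "",
      if (!is.na(mt$charge)) paste0(' fbc:charge="', mt$charge, '"') else "",
      '/>')
  }
  w('    </listOfSpecies>')

  ## bound parameters, deduplicated
  bvals <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bid <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", num(v)))
  w('    <listOfParameters>')
  for (v in bvals)
    w('      <parameter id="', bid(v), '" value="', num(v),
      '" constant="true"/>')
  w('    </listOfParameters>')

  w('    <listOfReactions>')
  for (j in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[j, ]
    st <- model$stoichiometry[, j]
    st <- st[st != 0]
    w('      <reaction id="', esc(rx$id), '" name="', esc(rx$name),
      '" reversible="', if (rx$lower_bound < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="', bid(rx$lower_bound),
      '" fbc:upperFluxBound="', bid(rx$upper_bound), '">')
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      w('        <listOfReactants>')
      for (mid in names(reac))
        w('          <speciesReference species="', esc(mid),
          '" stoichiometry="', num(-reac[[mid]]), '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(prod)) {
      w('        <listOfProducts>')
      for (mid in names(prod))
        w('          <speciesReference species="', esc(mid),
          '" stoichiometry="', num(prod[[mid]]), '" constant="true"/>')
      w('        </listOfProducts>')
    }
    if (nzchar(rx$gpr))
      w('        <fbc:geneProductAssociation>',
        gpr_to_sbml(rx$gpr),
        '</fbc:geneProductAssociation>')
    w('      </reaction>')
  }
  w('    </listOfReactions>')

  if (length(model$genes)) {
    w('    <fbc:listOfGeneProducts>')
    for (g in model$genes)
      w('      <fbc:geneProduct fbc:id="', esc(g), '" fbc:label="', esc(g), '"/>')
    w('    </fbc:listOfGeneProducts>')
  }
  if (length(model$objective)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    for (rid in names(model$objective))
      w('          <fbc:fluxObjective fbc:reaction="', esc(rid),
        '" fbc:coefficient="', num(model$objective[[rid]]), '"/>')
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
  invisible(path)
}

## GPR string -> nested fbc association XML
gpr_to_sbml <- function(gpr) {
  node <- gpr_ast(gpr)
  render <- function(nd) {
    if (is.character(nd))
      return(paste0('<fbc:geneProductRef fbc:geneProduct="', nd, '"/>'))
    kids <- paste(vapply(nd$args, render, character(1)), collapse = "")
    paste0('<fbc:', nd$op, '>', kids, '</fbc:', nd$op, '>')
  }
  render(node)
}

## small AST: character leaf, or list(op = "and"/"or", args = list(...))
gpr_ast <- function(gpr) {
  toks <- gpr_tokens(gpr)
  pos <- 1L
  parse_or <- function() {
    args <- list(parse_and())
    while (pos <= length(toks) && toks[pos] == "or") {
      pos <<- pos + 1L
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (pos <= length(toks) && toks[pos] == "and") {
      pos <<- pos + 1L
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    tk <- toks[pos]
    if (tk == "(") {
      pos <<- pos + 1L
      v <- parse_or()
      pos <<- pos + 1L
      return(v)
    }
    pos <<- pos + 1L
    tk
  }
  parse_or()
}
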