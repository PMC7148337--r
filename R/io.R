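# Model readers/writers: a JSON dialect mirroring the COBRA community JSON
# schema field names, and SBML Level 3 + FBC v2 built on xml2. Output is
# deterministic (ids sorted, fixed number formatting) so repeated saves of
# the same model are byte-identical.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

num_fmt <- function(x) {
  # deterministic, locale-independent numeric formatting
  ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%d", as.integer(x)),
         sub("0+$", "", sprintf("%.10f", x)))
}

# always used after an M_/R_/G_ prefix, so only invalid characters need
# replacing; ids made of [A-Za-z0-9_] round-trip exactly
sid <- function(x) gsub("[^A-Za-z0-9_]", "__", x)

#' Read a metabolic model from file
#'
#' Supports SBML Level 3 with the FBC v2 extension and a JSON dialect using
#' COBRA community schema field names (`metabolites`, `reactions` with
#' `lower_bound`/`upper_bound`/`gene_reaction_rule`, `genes`). GPR strings
#' are parsed into Boolean trees on load. A missing objective yields a
#' warning and an unset objective.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @return a `"metabolic_model"`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

#' Write a metabolic model to file
#'
#' Output is deterministic: metabolites, reactions and genes are sorted by
#' id, so two saves of the same model are byte-identical. Reactions with an
#' empty GPR get no gene-association element.
#'
#' @param model a `"metabolic_model"`.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  validate_model(model)
  if (format == "json") write_model_json(model, path) else write_model_sbml(model, path)
  invisible(path)
}

read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% sub("^.*_([a-z0-9]+)$", "\\1", m$id),
               formula = m$formula %||% NA_character_,
               charge = m$charge %||% NA_integer_, stringsAsFactors = FALSE)))
  objective <- NA_character_
  stoich <- list()
  gprs <- list()
  rx <- do.call(rbind, lapply(j$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s) || !length(s) || anyNA(suppressWarnings(as.numeric(s))))
      stop("malformed stoichiometry for reaction ", r$id)
    stoich[[r$id]] <<- stats::setNames(as.numeric(s), names(s))
    gprs[[r$id]] <<- parse_gpr(r$gene_reaction_rule %||% "")
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      objective <<- r$id
    data.frame(id = r$id, name = r$name %||% r$id,
               lb = r$lower_bound, ub = r$upper_bound,
               subsystem = r$subsystem %||% "", stringsAsFactors = FALSE)
  }))
  if (is.na(objective)) warning("no objective reaction found in ", path)
  metabolic_model(id = j$id %||% "model", metabolites = mets, reactions = rx,
                  stoichiometry = stoich, gpr = gprs, objective = objective)
}

write_model_json <- function(model, path) {
  ord_m <- order(model$metabolites$id)
  ord_r <- order(model$reactions$id)
  mets <- lapply(ord_m, function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(ord_r, function(i) {
    r <- model$reactions[i, ]
    s <- model$stoichiometry[[r$id]]
    s <- s[order(names(s))]
    list(id = r$id, name = r$name,
         metabolites = as.list(s),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = as.character(model$gpr[[r$id]]),
         subsystem = r$subsystem,
         objective_coefficient = if (identical(r$id, model$objective)) 1 else 0)
  })
  genes <- lapply(model_genes(model), function(g) list(id = g))
  jsonlite::write_json(list(id = model$id, metabolites = mets, reactions = rxns,
                            genes = genes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# ---- SBML L3 FBC v2 ---------------------------------------------------------

gpr_to_fbc <- function(rule, doc_ns_prefix = "fbc") {
  # returns a list tree for building xml nodes
  switch(rule$type,
    leaf = list(tag = "fbc:geneProductRef", ref = rule$gene),
    and  = list(tag = "fbc:and", children = lapply(rule$children, gpr_to_fbc)),
    or   = list(tag = "fbc:or", children = lapply(rule$children, gpr_to_fbc)),
    stop("cannot serialize GPR node of type ", rule$type))
}

write_model_sbml <- function(model, path) {
  mets <- model$metabolites[order(model$metabolites$id), , drop = FALSE]
  rxns <- model$reactions[order(model$reactions$id), , drop = FALSE]
  genes <- model_genes(model)
  comps <- sort(unique(mets$compartment))

  # shared flux-bound parameters, one per distinct value
  vals <- sort(unique(c(rxns$lb, rxns$ub)))
  pid <- stats::setNames(paste0("fb_", seq_along(vals)), num_fmt(vals))

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  ln <- character(0)
  put <- function(...) ln[[length(ln) + 1L]] <<- paste0(...)

  put('<?xml version="1.0" encoding="UTF-8"?>')
  put('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
      '" level="3" version="1" fbc:required="false">')
  put('  <model id="', sid(model$id), '" name="', esc(model$id),
      '" fbc:strict="true">')
  put('    <listOfCompartments>')
  for (cp in comps)
    put('      <compartment id="', sid(cp), '" constant="true" size="1"/>')
  put('    </listOfCompartments>')
  put('    <listOfSpecies>')
  for (i in seq_len(nrow(mets))) {
    m <- mets[i, ]
    extra <- ""
    if (!is.na(m$formula)) extra <- paste0(extra, ' fbc:chemicalFormula="', esc(m$formula), '"')
    if (!is.na(m$charge)) extra <- paste0(extra, ' fbc:charge="', m$charge, '"')
    put('      <species id="M_', sid(m$id), '" name="', esc(m$name),
        '" compartment="', sid(m$compartment),
        '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
        extra, '/>')
  }
  put('    </listOfSpecies>')
  put('    <listOfParameters>')
  for (k in seq_along(vals))
    put('      <parameter id="', pid[[k]], '" value="', num_fmt(vals[k]),
        '" constant="true"/>')
  put('    </listOfParameters>')
  put('    <listOfReactions>')
  for (i in seq_len(nrow(rxns))) {
    r <- rxns[i, ]
    s <- model$stoichiometry[[r$id]]
    s <- s[order(names(s))]
    put('      <reaction id="R_', sid(r$id), '" name="', esc(r$name),
        '" reversible="', if (r$lb < 0) "true" else "false",
        '" fast="false" fbc:lowerFluxBound="', pid[[num_fmt(r$lb)]],
        '" fbc:upperFluxBound="', pid[[num_fmt(r$ub)]], '">')
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      put('        <listOfReactants>')
      for (mid in names(reac))
        put('          <speciesReference species="M_', sid(mid),
            '" stoichiometry="', num_fmt(-reac[[mid]]), '" constant="true"/>')
      put('        </listOfReactants>')
    }
    if (length(prod)) {
      put('        <listOfProducts>')
      for (mid in names(prod))
        put('          <speciesReference species="M_', sid(mid),
            '" stoichiometry="', num_fmt(prod[[mid]]), '" constant="true"/>')
      put('        </listOfProducts>')
    }
    g <- model$gpr[[r$id]]
    if (g$type != "empty") {
      put('        <fbc:geneProductAssociation>')
      emit <- function(nd, indent) {
        pad <- strrep(" ", indent)
        if (nd$type == "leaf") {
          put(pad, '<fbc:geneProductRef fbc:geneProduct="G_', sid(nd$gene), '"/>')
        } else if (nd$type %in% c("and", "or")) {
          put(pad, '<fbc:', nd$type, '>')
          for (ch in nd$children) emit(ch, indent + 2L)
          put(pad, '</fbc:', nd$type, '>')
        } else stop("cannot serialize GPR node of type ", nd$type,
                    " for reaction ", r$id)
      }
      emit(g, 10L)
      put('        </fbc:geneProductAssociation>')
    }
    put('      </reaction>')
  }
  put('    </listOfReactions>')
  if (!is.na(model$objective)) {
    put('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    put('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    put('        <fbc:listOfFluxObjectives>')
    put('          <fbc:fluxObjective fbc:reaction="R_', sid(model$objective),
        '" fbc:coefficient="1"/>')
    put('        </fbc:listOfFluxObjectives>')
    put('      </fbc:objective>')
    put('    </fbc:listOfObjectives>')
  }
  if (length(genes)) {
    put('    <fbc:listOfGeneProducts>')
    for (g in genes)
      put('      <fbc:geneProduct fbc:id="G_', sid(g), '" fbc:label="', esc(g), '"/>')
    put('    </fbc:listOfGeneProducts>')
  }
  put('  </model>')
  put('</sbml>')
  writeLines(ln, path, useBytes = TRUE)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("not an SBML L3 document: ", path)

  att <- function(node, a) xml2::xml_attr(node, a)
  strip <- function(x, prefix) ifelse(startsWith(x, prefix),
                                      substring(x, nchar(prefix) + 1L), x)

  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabel <- stats::setNames(xml2::xml_attr(gps, "label"), xml2::xml_attr(gps, "id"))
  gene_of <- function(ref) {
    if (ref %in% names(glabel) && !is.na(glabel[[ref]])) glabel[[ref]]
    else strip(ref, "G_")
  }

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp, "charge"))),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") return(gpr_leaf(gene_of(att(node, "geneProduct"))))
    kids <- xml2::xml_children(node)
    gpr_node(nm, lapply(kids, parse_assoc))
  }

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  stoich <- list(); gprs <- list()
  rxns <- do.call(rbind, lapply(rx_nodes, function(nd) {
    rid <- strip(att(nd, "id"), "R_")
    refs <- function(xp, sign) {
      sr <- xml2::xml_find_all(nd, xp, ns)
      if (!length(sr)) return(NULL)
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (anyNA(coef)) stop("malformed stoichiometry in reaction ", rid)
      stats::setNames(sign * coef, strip(xml2::xml_attr(sr, "species"), "M_"))
    }
    s <- c(refs("./s:listOfReactants/s:speciesReference", -1),
           refs("./s:listOfProducts/s:speciesReference", +1))
    if (is.null(s)) stop("reaction ", rid, " has empty stoichiometry")
    stoich[[rid]] <<- s
    assoc <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation/*", ns)
    gprs[[rid]] <<- if (inherits(assoc, "xml_missing")) gpr_empty()
                    else parse_assoc(assoc)
    lbp <- att(nd, "lowerFluxBound"); ubp <- att(nd, "upperFluxBound")
    data.frame(id = rid, name = att(nd, "name"),
               lb = if (!is.na(lbp)) pval[[lbp]] else -1000,
               ub = if (!is.na(ubp)) pval[[ubp]] else 1000,
               subsystem = "", stringsAsFactors = FALSE)
  }))
  rxns$name[is.na(rxns$name)] <- rxns$id[is.na(rxns$name)]

  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- if (inherits(fo, "xml_missing")) {
    warning("no objective defined in ", path)
    NA_character_
  } else strip(att(fo, "reaction"), "R_")

  metabolic_model(id = strip(att(mdl, "id"), ""), metabolites = mets,
                  reactions = rxns, stoichiometry = stoich, gpr = gprs,
                  objective = objective)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
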