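#' Read a metabolic model from file
#'
#' Two on-disk formats are supported: a schema-versioned, sorted-key JSON
#' dialect (`"json"`, the package's full-fidelity format) and a restricted
#' SBML Level 3 document with the FBC version-2 package (`"sbml"`) covering
#' species/compartments, flux bounds, gene associations and the active
#' objective. Compartment tags are parsed from bracket suffixes of species
#' ids (`"glc[e]"`); when an SBML `compartment` attribute disagrees with the
#' suffix, the attribute wins with a warning.
#'
#' @param path file path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension).
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

#' Write a metabolic model to file
#'
#' Serialisation is deterministic: JSON keys are sorted and numbers written
#' at full precision, so identical models yield byte-identical files.
#' `read_model(write_model(m))` preserves ids, names, compartments,
#' formulas, formation energies, stoichiometry, bounds, GPR rules, subsystem
#' and the objective in both formats.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

## ---- JSON dialect (cocultr-model/1) ----------------------------------

num_or_null <- function(x) if (is.na(x)) NULL else x
chr_or_null <- function(x) if (is.na(x) || !nzchar(x)) NULL else x

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    r <- model$metabolites[i, ]
    drop_nulls(list(compartment = r$compartment, dgf = num_or_null(r$dgf),
                    formula = chr_or_null(r$formula), id = r$id,
                    name = r$name))
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- model$stoich[[r$id]]
    s <- s[order(names(s))]
    drop_nulls(list(gpr = chr_or_null(r$gpr), id = r$id, lb = r$lb,
                    metabolites = as.list(s),
                    subsystem = chr_or_null(r$subsystem), ub = r$ub))
  })
  ann <- model$annotations
  if (length(ann)) ann <- ann[order(names(ann))]
  doc <- list(annotations = ann, id = model$id, metabolites = mets,
              objective = model$objective, reactions = rxns,
              schema = "cocultr-model/1")
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null")
  writeLines(json, path)
}

drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  if (is.null(doc$schema) || !startsWith(doc$schema, "cocultr-model/"))
    stop("parse error in ", path, ": missing or unknown schema field")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% compartment_of(m$id),
               formula = m$formula %||% NA_character_,
               dgf = m$dgf %||% NA_real_, stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id, lb = r$lb, ub = r$ub, gpr = r$gpr %||% "",
               subsystem = r$subsystem %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r)
    unlist(r$metabolites))
  names(stoich) <- rxns$id
  metabolic_model(mets, rxns, stoich, objective = doc$objective,
                  id = doc$id %||% "model",
                  annotations = doc$annotations %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- SBML Level 3 + FBC v2 -------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

sbml_num <- function(x) {
  ifelse(is.infinite(x), ifelse(x > 0, "INF", "-INF"),
         formatC(x, format = "g", digits = 17))
}

write_model_sbml <- function(model, path) {
  mets <- model$metabolites
  rxns <- model$reactions
  genes <- sort(unique(unlist(lapply(rxns$gpr, gpr_genes))))
  gmap <- stats::setNames(paste0("G_", seq_along(genes)), genes)
  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="false">', xml_escape(model$id)),
    '    <listOfCompartments>')
  for (cp in sort(unique(mets$compartment)))
    L <- c(L, sprintf('      <compartment id="%s" constant="true"/>',
                      xml_escape(cp)))
  L <- c(L, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(mets))) {
    attrs <- sprintf(paste0('id="%s" name="%s" compartment="%s" ',
                            'hasOnlySubstanceUnits="false" ',
                            'boundaryCondition="false" constant="false"'),
                     xml_escape(mets$id[i]), xml_escape(mets$name[i]),
                     xml_escape(mets$compartment[i]))
    if (!is.na(mets$formula[i]))
      attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"',
                                     xml_escape(mets$formula[i])))
    if (!is.na(mets$dgf[i])) {
      L <- c(L, sprintf('      <species %s>', attrs),
             paste0('        <annotation><thermo xmlns="https://cocultr/ns" ',
                    sprintf('dgf="%s"/></annotation>', sbml_num(mets$dgf[i]))),
             '      </species>')
    } else L <- c(L, sprintf('      <species %s/>', attrs))
  }
  L <- c(L, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_len(nrow(rxns)))
    L <- c(L,
      sprintf('      <parameter id="lb_%d" value="%s" constant="true"/>',
              i, sbml_num(rxns$lb[i])),
      sprintf('      <parameter id="ub_%d" value="%s" constant="true"/>',
              i, sbml_num(rxns$ub[i])))
  L <- c(L, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(rxns))) {
    rid <- rxns$id[i]
    s <- model$stoich[[rid]]
    subs <- if (!is.na(rxns$subsystem[i]))
      sprintf(' name="%s"', xml_escape(rxns$subsystem[i])) else ""
    L <- c(L, sprintf(paste0('      <reaction id="%s"%s reversible="%s" ',
                             'fast="false" fbc:lowerFluxBound="lb_%d" ',
                             'fbc:upperFluxBound="ub_%d">'),
                      xml_escape(rid), subs,
                      tolower(rxns$lb[i] < 0), i, i))
    tree <- parse_gpr(rxns$gpr[i])
    if (!is.null(tree))
      L <- c(L, '        <fbc:geneProductAssociation>',
             sbml_gpr_xml(tree, gmap, indent = 10),
             '        </fbc:geneProductAssociation>')
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      L <- c(L, '        <listOfReactants>')
      for (k in order(names(reac)))
        L <- c(L, sprintf(paste0('          <speciesReference species="%s" ',
                                 'stoichiometry="%s" constant="true"/>'),
                          xml_escape(names(reac)[k]), sbml_num(-reac[[k]])))
      L <- c(L, '        </listOfReactants>')
    }
    if (length(prod)) {
      L <- c(L, '        <listOfProducts>')
      for (k in order(names(prod)))
        L <- c(L, sprintf(paste0('          <speciesReference species="%s" ',
                                 'stoichiometry="%s" constant="true"/>'),
                          xml_escape(names(prod)[k]), sbml_num(prod[[k]])))
      L <- c(L, '        </listOfProducts>')
    }
    L <- c(L, '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>',
         sprintf('    <fbc:listOfObjectives fbc:activeObjective="obj">'),
         '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
         '        <fbc:listOfFluxObjectives>',
         sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                        'fbc:coefficient="1"/>'), xml_escape(model$objective)),
         '        </fbc:listOfFluxObjectives>',
         '      </fbc:objective>',
         '    </fbc:listOfObjectives>')
  if (length(genes)) {
    L <- c(L, '    <fbc:listOfGeneProducts>')
    for (g in genes)
      L <- c(L, sprintf(paste0('      <fbc:geneProduct fbc:id="%s" ',
                               'fbc:label="%s"/>'),
                        gmap[[g]], xml_escape(g)))
    L <- c(L, '    </fbc:listOfGeneProducts>')
  }
  L <- c(L, '  </model>', '</sbml>')
  writeLines(L, path)
}

sbml_gpr_xml <- function(tree, gmap, indent) {
  pad <- strrep(" ", indent)
  if (is.character(tree))
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   pad, gmap[[tree]]))
  tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
  c(sprintf("%s<%s>", pad, tag),
    unlist(lapply(tree$args, sbml_gpr_xml, gmap = gmap,
                  indent = indent + 2)),
    sprintf("%s</%s>", pad, tag))
}

sbml_value <- function(x) {
  if (is.na(x) || x == "") return(NA_real_)
  if (x == "INF") return(Inf)
  if (x == "-INF") return(-Inf)
  suppressWarnings(as.numeric(x))
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing"))
    stop("parse error in ", path, ": no <model> element")
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- do.call(rbind, lapply(sp_nodes, function(n) {
    raw <- xml2::xml_attr(n, "id")
    nm <- xml2::xml_attr(n, "name")
    comp_attr <- xml2::xml_attr(n, "compartment")
    tag <- compartment_of(raw)
    if (nzchar(tag) && !is.na(comp_attr) && comp_attr != tag) {
      warning("species ", raw, ": compartment attribute '", comp_attr,
              "' overrides bracket suffix '", tag, "'", call. = FALSE)
      id <- paste0(strip_compartment(raw), "[", comp_attr, "]")
      tag <- comp_attr
    } else if (nzchar(tag)) {
      id <- raw
    } else if (!is.na(comp_attr)) {
      id <- paste0(raw, "[", comp_attr, "]")
      tag <- comp_attr
    } else stop("species ", raw, " has no compartment")
    th <- xml2::xml_find_first(n, ".//thermo")
    dgf <- if (inherits(th, "xml_missing")) NA_real_
           else sbml_value(xml2::xml_attr(th, "dgf"))
    data.frame(id = id, name = if (is.na(nm)) id else nm, compartment = tag,
               formula = xml2::xml_attr(n, "chemicalFormula"),
               dgf = dgf, stringsAsFactors = FALSE)
  }))
  raw_ids <- vapply(sp_nodes, function(n) xml2::xml_attr(n, "id"),
                    character(1))
  id_map <- stats::setNames(mets$id, raw_ids)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(
    vapply(params, function(n) sbml_value(xml2::xml_attr(n, "value")),
           numeric(1)),
    vapply(params, function(n) xml2::xml_attr(n, "id"), character(1)))
  gp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  glabel <- stats::setNames(
    vapply(gp_nodes, function(n) {
      lb <- xml2::xml_attr(n, "label")
      if (is.na(lb)) xml2::xml_attr(n, "id") else lb
    }, character(1)),
    vapply(gp_nodes, function(n) xml2::xml_attr(n, "id"), character(1)))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- list(); stoich <- list()
  for (n in rx_nodes) {
    rid <- xml2::xml_attr(n, "id")
    lbp <- xml2::xml_attr(n, "lowerFluxBound")
    ubp <- xml2::xml_attr(n, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]] else
      if (isTRUE(xml2::xml_attr(n, "reversible") == "true")) -Inf else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else Inf
    s <- numeric(0)
    for (sr in xml2::xml_find_all(n, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      sp <- if (sp %in% names(id_map)) id_map[[sp]] else sp
      if (!sp %in% mets$id)
        stop("validation error in ", path, ": reaction ", rid,
             " references unknown species ", sp)
      s[sp] <- (if (sp %in% names(s)) s[[sp]] else 0) -
        sbml_value(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(n, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      sp <- if (sp %in% names(id_map)) id_map[[sp]] else sp
      if (!sp %in% mets$id)
        stop("validation error in ", path, ": reaction ", rid,
             " references unknown species ", sp)
      s[sp] <- (if (sp %in% names(s)) s[[sp]] else 0) +
        sbml_value(xml2::xml_attr(sr, "stoichiometry"))
    }
    s <- s[s != 0]
    gpa <- xml2::xml_find_first(n, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else
      deparse_gpr(sbml_gpr_tree(xml2::xml_find_first(gpa, "./*"), glabel))
    nm <- xml2::xml_attr(n, "name")
    rxns[[rid]] <- data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                              subsystem = if (is.na(nm)) NA_character_
                                          else nm,
                              stringsAsFactors = FALSE)
    stoich[[rid]] <- s
  }
  obj_node <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  objective <- if (!inherits(obj_node, "xml_missing"))
    xml2::xml_attr(obj_node, "reaction") else names(rxns)[1]
  metabolic_model(mets, do.call(rbind, rxns), stoich, objective = objective,
                  id = xml2::xml_attr(mdl, "id") %||% "model")
}

sbml_gpr_tree <- function(node, glabel) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(if (g %in% names(glabel)) unname(glabel[[g]]) else g)
  }
  kids <- lapply(xml2::xml_find_all(node, "./*"), sbml_gpr_tree,
                 glabel = glabel)
  list(op = nm, args = kids)
}
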