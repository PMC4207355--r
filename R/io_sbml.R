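# SBML Level 3 Version 1 + FBC version 2 reader/writer built on xml2.
# Scope: species with fbc:charge / fbc:chemicalFormula, flux bounds as
# fbc:lowerFluxBound / fbc:upperFluxBound parameters, gene-product
# associations as fbc:and / fbc:or / fbc:geneProductRef trees.  A
# GENE_ASSOCIATION note in the classic COBRA style is honored as a
# fallback when a reaction has no FBC association.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_sbml_model <- function(network, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "true")

  comps <- unique(network$metabolites$compartment)
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cc in comps)
    xml2::xml_add_child(lc, "compartment", id = cc, constant = "true")

  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$metabolites))) {
    m <- network$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
                              compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(m$charge))
      xml2::xml_set_attr(sp, "fbc:charge", format(m$charge, digits = 17))
    if (!is.na(m$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
  }

  genes <- network$genes
  if (length(genes)) {
    lg <- xml2::xml_add_child(model, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = sbml_gene_id(g), "fbc:label" = g)
  }

  lp <- xml2::xml_add_child(model, "listOfParameters")
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(network$reactions))) {
    r <- network$reactions[j, ]
    plb <- paste0("lb_", j); pub <- paste0("ub_", j)
    xml2::xml_add_child(lp, "parameter", id = plb,
                        value = format(r$lower, digits = 17),
                        constant = "true")
    xml2::xml_add_child(lp, "parameter", id = pub,
                        value = format(r$upper, digits = 17),
                        constant = "true")
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id, name = r$name,
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false",
                              "fbc:lowerFluxBound" = plb,
                              "fbc:upperFluxBound" = pub)
    sto <- reaction_stoichiometry(network, r$id)
    rea <- sto[sto < 0]; pro <- sto[sto > 0]
    if (length(rea)) {
      node <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(rea))
        xml2::xml_add_child(node, "speciesReference", species = m,
                            stoichiometry = format(-rea[[m]], digits = 17),
                            constant = "true")
    }
    if (length(pro)) {
      node <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(pro))
        xml2::xml_add_child(node, "speciesReference", species = m,
                            stoichiometry = format(pro[[m]], digits = 17),
                            constant = "true")
    }
    g <- network$gpr[[r$id]]
    if (!is.null(g)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      write_gpr_node(ga, g)
    }
  }
  if (!is.null(network$biomass)) {
    lo <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = network$biomass,
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_gene_id <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))

write_gpr_node <- function(parent, node) {
  if (node$kind == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sbml_gene_id(node$gene),
                        "fbc:label" = node$gene)
  } else {
    el <- xml2::xml_add_child(parent, paste0("fbc:", node$kind))
    for (ch in node$children) write_gpr_node(el, ch)
  }
}

read_sbml_model <- function(path, default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML file ", sQuote(path), ": ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing"))
    stop("malformed SBML file ", sQuote(path), ": no <model> element")

  attr_of <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) xml2::xml_attr(node, paste0("fbc:", name)) else v
  }

  sp <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (!length(sp))
    stop("invalid model ", sQuote(path), ": no species (N = 0)")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "c",
                         xml2::xml_attr(sp, "compartment")),
    formula = vapply(sp, attr_of, "", name = "chemicalFormula"),
    charge = suppressWarnings(as.numeric(
      vapply(sp, attr_of, "", name = "charge"))),
    stringsAsFactors = FALSE)
  if (anyNA(mets$id) || any(!nzchar(mets$id)))
    stop("malformed SBML file ", sQuote(path), ": species without id")

  params <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rxns <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (!length(rxns))
    stop("invalid model ", sQuote(path), ": no reactions (M = 0)")
  ids <- xml2::xml_attr(rxns, "id")
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("malformed SBML file ", sQuote(path), ": reaction without id")
  if (anyDuplicated(ids))
    stop("duplicate reaction id in ", sQuote(path), ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  # gene-product id -> label mapping
  gps <- xml2::xml_find_all(model, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  glabel <- stats::setNames(
    ifelse(is.na(vapply(gps, attr_of, "", name = "label")),
           sub("^G_", "", vapply(gps, attr_of, "", name = "id")),
           vapply(gps, attr_of, "", name = "label")),
    vapply(gps, attr_of, "", name = "id"))

  sto <- list(); lo <- up <- numeric(length(rxns)); gprs <- character(length(rxns))
  for (j in seq_along(rxns)) {
    rn <- rxns[[j]]
    s <- numeric(0)
    for (ref in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      m <- xml2::xml_attr(ref, "species")
      s[m] <- (if (m %in% names(s)) s[[m]] else 0) -
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      m <- xml2::xml_attr(ref, "species")
      s[m] <- (if (m %in% names(s)) s[[m]] else 0) +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    if (!length(s))
      stop("malformed SBML file ", sQuote(path), ": reaction ",
           sQuote(ids[j]), " has empty stoichiometry")
    sto[[ids[j]]] <- s
    plb <- attr_of(rn, "lowerFluxBound"); pub <- attr_of(rn, "upperFluxBound")
    rev_attr <- identical(tolower(xml2::xml_attr(rn, "reversible")), "true")
    lo[j] <- if (!is.na(plb) && plb %in% names(pval)) pval[[plb]] else
      if (rev_attr) -default_bound else 0
    up[j] <- if (!is.na(pub) && pub %in% names(pval)) pval[[pub]] else
      default_bound
    ga <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gprs[j] <- if (!inherits(ga, "xml_missing")) {
      node <- read_gpr_node(xml2::xml_children(ga)[[1]], glabel, attr_of)
      deparse_gpr(node)
    } else {
      # classic COBRA notes fallback
      note <- xml2::xml_find_first(rn, ".//*[contains(text(),'GENE_ASSOCIATION')]")
      if (!inherits(note, "xml_missing"))
        trimws(sub(".*GENE_ASSOCIATION:", "", xml2::xml_text(note)))
      else ""
    }
  }

  biomass <- NULL
  fo <- xml2::xml_find_first(model, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    b <- attr_of(fo, "reaction")
    if (!is.na(b) && b %in% ids) biomass <- b
  }

  metabolic_network(
    metabolites = mets,
    reactions = data.frame(id = ids, lower = lo, upper = up, gpr = gprs,
                           stringsAsFactors = FALSE),
    stoichiometry = sto, biomass = biomass, default_bound = default_bound)
}

read_gpr_node <- function(node, glabel, attr_of) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    lbl <- attr_of(node, "label")
    if (is.na(lbl)) {
      gid <- attr_of(node, "geneProduct")
      lbl <- if (gid %in% names(glabel)) glabel[[gid]] else sub("^G_", "", gid)
    }
    return(gpr_leaf(lbl))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), read_gpr_node,
                   glabel = glabel, attr_of = attr_of)
    return(gpr_node(nm, kids))
  }
  stop("unsupported gene-association element: <", nm, ">")
}
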