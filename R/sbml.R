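# SBML Level 3 + FBC v2 input/output, covering the subset constraint-based
# models use: species, reactions with stoichiometry, flux bounds through fbc
# parameters, gene-product associations, and the active objective.

SBML_NS <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

#' Read a metabolic model from an SBML Level 3 (FBC) file
#'
#' Extracts stoichiometry, flux bounds (via the fbc flux-bound parameters),
#' gene-product associations and the active objective. Species flagged as
#' boundary condition are dropped from the stoichiometric matrix, as usual
#' for constraint-based analysis.
#'
#' @param path path to an SBML L3 file with the FBC package.
#' @return a [metabolic_model()].
#' @export
read_sbml_fbc <- function(path) {
  doc <- xml2::read_xml(path)
  mdl <- xml2::xml_find_first(doc, "./s:model", SBML_NS)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- "model"

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", SBML_NS)
  sp_id <- xml2::xml_attr(sp, "id")
  sp_boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_boundary]

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", SBML_NS)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  gps <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                            SBML_NS)
  gp_id <- xml2::xml_attr(gps, "fbc:id", ns = SBML_NS)
  gp_label <- xml2::xml_attr(gps, "fbc:label", ns = SBML_NS)
  gp_label[is.na(gp_label)] <- gp_id[is.na(gp_label)]
  gp_map <- stats::setNames(gp_label, gp_id)

  rxns <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", SBML_NS)
  if (!length(rxns)) stop("no reactions in ", path)
  rx_id <- xml2::xml_attr(rxns, "id")

  nr <- length(rx_id)
  S <- matrix(0, length(mets), nr, dimnames = list(mets, rx_id))
  lb <- ub <- numeric(nr)
  gpr <- character(nr)
  for (i in seq_len(nr)) {
    rn <- rxns[[i]]
    lbref <- xml2::xml_attr(rn, "fbc:lowerFluxBound", ns = SBML_NS)
    ubref <- xml2::xml_attr(rn, "fbc:upperFluxBound", ns = SBML_NS)
    if (is.na(lbref) || is.na(ubref) ||
        is.na(parval[lbref]) || is.na(parval[ubref]))
      stop("reaction ", rx_id[i], " lacks resolvable fbc flux bounds")
    lb[i] <- parval[[lbref]]
    ub[i] <- parval[[ubref]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rn, paste0("./s:", side, "/s:speciesReference"),
                                 SBML_NS)
      if (!length(refs)) next
      sgn <- if (side == "listOfReactants") -1 else 1
      spx <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      keep <- spx %in% mets
      if (any(keep))
        S[spx[keep], i] <- S[spx[keep], i] + sgn * st[keep]
    }
    assoc <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", SBML_NS)
    if (!inherits(assoc, "xml_missing")) {
      if (!length(gp_map))
        stop("reaction ", rx_id[i],
             " has a gene association but the model has no fbc:listOfGeneProducts")
      gpr[i] <- sbml_assoc_to_gpr(xml2::xml_children(assoc)[[1]], gp_map,
                                  rx_id[i])
    } else gpr[i] <- ""
  }

  obj <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    SBML_NS)
  if (inherits(obj, "xml_missing")) stop("no FBC objective in ", path)
  biomass <- xml2::xml_attr(obj, "fbc:reaction", ns = SBML_NS)

  metabolic_model(rx_id, mets, S, lb, ub, gpr, biomass, id = model_id)
}

sbml_assoc_to_gpr <- function(node, gp_map, rxn) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "fbc:geneProduct", ns = SBML_NS)
    lab <- gp_map[ref]
    if (is.na(lab)) stop("reaction ", rxn, ": unknown gene product '", ref, "'")
    return(unname(lab))
  }
  if (!nm %in% c("and", "or"))
    stop("reaction ", rxn, ": malformed gene association node <", nm, ">")
  kids <- vapply(xml2::xml_children(node), sbml_assoc_to_gpr, character(1),
                 gp_map = gp_map, rxn = rxn)
  paste0("(", paste(kids, collapse = paste0(" ", nm, " ")), ")")
}

#' Write a metabolic model to an SBML Level 3 (FBC) file
#'
#' Emits the same subset [read_sbml_fbc()] consumes, so models round-trip
#' losslessly (bounds, GPRs, objective).
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_fbc <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_NS[["s"]], '" xmlns:fbc="', SBML_NS[["fbc"]],
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(model$id), '" fbc:strict="true">'),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (met in model$metabolites)
    lines <- c(lines, paste0(
      '      <species id="', met, '" compartment="c" constant="false"',
      ' boundaryCondition="false" hasOnlySubstanceUnits="false"/>'))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  nr <- length(model$reactions)
  for (i in seq_len(nr)) {
    lines <- c(lines,
      sprintf('      <parameter id="bnd_lb_%d" value="%.17g" constant="true"/>', i, model$lb[i]),
      sprintf('      <parameter id="bnd_ub_%d" value="%.17g" constant="true"/>', i, model$ub[i]))
  }
  lines <- c(lines, '    </listOfParameters>')
  genes <- model$genes
  if (length(genes)) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>')
    for (g in genes)
      lines <- c(lines, paste0('      <fbc:geneProduct fbc:id="gp_', g,
                               '" fbc:label="', g, '"/>'))
    lines <- c(lines, '    </fbc:listOfGeneProducts>')
  }
  lines <- c(lines, '    <listOfReactions>')
  for (i in seq_len(nr)) {
    rx <- model$reactions[i]
    lines <- c(lines, paste0(
      '      <reaction id="', rx, '" reversible="',
      tolower(model$lb[i] < 0), '" fast="false" fbc:lowerFluxBound="bnd_lb_',
      i, '" fbc:upperFluxBound="bnd_ub_', i, '">'))
    col <- model$S[, rx]
    for (side in c(-1, 1)) {
      sel <- which(sign(col) == side)
      if (!length(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, paste0('        <', tag, '>'))
      for (k in sel)
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
          model$metabolites[k], abs(col[k])))
      lines <- c(lines, paste0('        </', tag, '>'))
    }
    tree <- model$gpr_tree[[rx]]
    if (!is.null(tree)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 sbml_gpr_to_assoc(tree, indent = "          "),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    paste0('          <fbc:fluxObjective fbc:reaction="', model$biomass,
           '" fbc:coefficient="1"/>'),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

sbml_gpr_to_assoc <- function(expr, indent = "") {
  if (is.character(expr))
    return(paste0(indent, '<fbc:geneProductRef fbc:geneProduct="gp_', expr,
                  '"/>'))
  inner <- unlist(lapply(expr$args, sbml_gpr_to_assoc,
                         indent = paste0(indent, "  ")))
  c(paste0(indent, "<fbc:", expr$op, ">"), inner,
    paste0(indent, "</fbc:", expr$op, ">"))
}
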