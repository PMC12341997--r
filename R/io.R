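#' Read and write metabolic models
#'
#' Two on-disk formats are supported. The JSON dialect (documented in
#' `inst/extdata/model-schema.md`) round-trips every field of a
#' `metabolic_model` exactly. The SBML reader/writer covers a pragmatic
#' subset of Level 3 + FBC v2: species (compartment, formula, charge),
#' reactions with bounds, gene-product associations and the (maximization)
#' objective. Unsupported constructs raise an error instead of being dropped
#' silently.
#'
#' @param path File path.
#' @param format `"json"` or `"sbml"`; guessed from the extension by default.
#' @return `read_model()` returns a validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' @rdname read_model
#' @param model A `metabolic_model`.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format, json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  mets <- lapply(j$metabolites, function(m) {
    metabolite(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment,
               formula = if (is.null(m$formula)) "" else m$formula,
               charge = if (is.null(m$charge)) NA_integer_ else m$charge)
  })
  rxns <- lapply(j$reactions, function(r) {
    if (is.null(r$lower_bound) || is.null(r$upper_bound)) {
      stop(sprintf("reaction '%s': missing bounds", r$id), call. = FALSE)
    }
    reaction(id = r$id,
             name = if (is.null(r$name)) r$id else r$name,
             stoichiometry = unlist(r$stoichiometry),
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             gpr = if (is.null(r$gpr)) NULL else r$gpr,
             subsystem = if (is.null(r$subsystem)) "" else r$subsystem)
  })
  metabolic_model(mets, rxns,
                  objective = j$objective$reaction,
                  id = if (is.null(j$id)) "model" else j$id)
}

write_model_json <- function(model, path) {
  validate_model(model)
  j <- list(
    id = model$id,
    metabolites = lapply(model$metabolites, function(m) {
      out <- list(id = m$id, name = m$name, compartment = m$compartment,
                  formula = m$formula)
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name,
           stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gpr = gpr_to_string(r$gpr), subsystem = r$subsystem)
    }),
    objective = if (is.null(model$objective)) NULL else
      list(reaction = model$objective, sense = "maximize")
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

# --- SBML Level 3 + FBC v2 subset ------------------------------------------

SBML_NS <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

sbml_mangle <- function(id) {
  # SBML SIds must match [A-Za-z_][A-Za-z0-9_]*; model ids may contain
  # brackets etc. Encode offending characters as __uXXXX__.
  chars <- strsplit(id, "")[[1]]
  ok <- grepl("[A-Za-z0-9_]", chars)
  chars[!ok] <- vapply(chars[!ok],
                       function(ch) sprintf("__u%04d__", utf8ToInt(ch)),
                       character(1))
  out <- paste0(chars, collapse = "")
  if (grepl("^[0-9]", out)) out <- paste0("_", out)
  out
}

sbml_unmangle <- function(sid) {
  out <- gsub("__u([0-9]{4})__", "\\\\u\\1;", sid)
  while (grepl("\\\\u[0-9]{4};", out)) {
    m <- regmatches(out, regexpr("\\\\u[0-9]{4};", out))
    ch <- intToUtf8(as.integer(substr(m, 3, 6)))
    out <- sub("\\\\u[0-9]{4};", ch, out, fixed = FALSE)
  }
  sub("^_([0-9])", "\\1", out)
}

write_model_sbml <- function(model, path) {
  validate_model(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS[["s"]], SBML_NS[["fbc"]]),
    sprintf('  <model id="%s" fbc:strict="true">', esc(sbml_mangle(model$id))),
    '    <listOfCompartments>')
  comps <- unique(vapply(model$metabolites, `[[`, character(1), "compartment"))
  lines <- c(lines,
             sprintf('      <compartment id="%s" constant="true"/>', comps),
             '    </listOfCompartments>',
             '    <listOfSpecies>')
  for (m in model$metabolites) {
    attrs <- sprintf('id="%s" name="%s" compartment="%s" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"',
                     esc(sbml_mangle(m$id)), esc(m$name), m$compartment)
    if (nzchar(m$formula)) attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    if (!is.na(m$charge)) attrs <- paste0(attrs, sprintf(' fbc:charge="%d"', m$charge))
    lines <- c(lines, sprintf('      <species %s/>', attrs))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  bnds <- bounds_matrix(model)
  ubnd <- sort(unique(as.numeric(bnds)))
  numfmt <- function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15)
  pid <- function(v) sprintf("bnd_%s", sbml_mangle(gsub("-", "m", numfmt(v))))
  lines <- c(lines,
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     vapply(ubnd, pid, character(1)),
                     vapply(ubnd, numfmt, character(1))),
             '    </listOfParameters>')
  genes <- sort(unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr)))))
  if (length(genes)) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
               sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                       vapply(genes, sbml_mangle, character(1)), esc(genes)),
               '    </fbc:listOfGeneProducts>')
  }
  gpa_xml <- function(tree, indent) {
    pad <- strrep(" ", indent)
    if (tree$kind == "GENE") {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     pad, sbml_mangle(tree$gene)))
    }
    tag <- if (tree$kind == "AND") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(tree$children, gpa_xml, indent = indent + 2L)),
      sprintf("%s</%s>", pad, tag))
  }
  lines <- c(lines, '    <listOfReactions>')
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(sbml_mangle(r$id)), esc(r$name),
      tolower(r$lower_bound < 0), pid(r$lower_bound), pid(r$upper_bound)))
    subs <- r$stoichiometry[r$stoichiometry < 0]
    prods <- r$stoichiometry[r$stoichiometry > 0]
    if (length(subs)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         vapply(names(subs), sbml_mangle, character(1)),
                         vapply(-unname(subs), numfmt, character(1))),
                 '        </listOfReactants>')
    }
    if (length(prods)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         vapply(names(prods), sbml_mangle, character(1)),
                         vapply(unname(prods), numfmt, character(1))),
                 '        </listOfProducts>')
    }
    if (!is.null(r$gpr)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpa_xml(r$gpr, 10L),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (!is.null(model$objective)) {
    lines <- c(lines,
               '    <fbc:listOfObjectives fbc:activeObjective="obj">',
               '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
               '        <fbc:listOfFluxObjectives>',
               sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                       sbml_mangle(model$objective)),
               '        </fbc:listOfFluxObjectives>',
               '      </fbc:objective>',
               '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  mdl <- xml2::xml_find_first(doc, "./s:model", SBML_NS)
  if (inherits(mdl, "xml_missing")) stop("SBML file has no <model>", call. = FALSE)
  unsupported <- c("listOfRules", "listOfEvents", "listOfConstraints",
                   "listOfFunctionDefinitions")
  for (tag in unsupported) {
    if (!inherits(xml2::xml_find_first(mdl, paste0("./s:", tag), SBML_NS),
                  "xml_missing")) {
      stop(sprintf("unsupported SBML construct: %s", tag), call. = FALSE)
    }
  }
  params <- xml2::xml_find_all(mdl, "./s:listOfParameters/s:parameter", SBML_NS)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  gps <- xml2::xml_find_all(mdl, "./fbc:listOfGeneProducts/fbc:geneProduct", SBML_NS)
  glabels <- stats::setNames(xml2::xml_attr(gps, "fbc:label", ns = SBML_NS),
                             xml2::xml_attr(gps, "fbc:id", ns = SBML_NS))
  mets <- lapply(xml2::xml_find_all(mdl, "./s:listOfSpecies/s:species", SBML_NS),
                 function(sp) {
    ch <- xml2::xml_attr(sp, "fbc:charge", ns = SBML_NS)
    metabolite(id = sbml_unmangle(xml2::xml_attr(sp, "id")),
               name = xml2::xml_attr(sp, "name") %||% "",
               compartment = xml2::xml_attr(sp, "compartment"),
               formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = SBML_NS) %||% "",
               charge = if (is.na(ch)) NA_integer_ else as.integer(ch))
  })
  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "fbc:geneProduct", ns = SBML_NS)
      lbl <- glabels[gid]
      return(gpr_leaf(if (is.na(lbl)) sbml_unmangle(sub("^G_", "", gid)) else unname(lbl)))
    }
    kids <- lapply(xml2::xml_children(node), parse_gpa)
    gpr_node(toupper(nm), kids)
  }
  rxns <- lapply(xml2::xml_find_all(mdl, "./s:listOfReactions/s:reaction", SBML_NS),
                 function(rx) {
    rid <- sbml_unmangle(xml2::xml_attr(rx, "id"))
    lb_id <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns = SBML_NS)
    ub_id <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns = SBML_NS)
    if (is.na(lb_id) || is.na(ub_id) || is.na(pvals[lb_id]) || is.na(pvals[ub_id])) {
      stop(sprintf("reaction '%s': missing fbc flux bounds", rid), call. = FALSE)
    }
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(rx, xp, SBML_NS)
      stats::setNames(sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
                      vapply(xml2::xml_attr(nodes, "species"), sbml_unmangle,
                             character(1)))
    }
    st <- c(refs("./s:listOfReactants/s:speciesReference", -1),
            refs("./s:listOfProducts/s:speciesReference", +1))
    gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation", SBML_NS)
    gpr <- if (inherits(gpa, "xml_missing")) NULL else
      parse_gpa(xml2::xml_child(gpa))
    reaction(id = rid, name = xml2::xml_attr(rx, "name") %||% rid,
             stoichiometry = st,
             lower_bound = unname(pvals[lb_id]), upper_bound = unname(pvals[ub_id]),
             gpr = gpr)
  })
  obj_node <- xml2::xml_find_first(
    mdl, "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    SBML_NS)
  objective <- if (inherits(obj_node, "xml_missing")) NULL else
    sbml_unmangle(xml2::xml_attr(obj_node, "fbc:reaction", ns = SBML_NS))
  metabolic_model(mets, rxns, objective = objective,
                  id = sbml_unmangle(xml2::xml_attr(mdl, "id") %||% "model"))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
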