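DNFBA_XMLNS <- "https://example.org/dnfba/annotations"

#' @noRd
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a model as SBML Level 3 Version 1
#'
#' Emits SBML L3V1 with flux bounds encoded through the flux-balance
#' constraints (fbc) package: one constant parameter per bound, referenced
#' from each reaction's `fbc:lowerFluxBound` / `fbc:upperFluxBound`
#' attributes. Fields of the network representation that core SBML cannot
#' carry (boundary kind, speed tag, reference flux, group labels, currency
#' flags) travel in a package annotation element, so a write/read round
#' trip reproduces the model exactly (provenance excepted). Output is
#' assembled in model order with fixed formatting: writing the same model
#' twice yields byte-identical bytes.
#'
#' @param model a `cell_model` (or a `model_document`, whose model is
#'   written).
#' @param sink file path or connection.
#' @export
write_sbml_model <- function(model, sink) {
  if (inherits(model, "model_document")) model <- model$model
  stopifnot(inherits(model, "cell_model"))
  validate_cell_model(model)
  num <- function(x) {
    s <- format_lossless(x)
    s[s == "Inf"] <- "INF"
    s
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    "  <model id=\"dnfba_model\" fbc:strict=\"false\">",
    "    <listOfCompartments>")
  for (cp in COMPARTMENTS)
    out <- c(out, sprintf("      <compartment id=\"%s\" constant=\"true\"/>",
                          cp))
  out <- c(out, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    out <- c(out, sprintf(paste0(
      "      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
      "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
      "constant=\"false\">"),
      xml_escape(m$id), xml_escape(m$name), m$compartment),
      "        <annotation>",
      sprintf("          <dnfba:meta xmlns:dnfba=\"%s\" isCurrency=\"%s\"/>",
              DNFBA_XMLNS, tolower(m$is_currency)),
      "        </annotation>",
      "      </species>")
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfParameters>")
  for (r in model$reactions) {
    out <- c(out,
      sprintf("      <parameter id=\"lb_%s\" value=\"%s\" constant=\"true\"/>",
              r$id, num(r$lower_bound)),
      sprintf("      <parameter id=\"ub_%s\" value=\"%s\" constant=\"true\"/>",
              r$id, if (is.finite(r$upper_bound)) num(r$upper_bound) else
                "INF"))
  }
  out <- c(out, "    </listOfParameters>", "    <listOfReactions>")
  for (r in model$reactions) {
    out <- c(out, sprintf(paste0(
      "      <reaction id=\"%s\" name=\"%s\" reversible=\"false\" ",
      "fast=\"false\" fbc:lowerFluxBound=\"lb_%s\" ",
      "fbc:upperFluxBound=\"ub_%s\">"),
      xml_escape(r$id), xml_escape(r$name), r$id, r$id))
    meta <- sprintf(paste0(
      "        <annotation>\n          <dnfba:meta xmlns:dnfba=\"%s\" ",
      "boundaryKind=\"%s\" speedTag=\"%s\"%s%s/>\n        </annotation>"),
      DNFBA_XMLNS, r$boundary_kind, r$speed_tag,
      if (is.finite(r$best_reference_flux))
        sprintf(" bestReferenceFlux=\"%s\"", num(r$best_reference_flux))
      else "",
      if (length(r$groups))
        sprintf(" groups=\"%s\"",
                xml_escape(paste(gsub("αSYN", "aSYN", r$groups, fixed = TRUE),
                                 collapse = ";")))
      else "")
    out <- c(out, meta)
    st <- r$stoichiometry
    for (side in c(-1, 1)) {
      sel <- if (side < 0) st < 0 else st > 0
      if (!any(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      out <- c(out, sprintf("        <%s>", tag))
      for (mid in names(st)[sel])
        out <- c(out, sprintf(paste0(
          "          <speciesReference species=\"%s\" stoichiometry=\"%s\" ",
          "constant=\"true\"/>"), xml_escape(mid), num(abs(st[[mid]]))))
      out <- c(out, sprintf("        </%s>", tag))
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>")
  con <- if (is.character(sink)) file(sink, open = "wb") else sink
  if (is.character(sink)) on.exit(close(con))
  writeLines(out, con, useBytes = FALSE, sep = "\n")
  invisible(sink)
}

#' Read a model from SBML (Level 2 or Level 3)
#'
#' Builds one metabolite per species and one reaction per SBML reaction;
#' kinetic laws are ignored except as a carrier of flux bounds. Bounds are
#' resolved in order of preference: fbc `lowerFluxBound`/`upperFluxBound`
#' parameter references (Level 3), `LOWER_BOUND`/`UPPER_BOUND` local
#' kinetic-law parameters (the common Level 2 constraint encoding), else
#' the default policy range 0-100 uM/h with a warning. Boundary kinds are
#' taken from the package annotation when present, otherwise inferred from
#' the stoichiometry sign pattern or the conventional `...IN`/`...OUT` id
#' suffixes of exchange reactions. MIRIAM-style resource annotations are
#' collected verbatim into the document's annotation map; they are
#' preserved, not interpreted.
#'
#' @param source file path, URL-free connection, or raw XML string.
#' @param provenance provenance recorded on the model (default
#'   `"deposited"`).
#' @return object of class `"model_document"`: `model` (a validated
#'   `cell_model`), `sbml_level_version` (e.g. `"L3V1"`), `annotations`
#'   (named list: species/reaction id -> character vector of resource
#'   URIs).
#' @export
read_sbml_model <- function(source, provenance = "deposited") {
  doc <- tryCatch(xml2::read_xml(source),
                  error = function(e) stop("parse error: not well-formed ",
                                           "SBML XML: ", conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (root != "sbml")
    stop("parse error: root element is <", root, ">, expected <sbml>")
  level <- xml2::xml_attr(doc, "level")
  version <- xml2::xml_attr(doc, "version")
  if (!level %in% c("2", "3"))
    stop("parse error: unsupported SBML level '", level,
         "' on element <sbml>")
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing"))
    stop("parse error: missing <model> element")

  first_attr <- function(node, names) {
    for (nm in names) {
      v <- xml2::xml_attr(node, nm)
      if (!is.na(v)) return(v)
    }
    NA_character_
  }
  annotations <- list()
  collect_miriam <- function(node, id) {
    lis <- xml2::xml_find_all(node, ".//*[local-name()='li']")
    uris <- vapply(lis, function(li)
      first_attr(li, c("resource", "rdf:resource")), "")
    uris <- uris[!is.na(uris) & nzchar(uris)]
    if (length(uris)) annotations[[id]] <<- uris
  }
  dn_meta <- function(node) {
    meta <- xml2::xml_find_first(
      node, sprintf(".//*[local-name()='meta' and namespace-uri()='%s']",
                    DNFBA_XMLNS))
    if (inherits(meta, "xml_missing")) NULL else meta
  }

  species <- xml2::xml_find_all(model_node, "./s:listOfSpecies/s:species", ns)
  if (!length(species))
    stop("parse error: model has no <species>")
  mets <- list()
  for (sp in species) {
    id <- xml2::xml_attr(sp, "id")
    comp <- xml2::xml_attr(sp, "compartment")
    if (is.na(comp) || !comp %in% COMPARTMENTS) comp <- "cytosol"
    meta <- dn_meta(sp)
    is_cur <- !is.null(meta) &&
      identical(xml2::xml_attr(meta, "isCurrency"), "true")
    nm <- xml2::xml_attr(sp, "name")
    mets[[length(mets) + 1L]] <-
      metabolite(id, if (is.na(nm)) id else nm, comp, is_cur)
    collect_miriam(sp, id)
  }
  mets <- do.call(rbind, mets)

  params <- xml2::xml_find_all(model_node,
                               "./s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(
    vapply(params, function(p) {
      v <- xml2::xml_attr(p, "value")
      if (identical(v, "INF")) Inf else as.numeric(v)
    }, numeric(1)),
    vapply(params, function(p) xml2::xml_attr(p, "id"), ""))

  rnodes <- xml2::xml_find_all(model_node,
                               "./s:listOfReactions/s:reaction", ns)
  if (!length(rnodes)) stop("parse error: model has no <reaction>")
  default_range <- bounds_policy()$default_range
  defaulted <- character()
  reactions <- list()
  for (rn in rnodes) {
    id <- xml2::xml_attr(rn, "id")
    st <- numeric()
    for (side in c("Reactants", "Products")) {
      refs <- xml2::xml_find_all(
        rn, sprintf("./s:listOf%s/s:speciesReference", side), ns)
      for (ref in refs) {
        mid <- xml2::xml_attr(ref, "species")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        if (is.na(coef))
          stop("model-integrity error: reaction ", id,
               ": unparseable stoichiometry for ", mid)
        signed <- if (side == "Reactants") -coef else coef
        st[mid] <- (st[mid] %||% 0) + signed
      }
    }
    if (!length(st))
      stop("model-integrity error: reaction ", id, " has no stoichiometry")

    lbref <- first_attr(rn, c("fbc:lowerFluxBound", "lowerFluxBound"))
    ubref <- first_attr(rn, c("fbc:upperFluxBound", "upperFluxBound"))
    lb <- ub <- NA_real_
    if (!is.na(lbref) && lbref %in% names(pval)) lb <- pval[[lbref]]
    if (!is.na(ubref) && ubref %in% names(pval)) ub <- pval[[ubref]]
    if (is.na(lb) || is.na(ub)) {
      klp <- xml2::xml_find_all(
        rn, ".//s:kineticLaw//s:parameter | .//s:kineticLaw//s:localParameter",
        ns)
      for (p in klp) {
        pid <- xml2::xml_attr(p, "id")
        v <- as.numeric(xml2::xml_attr(p, "value"))
        if (identical(pid, "LOWER_BOUND") && is.na(lb)) lb <- v
        if (identical(pid, "UPPER_BOUND") && is.na(ub)) ub <- v
      }
    }
    if (is.na(lb)) { lb <- default_range[1]; defaulted <- c(defaulted, id) }
    if (is.na(ub)) { ub <- default_range[2]; defaulted <- c(defaulted, id) }
    lb <- max(lb, 0)   # irreversible network: fluxes are non-negative

    meta <- dn_meta(rn)
    kind <- if (!is.null(meta)) xml2::xml_attr(meta, "boundaryKind") else NA
    if (is.na(kind) || is.null(kind)) {
      kind <- if (all(st > 0)) "input" else if (all(st < 0)) "output"
      else "internal"
      if (kind == "internal" && grepl("IN$", id)) kind <- "input"
      if (kind == "internal" && grepl("OUT$", id)) kind <- "output"
    }
    tag <- if (!is.null(meta)) xml2::xml_attr(meta, "speedTag") else NA
    if (is.na(tag) || is.null(tag)) tag <- "default"
    bref <- if (!is.null(meta)) xml2::xml_attr(meta, "bestReferenceFlux")
    else NA
    grp <- if (!is.null(meta)) xml2::xml_attr(meta, "groups") else NA
    grp <- if (is.na(grp)) character() else
      normalize_group_label(strsplit(grp, ";", fixed = TRUE)[[1]])
    nm <- xml2::xml_attr(rn, "name")
    reactions[[length(reactions) + 1L]] <- reaction(
      id, st, lb, ub, boundary_kind = kind, speed_tag = tag,
      best_reference_flux = if (is.na(bref)) NA_real_ else as.numeric(bref),
      groups = grp, name = if (is.na(nm)) id else nm)
    collect_miriam(rn, id)
  }
  if (length(defaulted))
    warning("no flux bounds found for ", length(unique(defaulted)),
            " reaction(s); default range (", default_range[1], ", ",
            default_range[2], ") applied")
  model <- cell_model(mets, reactions, provenance = provenance)
  structure(list(model = model,
                 sbml_level_version = paste0("L", level, "V", version),
                 annotations = annotations),
            class = "model_document")
}

#' @export
print.model_document <- function(x, ...) {
  cat("model_document (", x$sbml_level_version, "), ",
      length(x$annotations), " annotated elements\n", sep = "")
  print(x$model)
  invisible(x)
}
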