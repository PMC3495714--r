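#' Read a metabolic model from SBML or JSON
#'
#' Two formats are supported. SBML Level 3 with the fbc extension is the
#' interchange format of the constraint-based modeling ecosystem; the reader
#' accepts fbc parameter-referenced flux bounds and falls back to the
#' `reversible` attribute (reversible `[-1000, 1000]`, irreversible
#' `[0, 1000]`) when a reaction carries no explicit numeric bounds. The JSON
#' dialect is a flat, diff-friendly object with `metabolites`, `reactions`
#' (stoichiometry as an id -> coefficient map), `biomass`, `proton_exchange`,
#' and `ratio_constraints` fields.
#'
#' A file that names no biomass or proton exchange loads with those fields
#' unset (a warning is emitted); they are only required at solve / SPF time.
#'
#' @param path Path to the model file.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension).
#' @return An `fbr_model`.
#' @seealso [write_model()]
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  model <- switch(format,
                  json = read_model_json(path),
                  sbml = read_model_sbml(path))
  if (is.na(model$biomass_id) || is.na(model$proton_exchange_id)) {
    warn("Model file names no biomass and/or proton exchange reaction; set them before solving.")
  }
  model
}

#' Write a metabolic model to SBML or JSON
#'
#' Writing then re-reading reproduces metabolite and reaction ids,
#' stoichiometries, and bounds exactly, in both formats. Ratio constraints
#' are serialized in the JSON `ratio_constraints` section and, for SBML, in a
#' package annotation block, and are restored on read.
#'
#' @param model An `fbr_model`.
#' @param path Output path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

# ---- JSON dialect ----------------------------------------------------------

read_model_json <- function(path) {
  raw <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) abort(paste0("JSON parse failure in '", path, "': ",
                                     conditionMessage(e)))
  )
  mets <- purrr::map_dfr(raw$metabolites, function(m) {
    if (is.null(m$id)) abort("JSON model: metabolite without an 'id' element.")
    tibble(id = m$id, name = m$name %||% m$id,
           compartment = m$compartment %||% "cytosol")
  })
  if (nrow(mets) == 0) mets <- empty_metabolite_table()
  rxns <- purrr::map_dfr(raw$reactions, function(r) {
    if (is.null(r$id)) abort("JSON model: reaction without an 'id' element.")
    tibble(
      id = r$id,
      stoichiometry = list(unlist(r$stoichiometry) %||% setNames(numeric(0), character(0))),
      lower_bound = as.numeric(r$lower_bound %||% NA_real_),
      upper_bound = as.numeric(r$upper_bound %||% NA_real_),
      is_exchange = isTRUE(r$is_exchange),
      gene_association = r$gene_association %||% NA_character_
    )
  })
  if (nrow(rxns) == 0) rxns <- empty_reaction_table()
  ratios <- purrr::map(raw$ratio_constraints %||% list(), function(rc) {
    flux_ratio(rc$id, unlist(rc$numerator), unlist(rc$denominator), rc$ratio)
  })
  metabolic_model(
    metabolites = mets, reactions = rxns,
    biomass_id = raw$biomass %||% NA_character_,
    proton_exchange_id = raw$proton_exchange %||% NA_character_,
    ratio_constraints = ratios
  )
}

write_model_json <- function(model, path) {
  as_map <- function(v) if (length(v)) as.list(v) else structure(list(), names = character(0))
  out <- list(
    metabolites = purrr::pmap(model$metabolites, function(id, name, compartment) {
      list(id = id, name = name, compartment = compartment)
    }),
    reactions = purrr::pmap(model$reactions,
      function(id, stoichiometry, lower_bound, upper_bound, is_exchange,
               gene_association) {
        r <- list(id = id, stoichiometry = as_map(stoichiometry),
                  lower_bound = lower_bound, upper_bound = upper_bound,
                  is_exchange = is_exchange)
        if (!is.na(gene_association)) r$gene_association <- gene_association
        r
      }),
    ratio_constraints = purrr::map(unname(model$ratio_constraints), function(rc) {
      list(id = rc$id, numerator = as_map(rc$numerator),
           denominator = as_map(rc$denominator), ratio = rc$ratio)
    })
  )
  if (!is.na(model$biomass_id)) out$biomass <- model$biomass_id
  if (!is.na(model$proton_exchange_id)) out$proton_exchange <- model$proton_exchange_id
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# ---- SBML Level 3 + fbc ----------------------------------------------------

SBML_NS <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  fbr = "https://fbratio.r-lib.invalid/ns"
)

num_attr <- function(x) sprintf("%.17g", x)

read_model_sbml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(paste0("SBML parse failure in '", path, "': ",
                                     conditionMessage(e)))
  )
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  # attribute names must carry whatever prefix the document declared for fbc
  fbc_prefix <- names(ns)[ns == SBML_NS[["fbc"]]][1]
  fbc_attr <- function(node, attr) {
    if (is.na(fbc_prefix)) return(xml2::xml_attr(node, attr))
    xml2::xml_attr(node, paste0(fbc_prefix, ":", attr), ns = ns)
  }
  species <- xml2::xml_find_all(doc, ".//sbml:listOfSpecies/sbml:species", ns)
  mets <- tibble(
    id = xml2::xml_attr(species, "id"),
    name = dplyr::coalesce(xml2::xml_attr(species, "name"),
                           xml2::xml_attr(species, "id")),
    compartment = dplyr::coalesce(xml2::xml_attr(species, "compartment"),
                                  "cytosol")
  )
  if (anyNA(mets$id)) abort("SBML: a <species> element lacks an 'id'.")

  params <- xml2::xml_find_all(doc, ".//sbml:listOfParameters/sbml:parameter", ns)
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfReactions/sbml:reaction", ns)
  rxns <- purrr::map_dfr(rx_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    if (is.na(id)) abort("SBML: a <reaction> element lacks an 'id'.")
    sto <- sbml_stoichiometry(node, ns, id)
    lb_ref <- fbc_attr(node, "lowerFluxBound")
    ub_ref <- fbc_attr(node, "upperFluxBound")
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
          else if (reversible) -FBR_DEFAULT_BOUND else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]]
          else FBR_DEFAULT_BOUND
    tibble(
      id = id, stoichiometry = list(sto), lower_bound = lb, upper_bound = ub,
      is_exchange = length(sto) == 1,
      gene_association = sbml_gene_association(node, ns, fbc_attr)
    )
  })
  if (nrow(rxns) == 0) rxns <- empty_reaction_table()

  biomass <- NA_character_
  obj <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (!inherits(obj, "xml_missing")) {
    biomass <- fbc_attr(obj, "reaction")
  }
  proton <- NA_character_
  pnode <- xml2::xml_find_first(doc, ".//fbr:protonExchange", ns)
  if (!inherits(pnode, "xml_missing")) proton <- xml2::xml_attr(pnode, "reaction")

  ratios <- purrr::map(
    xml2::xml_find_all(doc, ".//fbr:ratioConstraint", ns),
    function(node) {
      flux_ratio(
        xml2::xml_attr(node, "id"),
        parse_side(xml2::xml_attr(node, "numerator")),
        parse_side(xml2::xml_attr(node, "denominator")),
        as.numeric(xml2::xml_attr(node, "value"))
      )
    })

  metabolic_model(metabolites = mets, reactions = rxns, biomass_id = biomass,
                  proton_exchange_id = proton, ratio_constraints = ratios)
}

sbml_stoichiometry <- function(node, ns, rxn_id) {
  get_side <- function(xpath, sign) {
    refs <- xml2::xml_find_all(node, xpath, ns)
    ids <- xml2::xml_attr(refs, "species")
    coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    coef[is.na(coef)] <- 1
    if (anyNA(ids)) {
      abort(paste0("SBML reaction '", rxn_id,
                   "': speciesReference without a 'species' attribute."))
    }
    setNames(sign * coef, ids)
  }
  out <- c(get_side("./sbml:listOfReactants/sbml:speciesReference", -1),
           get_side("./sbml:listOfProducts/sbml:speciesReference", +1))
  if (anyDuplicated(names(out))) out <- tapply(out, names(out), sum)
  out
}

sbml_gene_association <- function(node, ns, fbc_attr) {
  g <- xml2::xml_find_first(
    node, "./fbc:geneProductAssociation/fbc:geneProductRef", ns)
  if (inherits(g, "xml_missing")) NA_character_
  else fbc_attr(g, "geneProduct")
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS[["sbml"]], "xmlns:fbc" = SBML_NS[["fbc"]],
    "xmlns:fbr" = SBML_NS[["fbr"]],
    level = "3", version = "1", "fbc:required" = "false"
  )
  mnode <- xml2::xml_add_child(doc, "model", id = "fbratio_model",
                               "fbc:strict" = "true")

  annot <- xml2::xml_add_child(mnode, "annotation")
  meta <- xml2::xml_add_child(annot, "fbr:fbratio")
  if (!is.na(model$proton_exchange_id)) {
    xml2::xml_add_child(meta, "fbr:protonExchange",
                        reaction = model$proton_exchange_id)
  }
  side_str <- function(w) paste(paste0(names(w), "*", w), collapse = ",")
  for (rc in model$ratio_constraints) {
    xml2::xml_add_child(meta, "fbr:ratioConstraint", id = rc$id,
                        numerator = side_str(rc$numerator),
                        denominator = side_str(rc$denominator),
                        value = num_attr(rc$ratio))
  }

  comp <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cid in unique(c(model$metabolites$compartment, "cytosol"))) {
    xml2::xml_add_child(comp, "compartment", id = cid, constant = "true")
  }

  sp <- xml2::xml_add_child(mnode, "listOfSpecies")
  purrr::pwalk(model$metabolites, function(id, name, compartment) {
    xml2::xml_add_child(sp, "species", id = id, name = name,
                        compartment = compartment,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  })

  par <- xml2::xml_add_child(mnode, "listOfParameters")
  purrr::pwalk(model$reactions[c("id", "lower_bound", "upper_bound")],
    function(id, lower_bound, upper_bound) {
      xml2::xml_add_child(par, "parameter", id = paste0(id, "_lb"),
                          value = num_attr(lower_bound), constant = "true")
      xml2::xml_add_child(par, "parameter", id = paste0(id, "_ub"),
                          value = num_attr(upper_bound), constant = "true")
    })

  rx <- xml2::xml_add_child(mnode, "listOfReactions")
  purrr::pwalk(model$reactions, function(id, stoichiometry, lower_bound,
                                         upper_bound, is_exchange,
                                         gene_association) {
    rnode <- xml2::xml_add_child(
      rx, "reaction", id = id,
      reversible = if (lower_bound < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = paste0(id, "_lb"),
      "fbc:upperFluxBound" = paste0(id, "_ub")
    )
    if (!is.na(gene_association)) {
      gpa <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      xml2::xml_add_child(gpa, "fbc:geneProductRef",
                          "fbc:geneProduct" = gene_association)
    }
    reac <- stoichiometry[stoichiometry < 0]
    prod <- stoichiometry[stoichiometry > 0]
    if (length(reac)) {
      lnode <- xml2::xml_add_child(rnode, "listOfReactants")
      for (i in seq_along(reac)) {
        xml2::xml_add_child(lnode, "speciesReference", species = names(reac)[i],
                            stoichiometry = num_attr(-reac[[i]]),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lnode <- xml2::xml_add_child(rnode, "listOfProducts")
      for (i in seq_along(prod)) {
        xml2::xml_add_child(lnode, "speciesReference", species = names(prod)[i],
                            stoichiometry = num_attr(prod[[i]]),
                            constant = "true")
      }
    }
  })

  if (!is.na(model$biomass_id)) {
    objs <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                               "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = model$biomass_id,
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
}
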