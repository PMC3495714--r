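#' Construct a constraint-based metabolic model
#'
#' A metabolic model couples a metabolite table, a reaction table (each
#' reaction carrying a signed stoichiometry over metabolite ids and a pair of
#' flux bounds), and an ordered set of flux-ratio constraints that are
#' appended to the stoichiometric matrix as extra rows when the model is
#' assembled for solving. All fluxes are in mmol/(h.gDCW) and growth in 1/h.
#'
#' Exchange reactions are written over a single (extracellular) metabolite in
#' the secretion-positive convention: `met_e ->`, so a positive flux is
#' secretion and a negative flux is uptake.
#'
#' @param metabolites A data frame with columns `id`, `name`, `compartment`
#'   (ids unique, compartments non-empty).
#' @param reactions A data frame with columns `id`, `stoichiometry` (a list
#'   column of named numeric vectors, metabolite id -> signed coefficient,
#'   negative = consumed), `lower_bound`, `upper_bound`, `is_exchange`, and
#'   optionally `gene_association`.
#' @param biomass_id,proton_exchange_id Reaction ids of the biomass drain and
#'   the extracellular proton exchange. May be left `NA` at construction and
#'   set later; they are required only when solving or fixing the specific
#'   proton flux.
#' @param ratio_constraints A list of [flux_ratio()] objects.
#' @return An object of class `fbr_model`.
#' @seealso [read_model()], [stoich_matrix()], [add_flux_ratio()]
#' @examples
#' m <- metabolic_model(
#'   metabolites = tibble::tibble(
#'     id = c("a", "b"), name = c("A", "B"), compartment = "cytosol"
#'   ),
#'   reactions = tibble::tibble(
#'     id = c("up", "conv", "out"),
#'     stoichiometry = list(c(a = 1), c(a = -1, b = 1), c(b = -1)),
#'     lower_bound = 0, upper_bound = 1000,
#'     is_exchange = c(TRUE, FALSE, TRUE)
#'   )
#' )
#' stoich_matrix(m)
#' @export
metabolic_model <- function(metabolites = NULL, reactions = NULL,
                            biomass_id = NA_character_,
                            proton_exchange_id = NA_character_,
                            ratio_constraints = list()) {
  metabolites <- normalize_metabolites(metabolites)
  reactions <- normalize_reactions(reactions)
  model <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      biomass_id = biomass_id %||% NA_character_,
      proton_exchange_id = proton_exchange_id %||% NA_character_,
      ratio_constraints = list()
    ),
    class = "fbr_model"
  )
  validate_model(model)
  for (rc in ratio_constraints) model <- add_flux_ratio(model, rc)
  model
}

empty_metabolite_table <- function() {
  tibble(id = character(), name = character(), compartment = character())
}

empty_reaction_table <- function() {
  tibble(
    id = character(), stoichiometry = list(),
    lower_bound = double(), upper_bound = double(),
    is_exchange = logical(), gene_association = character()
  )
}

normalize_metabolites <- function(metabolites) {
  if (is.null(metabolites) || nrow(as_tibble(metabolites)) == 0) {
    return(empty_metabolite_table())
  }
  metabolites <- as_tibble(metabolites)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "cytosol"
  metabolites[c("id", "name", "compartment")]
}

normalize_reactions <- function(reactions) {
  if (is.null(reactions) || nrow(as_tibble(reactions)) == 0) {
    return(empty_reaction_table())
  }
  reactions <- as_tibble(reactions)
  if (!"is_exchange" %in% names(reactions)) reactions$is_exchange <- FALSE
  if (!"gene_association" %in% names(reactions)) {
    reactions$gene_association <- NA_character_
  }
  if (!"lower_bound" %in% names(reactions)) reactions$lower_bound <- NA_real_
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- NA_real_
  # default bounds: reversible +-1000, irreversible [0, 1000]; infinities are
  # clamped so the LP always has finite box constraints
  reactions$lower_bound[is.na(reactions$lower_bound)] <- 0
  reactions$upper_bound[is.na(reactions$upper_bound)] <- FBR_DEFAULT_BOUND
  reactions$lower_bound <- pmax(reactions$lower_bound, -FBR_DEFAULT_BOUND)
  reactions$upper_bound <- pmin(reactions$upper_bound, FBR_DEFAULT_BOUND)
  reactions$stoichiometry <- lapply(reactions$stoichiometry, function(s) {
    s <- unlist(s)
    storage.mode(s) <- "double"
    s
  })
  reactions[c("id", "stoichiometry", "lower_bound", "upper_bound",
              "is_exchange", "gene_association")]
}

#' Conventional flux bound magnitude
#'
#' The customary "infinite" flux bound of constraint-based models,
#' 1000 mmol/(h.gDCW). Reactions without explicit bounds default to
#' `[0, 1000]` (irreversible) or `[-1000, 1000]` (reversible), and larger or
#' infinite bounds are clamped to this magnitude so every linear program has
#' finite box constraints.
#' @export
FBR_DEFAULT_BOUND <- 1000

validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    abort(paste0("Duplicate metabolite ids: ",
                 paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxns$id)) {
    abort(paste0("Duplicate reaction ids: ",
                 paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  }
  if (nrow(mets) > 0 && any(!nzchar(mets$compartment) | is.na(mets$compartment))) {
    abort("Every metabolite needs a non-empty compartment.")
  }
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
    abort(paste0("lower_bound > upper_bound for: ", paste(bad, collapse = ", ")))
  }
  for (i in seq_len(nrow(rxns))) {
    s <- rxns$stoichiometry[[i]]
    if (length(s) == 0 && !rxns$is_exchange[i]) {
      abort(paste0("Reaction '", rxns$id[i],
                   "' has empty stoichiometry but is not an exchange."))
    }
    if (rxns$is_exchange[i] && length(s) != 1) {
      abort(paste0("Exchange reaction '", rxns$id[i],
                   "' must touch exactly one metabolite."))
    }
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown) > 0) {
      abort(paste0("Reaction '", rxns$id[i], "' references unknown metabolite(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  for (id in c(model$biomass_id, model$proton_exchange_id)) {
    if (!is.na(id) && !id %in% rxns$id) {
      abort(paste0("Reaction id '", id, "' not present in the model."))
    }
  }
  invisible(model)
}

reaction_index <- function(model, id, context = "reaction") {
  idx <- match(id, model$reactions$id)
  if (anyNA(idx)) {
    abort(paste0("Unknown ", context, " id(s): ",
                 paste(id[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Assemble the stoichiometric matrix, ratio rows included
#'
#' Returns the matrix `S` of the flux balance system `S v = 0`. Rows are the
#' model metabolites followed by one row per flux-ratio constraint (in
#' insertion order); columns are the reactions. A ratio row for
#' `sum(w_i v_i) / sum(w_j v_j) = k` holds `+w_i` in each numerator column and
#' `-k w_j` in each denominator column, so the appended balance enforces the
#' ratio exactly when `S v = 0` is solved.
#'
#' @param model An `fbr_model`.
#' @param ratio_rows Include the flux-ratio rows (default `TRUE`).
#' @return A dense numeric matrix with metabolite/constraint row names and
#'   reaction column names.
#' @export
stoich_matrix <- function(model, ratio_rows = TRUE) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    s <- model$reactions$stoichiometry[[j]]
    if (length(s)) S[names(s), j] <- s
  }
  if (ratio_rows && length(model$ratio_constraints) > 0) {
    rows <- t(vapply(model$ratio_constraints, function(rc) {
      ratio_row(rc, rxns)
    }, numeric(length(rxns))))
    rownames(rows) <- vapply(model$ratio_constraints, `[[`, "", "id")
    S <- rbind(S, rows)
  }
  S
}

#' Overwrite reaction bounds from an irreversibility table
#'
#' Applies a table of `(reaction, lower, upper)` rows, overwriting the bounds
#' of the listed reactions and leaving every other bound untouched. This is
#' the mechanism used to impose thermodynamic irreversibility on the
#' ferredoxin block (PFO, HYDA, FNO, FNPO all become `[0, 1000]`) before
#' simulating clostridial metabolism.
#'
#' @param model An `fbr_model`.
#' @param table A data frame with columns `reaction`, `lower`, `upper`.
#' @return The model with updated bounds.
#' @export
apply_irreversibility_table <- function(model, table) {
  table <- as_tibble(table)
  if (nrow(table) == 0) return(model)
  stopifnot(all(c("reaction", "lower", "upper") %in% names(table)))
  idx <- reaction_index(model, table$reaction)
  model$reactions$lower_bound[idx] <- as.numeric(table$lower)
  model$reactions$upper_bound[idx] <- as.numeric(table$upper)
  validate_model(model)
  model
}

#' Set reaction bounds
#'
#' @param model An `fbr_model`.
#' @param id Reaction id.
#' @param lower,upper New bounds; `NULL` leaves a bound unchanged.
#' @return The updated model.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  idx <- reaction_index(model, id)
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- upper
  validate_model(model)
  model
}

#' @export
print.fbr_model <- function(x, ...) {
  cat("<fbr_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ",
      length(x$ratio_constraints), " flux-ratio constraint(s)\n", sep = "")
  if (!is.na(x$biomass_id)) cat("  biomass:        ", x$biomass_id, "\n", sep = "")
  if (!is.na(x$proton_exchange_id)) {
    cat("  proton exchange:", x$proton_exchange_id, "\n")
  }
  invisible(x)
}

#' Summarize a model's reactions as a tibble
#'
#' @param x An `fbr_model`.
#' @param ... Unused.
#' @return A tibble with one row per reaction: id, bounds, exchange flag, and
#'   a compact reaction string.
#' @export
tidy.fbr_model <- function(x, ...) {
  eqn <- vapply(x$reactions$stoichiometry, format_reaction_string, "")
  tibble(
    reaction = x$reactions$id,
    equation = eqn,
    lower_bound = x$reactions$lower_bound,
    upper_bound = x$reactions$upper_bound,
    is_exchange = x$reactions$is_exchange
  )
}

format_reaction_string <- function(s) {
  if (length(s) == 0) return("->")
  fmt <- function(v) {
    paste(ifelse(abs(v) == 1, names(v),
                 paste0(format(abs(v), trim = TRUE), " ", names(v))),
          collapse = " + ")
  }
  lhs <- s[s < 0]
  rhs <- s[s > 0]
  paste(fmt(lhs), "->", fmt(rhs))
}
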