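#' Define a flux-ratio constraint
#'
#' A flux-ratio constraint forces the quotient of two (weighted sums of)
#' fluxes to a fixed value `k`:
#' \deqn{\frac{\sum_i w_i v_i}{\sum_j w_j v_j} = k,}
#' which is imposed linearly as \eqn{\sum_i w_i v_i - k \sum_j w_j v_j = 0},
#' one extra row of the stoichiometric matrix with `+w_i` in each numerator
#' column and `-k w_j` in each denominator column. For the classic thiolase /
#' phosphotransacetylase split with `k = 2` the appended row carries `+1`
#' under THL and `-2` under PTA.
#'
#' `k = 0` is allowed and forces the numerator fluxes to zero, the ratio
#' expression of a knockout.
#'
#' @param id Constraint identifier, unique within a model.
#' @param numerator,denominator Either a character vector of reaction ids
#'   (unit weights) or a named numeric vector of positive weights.
#' @param ratio The target ratio `k`, a non-negative number.
#' @return An object of class `fbr_ratio`.
#' @examples
#' flux_ratio("thl_pta", "THL", "PTA", 2)
#' flux_ratio("coat_bhbd", c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD", 1.09)
#' @export
flux_ratio <- function(id, numerator, denominator, ratio) {
  numerator <- as_weights(numerator, "numerator")
  denominator <- as_weights(denominator, "denominator")
  if (length(intersect(names(numerator), names(denominator))) > 0) {
    abort("Numerator and denominator reaction sets must be disjoint.")
  }
  if (!is.numeric(ratio) || length(ratio) != 1 || is.na(ratio) || ratio < 0) {
    abort("`ratio` must be a single non-negative number.")
  }
  structure(
    list(id = id, numerator = numerator, denominator = denominator,
         ratio = as.numeric(ratio)),
    class = "fbr_ratio"
  )
}

as_weights <- function(x, side) {
  if (is.character(x)) x <- setNames(rep(1, length(x)), x)
  if (length(x) == 0) abort(paste0("The ", side, " side must be non-empty."))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort(paste0("The ", side, " side must name its reactions."))
  }
  if (any(x <= 0)) abort(paste0(side, " weights must be positive."))
  storage.mode(x) <- "double"
  x
}

#' @export
print.fbr_ratio <- function(x, ...) {
  side <- function(w) {
    paste(ifelse(w == 1, names(w), paste0(w, "*", names(w))), collapse = " + ")
  }
  cat("<fbr_ratio> ", x$id, ": (", side(x$numerator), ") : (",
      side(x$denominator), ") = ", x$ratio, "\n", sep = "")
  invisible(x)
}

# the appended stoichiometric-matrix row for one constraint
ratio_row <- function(rc, reaction_ids) {
  row <- setNames(numeric(length(reaction_ids)), reaction_ids)
  row[names(rc$numerator)] <- row[names(rc$numerator)] + rc$numerator
  row[names(rc$denominator)] <- row[names(rc$denominator)] -
    rc$ratio * rc$denominator
  unname(row)
}

#' Attach a flux-ratio constraint to a model
#'
#' Adds the constraint to the model; on assembly ([stoich_matrix()]) and at
#' solve time the constraint contributes one extra zero-right-hand-side row.
#' Ratio constraints apply to net signed fluxes, so a warning is emitted when
#' a participating reaction is reversible (negative lower bound): the
#' constrained quotient is then a quotient of net fluxes, which may not be
#' what an enzyme-level ratio intends.
#'
#' @param model An `fbr_model`.
#' @param constraint An [flux_ratio()] object, or `NULL` to build one from the
#'   remaining arguments.
#' @param id,numerator,denominator,ratio Passed to [flux_ratio()] when
#'   `constraint` is not given.
#' @return The model with the constraint appended (insertion order is
#'   preserved and determines row order in the assembled matrix).
#' @export
add_flux_ratio <- function(model, constraint = NULL, id = NULL,
                           numerator = NULL, denominator = NULL, ratio = NULL) {
  if (is.null(constraint)) {
    constraint <- flux_ratio(id, numerator, denominator, ratio)
  }
  stopifnot(inherits(constraint, "fbr_ratio"))
  members <- c(names(constraint$numerator), names(constraint$denominator))
  idx <- reaction_index(model, members, context = "ratio-constraint reaction")
  if (constraint$id %in% names(model$ratio_constraints)) {
    abort(paste0("A ratio constraint with id '", constraint$id,
                 "' already exists."))
  }
  rev_members <- members[model$reactions$lower_bound[idx] < 0]
  if (length(rev_members) > 0) {
    warn(paste0("Ratio constraint '", constraint$id,
                "' touches reversible reaction(s): ",
                paste(rev_members, collapse = ", "),
                "; the ratio applies to net signed fluxes."))
  }
  model$ratio_constraints[[constraint$id]] <- constraint
  model
}

#' Remove a flux-ratio constraint
#'
#' @param model An `fbr_model`.
#' @param id Constraint id to drop.
#' @return The model without the constraint; remaining constraints keep their
#'   relative order.
#' @export
remove_flux_ratio <- function(model, id) {
  if (!id %in% names(model$ratio_constraints)) {
    abort(paste0("No ratio constraint with id '", id, "'."))
  }
  model$ratio_constraints[[id]] <- NULL
  model
}

#' Replace the target value of an attached ratio constraint
#'
#' @param model An `fbr_model`.
#' @param id Constraint id.
#' @param ratio New target ratio `k`.
#' @return The updated model.
#' @export
set_ratio_value <- function(model, id, ratio) {
  if (!id %in% names(model$ratio_constraints)) {
    abort(paste0("No ratio constraint with id '", id, "'."))
  }
  rc <- model$ratio_constraints[[id]]
  model$ratio_constraints[[id]] <- flux_ratio(rc$id, rc$numerator,
                                              rc$denominator, ratio)
  model
}

#' Audit how well a solution satisfies a ratio constraint
#'
#' Returns the scaled residual
#' `|sum(w_i v_i) - k sum(w_j v_j)| / (1 + |sum(w_j v_j)|)`; zero means the
#' constraint is met exactly.
#'
#' @param solution An optimal `fbr_solution`.
#' @param constraint An `fbr_ratio`.
#' @return A single non-negative number.
#' @export
ratio_residual <- function(solution, constraint) {
  stopifnot(inherits(solution, "fbr_solution"), inherits(constraint, "fbr_ratio"))
  if (solution$status != "optimal") {
    abort("ratio_residual() needs an optimal solution.")
  }
  members <- c(names(constraint$numerator), names(constraint$denominator))
  missing <- setdiff(members, names(solution$fluxes))
  if (length(missing) > 0) {
    abort(paste0("Solution lacks fluxes for: ", paste(missing, collapse = ", ")))
  }
  num <- sum(constraint$numerator * solution$fluxes[names(constraint$numerator)])
  den <- sum(constraint$denominator * solution$fluxes[names(constraint$denominator)])
  abs(num - constraint$ratio * den) / (1 + abs(den))
}

#' Realized flux ratio of a solution
#'
#' The quotient `sum(w_i v_i) / sum(w_j v_j)` actually attained by a flux
#' vector, e.g. a total CoA-transferase flux of 3.31 over a BHBD flux of 3.04
#' gives 1.09. When the denominator sum is below `1e-9` in magnitude the
#' quotient is undefined and `NA` is returned.
#'
#' @param solution An optimal `fbr_solution`.
#' @param numerator,denominator Reaction ids (character, unit weights) or
#'   named positive weights.
#' @return A number, or `NA_real_` when the denominator vanishes.
#' @export
realized_ratio <- function(solution, numerator, denominator) {
  stopifnot(inherits(solution, "fbr_solution"))
  if (solution$status != "optimal") {
    abort("realized_ratio() needs an optimal solution.")
  }
  numerator <- as_weights(numerator, "numerator")
  denominator <- as_weights(denominator, "denominator")
  num <- sum(numerator * solution$fluxes[names(numerator)])
  den <- sum(denominator * solution$fluxes[names(denominator)])
  if (abs(den) < 1e-9) return(NA_real_)
  num / den
}

#' Read and write flux-ratio constraints as TSV
#'
#' The file has columns `id`, `numerator`, `denominator`, `ratio`; each side
#' is a comma-separated list of `reaction` or `reaction*weight` terms.
#'
#' @param path File path.
#' @return `read_ratio_tsv()` returns a list of `fbr_ratio` objects.
#' @export
read_ratio_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          id = readr::col_character(),
                          numerator = readr::col_character(),
                          denominator = readr::col_character(),
                          ratio = readr::col_double()
                        ))
  purrr::pmap(df, function(id, numerator, denominator, ratio) {
    flux_ratio(id, parse_side(numerator), parse_side(denominator), ratio)
  })
}

parse_side <- function(x) {
  terms <- strsplit(trimws(x), ",")[[1]]
  parts <- strsplit(trimws(terms), "\\*")
  ids <- vapply(parts, `[[`, "", 1)
  w <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[2]) else 1, 0)
  setNames(w, trimws(ids))
}

#' @param constraints A list of `fbr_ratio` objects.
#' @rdname read_ratio_tsv
#' @export
write_ratio_tsv <- function(constraints, path) {
  side_str <- function(w) {
    paste(ifelse(w == 1, names(w), paste0(names(w), "*", w)), collapse = ",")
  }
  df <- tibble(
    id = vapply(constraints, `[[`, "", "id"),
    numerator = vapply(constraints, function(rc) side_str(rc$numerator), ""),
    denominator = vapply(constraints, function(rc) side_str(rc$denominator), ""),
    ratio = vapply(constraints, `[[`, 0, "ratio")
  )
  readr::write_tsv(df, path)
  invisible(path)
}
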