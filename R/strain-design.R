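#' Ratio arithmetic for gene knockdown
#'
#' A partial knockdown of an enzyme reduces the share of flux it draws at its
#' branch point. Expressed on a flux-ratio constraint, knocking down the
#' numerator-side enzyme by a fraction `f` multiplies the ratio by `1 - f`;
#' knocking down the denominator-side enzyme divides it by `1 - f`. An 80
#' percent knockdown of the denominator enzyme therefore maps a wild-type
#' ratio of 10 to 50, and 0.25 to 1.25.
#'
#' @param wt_ratio Wild-type ratio value (non-negative).
#' @param fraction Knockdown fraction in `[0, 1]`; `0` is no edit and `1` a
#'   full knockout.
#' @param side Which side of the ratio carries the edited enzyme.
#' @return The adjusted ratio value.
#' @examples
#' knockdown_ratio(10, 0.8, "denominator")   # 50
#' knockdown_ratio(0.25, 0.8, "denominator") # 1.25
#' knockdown_ratio(1.09, 0.8, "numerator")   # 0.218
#' @export
knockdown_ratio <- function(wt_ratio, fraction,
                            side = c("numerator", "denominator")) {
  side <- match.arg(side)
  stopifnot(wt_ratio >= 0, fraction >= 0, fraction <= 1)
  if (side == "numerator") {
    wt_ratio * (1 - fraction)
  } else {
    if (fraction == 1) {
      abort(paste0("A full denominator knockout gives an infinite ratio; ",
                   "impose it by zeroing the reaction bounds instead ",
                   "(see `engineering_edit(mode = \"knockout\")`)."))
    }
    wt_ratio / (1 - fraction)
  }
}

#' Ratio arithmetic for gene over-expression
#'
#' Over-expression by `percent` percent multiplies the edited enzyme's
#' expression by `2^(percent/100)` under the default doubling-per-100%
#' convention (100% doubles the enzyme, 500% gives 32-fold), or by
#' `1 + percent/100` under the linear convention. The ratio is multiplied by
#' the factor when the numerator enzyme is edited and divided by it for the
#' denominator: over-expressing the denominator enzyme by 100, 200, and 500
#' percent maps a wild-type ratio of 10 to 5, 2.5, and 0.3125.
#'
#' @param wt_ratio Wild-type ratio value.
#' @param percent Over-expression level in percent above wild type (`0` = no
#'   change).
#' @param side Which side carries the edited enzyme.
#' @param convention `"doubling"` (default) or `"linear"` expression scaling.
#' @return The adjusted ratio value.
#' @examples
#' overexpress_ratio(10, 100, "denominator") # 5
#' overexpress_ratio(10, 500, "denominator") # 0.3125
#' @export
overexpress_ratio <- function(wt_ratio, percent,
                              side = c("numerator", "denominator"),
                              convention = c("doubling", "linear")) {
  side <- match.arg(side)
  convention <- match.arg(convention)
  stopifnot(wt_ratio >= 0, percent >= 0)
  m <- switch(convention,
              doubling = 2^(percent / 100),
              linear = 1 + percent / 100)
  if (side == "numerator") wt_ratio * m else wt_ratio / m
}

#' Describe a single strain-engineering edit
#'
#' An edit targets one side of an existing flux-ratio constraint and rewrites
#' its value through [knockdown_ratio()] or [overexpress_ratio()]; a knockout
#' instead zeroes the bounds of every reaction on the targeted side (the
#' ratio-value equivalent would be infinite for denominator knockouts).
#'
#' @param constraint Id of the targeted ratio constraint.
#' @param side `"numerator"` or `"denominator"`.
#' @param mode `"knockdown"`, `"overexpression"`, or `"knockout"`.
#' @param magnitude Knockdown fraction in `[0, 1]` or over-expression percent;
#'   ignored for knockouts.
#' @param convention Expression convention for over-expression edits.
#' @return An object of class `fbr_edit`.
#' @examples
#' engineering_edit("thl_aad1", "denominator", "knockdown", 0.8)
#' @export
engineering_edit <- function(constraint,
                             side = c("numerator", "denominator"),
                             mode = c("knockdown", "overexpression", "knockout"),
                             magnitude = NULL,
                             convention = c("doubling", "linear")) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  if (mode == "knockdown") {
    stopifnot(!is.null(magnitude), magnitude >= 0, magnitude <= 1)
    if (magnitude == 1) mode <- "knockout"
  }
  if (mode == "overexpression") stopifnot(!is.null(magnitude), magnitude >= 0)
  structure(
    list(constraint = constraint, side = side, mode = mode,
         magnitude = magnitude, convention = convention),
    class = "fbr_edit"
  )
}

#' @export
print.fbr_edit <- function(x, ...) {
  cat("<fbr_edit> ", x$mode, " of the ", x$side, " of '", x$constraint, "'",
      if (!is.null(x$magnitude)) paste0(" (", x$magnitude,
        if (x$mode == "overexpression") "%" else "", ")"), "\n", sep = "")
  invisible(x)
}

# rewrite the model's ratio constraints (and bounds, for knockouts) per edits
apply_edits <- function(model, edits) {
  targets <- vapply(edits, `[[`, "", "constraint")
  dup <- targets[duplicated(targets)]
  if (length(dup) > 0) {
    abort(paste0("Conflicting edits target the same constraint(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  for (e in edits) {
    if (!e$constraint %in% names(model$ratio_constraints)) {
      abort(paste0("Edit targets unknown ratio constraint '", e$constraint, "'."))
    }
    rc <- model$ratio_constraints[[e$constraint]]
    if (e$mode == "knockout") {
      side_rxns <- names(rc[[e$side]])
      for (r in side_rxns) model <- set_bounds(model, r, lower = 0, upper = 0)
      if (e$side == "numerator") {
        model <- set_ratio_value(model, rc$id, 0)
      }
    } else if (e$mode == "knockdown") {
      model <- set_ratio_value(
        model, rc$id, knockdown_ratio(rc$ratio, e$magnitude, e$side))
    } else {
      model <- set_ratio_value(
        model, rc$id,
        overexpress_ratio(rc$ratio, e$magnitude, e$side, e$convention))
    }
  }
  model
}

#' Wild-type ratio value as a function of the specific proton flux
#'
#' In the wild type some branch ratios are not constrained and vary with the
#' SPF; to knock such a ratio down proportionally, its SPF-dependent
#' wild-type profile is extracted from a scan and rescaled. Rows where the
#' denominator flux vanishes (below `1e-9`) are dropped; the profile
#' interpolates piecewise-linearly between the remaining knots.
#'
#' @param scan An `fbr_scan` whose tracked columns include all reactions of
#'   both sides.
#' @param numerator,denominator Reaction ids or named positive weights.
#' @return An `fbr_profile`: a tibble of `(spf, ratio)` knots.
#' @export
wildtype_ratio_profile <- function(scan, numerator, denominator) {
  stopifnot(inherits(scan, "fbr_scan"))
  numerator <- as_weights(numerator, "numerator")
  denominator <- as_weights(denominator, "denominator")
  members <- c(names(numerator), names(denominator))
  missing <- setdiff(members, attr(scan, "tracked"))
  if (length(missing) > 0) {
    abort(paste0("Scan does not track: ", paste(missing, collapse = ", ")))
  }
  rows <- dplyr::filter(as_tibble(scan), .data$status == "optimal")
  num <- as.matrix(rows[names(numerator)]) %*% numerator
  den <- as.matrix(rows[names(denominator)]) %*% denominator
  keep <- abs(den) >= 1e-9
  if (sum(keep) < 2) {
    abort("Fewer than two scan rows have a defined ratio; cannot build a profile.")
  }
  new_profile(tibble(spf = rows$spf[keep], ratio = as.numeric(num[keep] / den[keep])))
}

new_profile <- function(df) {
  df <- dplyr::arrange(df, .data$spf)
  if (anyDuplicated(df$spf)) abort("Profile SPF knots must be distinct.")
  structure(df, class = c("fbr_profile", class(tibble())))
}

#' Build a ratio profile from explicit knots
#'
#' @param spf Strictly increasing SPF values.
#' @param ratio Non-negative ratio values, one per knot.
#' @return An `fbr_profile`.
#' @export
ratio_profile <- function(spf, ratio) {
  stopifnot(length(spf) == length(ratio), all(ratio >= 0))
  new_profile(tibble(spf = as.numeric(spf), ratio = as.numeric(ratio)))
}

#' Scale a ratio profile by a constant fraction
#'
#' Emulates a proportional knockdown of an SPF-dependent wild-type ratio:
#' every ratio value is multiplied by `fraction`, the SPF knots are kept.
#'
#' @param profile An `fbr_profile`.
#' @param fraction A value in `(0, 1]`.
#' @return The scaled profile.
#' @export
scale_profile <- function(profile, fraction) {
  stopifnot(inherits(profile, "fbr_profile"), fraction > 0, fraction <= 1)
  profile$ratio <- profile$ratio * fraction
  profile
}

#' Evaluate a ratio profile at given SPF values
#'
#' Piecewise-linear interpolation through the knots; values outside the knot
#' range take the nearest knot's ratio.
#'
#' @param profile An `fbr_profile`.
#' @param spf SPF value(s).
#' @return Numeric vector of ratio values.
#' @export
profile_value <- function(profile, spf) {
  stopifnot(inherits(profile, "fbr_profile"))
  approx(profile$spf, profile$ratio, xout = spf, rule = 2)$y
}

#' Plot a ratio profile
#'
#' @param object An `fbr_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fbr_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$spf, .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "specific proton flux (mmol H+/h/gDCW)",
                  y = "wild-type flux ratio")
}

#' Simulate an engineered strain across a specific-proton-flux scan
#'
#' Applies a set of base ratio constraints, strain edits
#' ([engineering_edit()]), optional new constraints introduced by the
#' strategy, and optional SPF-dependent constraint values (profiles), then
#' runs [scan_spf()]. With no edits and no extras this reduces exactly to the
#' wild-type scan.
#'
#' @param model An `fbr_model` without the base constraints attached.
#' @param base_ratios List of [flux_ratio()] constraints defining the
#'   reference strain (e.g. [wildtype_ratio_set()]).
#' @param edits List of [engineering_edit()] objects rewriting base ratios.
#' @param extra_ratios List of [flux_ratio()] constraints the strategy
#'   introduces beyond the base set.
#' @param profile_ratios Named list mapping constraint ids to
#'   `fbr_profile` objects; before each SPF point is solved the constraint's
#'   value is set from the profile at that SPF.
#' @param spf_values,glucose_uptake,tracked,options Passed to [scan_spf()].
#' @param label Free-text strategy description stored on the result.
#' @return An `fbr_scan` with a `strategy` attribute.
#' @examples
#' m <- build_toy_model()
#' wt <- simulate_strategy(m, wildtype_ratio_set(),
#'                         spf_values = c(-10, -5, 0, 5))
#' @export
simulate_strategy <- function(model, base_ratios, edits = list(),
                              extra_ratios = list(), profile_ratios = list(),
                              spf_values = seq(-30, 5, by = 1),
                              glucose_uptake = 10, tracked = NULL,
                              options = solve_options(), label = NULL) {
  for (rc in base_ratios) model <- add_flux_ratio(model, rc)
  for (rc in extra_ratios) model <- add_flux_ratio(model, rc)
  model <- apply_edits(model, edits)

  if (length(profile_ratios) == 0) {
    scan <- scan_spf(model, spf_values = spf_values,
                     glucose_uptake = glucose_uptake, tracked = tracked,
                     options = options)
  } else {
    unknown <- setdiff(names(profile_ratios), names(model$ratio_constraints))
    if (length(unknown) > 0) {
      abort(paste0("Profile for unknown constraint(s): ",
                   paste(unknown, collapse = ", ")))
    }
    tracked <- tracked %||% default_tracked_reactions(model)
    spf_values <- sort(unique(spf_values))
    rows <- purrr::map_dfr(spf_values, function(spf) {
      m <- model
      for (id in names(profile_ratios)) {
        m <- set_ratio_value(m, id, profile_value(profile_ratios[[id]], spf))
      }
      as_tibble(scan_spf(m, spf_values = spf, glucose_uptake = glucose_uptake,
                         tracked = tracked, options = options))
    })
    scan <- structure(rows,
                      glucose_uptake = glucose_uptake,
                      ratio_constraints = model$ratio_constraints,
                      tracked = tracked,
                      class = c("fbr_scan", class(tibble())))
  }
  attr(scan, "strategy") <- label %||% describe_edits(edits, extra_ratios)
  scan
}

describe_edits <- function(edits, extra_ratios) {
  if (length(edits) == 0 && length(extra_ratios) == 0) return("wild type")
  parts <- c(
    vapply(edits, function(e) {
      paste0(e$mode, "(", e$constraint, ":", e$side,
             if (!is.null(e$magnitude)) paste0(", ", e$magnitude), ")")
    }, ""),
    vapply(extra_ratios, function(rc) paste0(rc$id, "=", rc$ratio), "")
  )
  paste(parts, collapse = "; ")
}
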