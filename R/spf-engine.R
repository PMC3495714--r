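#' Fix the specific proton flux of a model
#'
#' The specific proton flux (SPF) is the net rate of proton transport across
#' the membrane, negative when protons leave the cell (acidogenesis) and
#' positive when protons are taken up (solventogenesis). The proton exchange
#' reaction is written secretion-positive, so fixing the SPF to `spf` pins
#' the exchange flux to `-spf` (both bounds).
#'
#' @param model An `fbr_model` with `proton_exchange_id` set.
#' @param spf SPF value in mmol H+/(h.gDCW).
#' @return The model with the proton exchange flux fixed.
#' @export
set_spf <- function(model, spf) {
  if (is.na(model$proton_exchange_id)) {
    abort("Set `proton_exchange_id` on the model before fixing the SPF.")
  }
  set_bounds(model, model$proton_exchange_id, lower = -spf, upper = -spf)
}

#' Fix or cap the glucose uptake rate
#'
#' @param model An `fbr_model` containing an `EX_GLC`-style glucose exchange.
#' @param rate Uptake rate in mmol/(h.gDCW) (positive number).
#' @param exchange_id Id of the glucose exchange reaction.
#' @param fixed If `TRUE` (default) the uptake is an equality, the protocol
#'   used for SPF scans; if `FALSE` it is an upper limit on uptake.
#' @return The updated model.
#' @export
set_glucose_uptake <- function(model, rate, exchange_id = "EX_GLC",
                               fixed = TRUE) {
  stopifnot(rate > 0)
  set_bounds(model, exchange_id, lower = -rate,
             upper = if (fixed) -rate else 0)
}

default_tracked_reactions <- function(model) {
  exch <- model$reactions$id[model$reactions$is_exchange]
  key <- intersect(
    c("THL", "PTA", "AAD_1", "AAD_2", "AAD_3", "PFO", "LDH", "BHBD", "PTB",
      "CoAT_ACETATE", "CoAT_BUTYRATE", "CO2_EXPORT", "CO2_TO_HCO3", "HYDA"),
    model$reactions$id
  )
  unique(c(exch, key))
}

#' Scan growth and fluxes across a grid of specific proton fluxes
#'
#' For each SPF value the glucose uptake is fixed, the proton exchange is
#' pinned, and the two-stage flux balance problem is solved; one row is
#' recorded per grid point whether or not it is feasible, so the scan never
#' aborts on an infeasible SPF. Rows are keyed (sorted) by SPF value, making
#' the result invariant to the order of the requested grid.
#'
#' @param model An `fbr_model` with biomass and proton exchange configured
#'   (ratio constraints already attached, if any).
#' @param spf_values SPF grid in mmol H+/(h.gDCW); the default covers the
#'   physiological range -30 (strong efflux, acidogenesis) to +5 (influx,
#'   solventogenesis) in unit steps.
#' @param glucose_uptake Fixed glucose uptake rate, mmol/(h.gDCW).
#' @param tracked Reaction ids whose fluxes become scan columns; defaults to
#'   all exchanges plus the branch-point enzymes.
#' @param options A [solve_options()] list.
#' @return An `fbr_scan` tibble: `spf`, `status`, `growth`, `total_flux`,
#'   then one column per tracked reaction (NA on infeasible rows).
#' @examples
#' m <- add_wildtype_ratios(build_toy_model())
#' scan <- scan_spf(m, spf_values = seq(-15, 5, by = 5))
#' scan[, c("spf", "status", "growth")]
#' @export
scan_spf <- function(model, spf_values = seq(-30, 5, by = 1),
                     glucose_uptake = 10, tracked = NULL,
                     options = solve_options()) {
  stopifnot(inherits(model, "fbr_model"))
  if (is.na(model$biomass_id) || is.na(model$proton_exchange_id)) {
    abort("scan_spf() needs both `biomass_id` and `proton_exchange_id` set.")
  }
  tracked <- tracked %||% default_tracked_reactions(model)
  reaction_index(model, tracked, context = "tracked reaction")
  model <- set_glucose_uptake(model, glucose_uptake)
  spf_values <- sort(unique(spf_values))

  rows <- purrr::map_dfr(spf_values, function(spf) {
    sol <- solve_fba(set_spf(model, spf), options)
    fl <- if (sol$status == "optimal") sol$fluxes[tracked]
          else setNames(rep(NA_real_, length(tracked)), tracked)
    dplyr::bind_cols(
      tibble(spf = spf, status = sol$status, growth = sol$growth_rate,
             total_flux = sol$total_flux),
      as_tibble(as.list(setNames(fl, tracked)))
    )
  })

  structure(
    rows,
    glucose_uptake = glucose_uptake,
    ratio_constraints = model$ratio_constraints,
    tracked = tracked,
    class = c("fbr_scan", class(rows))
  )
}

#' Extract the full solution at one SPF value
#'
#' Re-solves the model at a single SPF with the scan's protocol, returning
#' the complete `fbr_solution` (a scan row only keeps tracked fluxes).
#'
#' @param model The model used for the scan.
#' @param spf SPF value.
#' @param glucose_uptake Fixed glucose uptake rate.
#' @param options A [solve_options()] list.
#' @return An `fbr_solution`.
#' @export
solve_at_spf <- function(model, spf, glucose_uptake = 10,
                         options = solve_options()) {
  model <- set_glucose_uptake(model, glucose_uptake)
  solve_fba(set_spf(model, spf), options)
}

#' @export
print.fbr_scan <- function(x, ...) {
  n_ok <- sum(x$status == "optimal")
  cat("<fbr_scan> ", nrow(x), " SPF points (", n_ok, " feasible), glucose ",
      attr(x, "glucose_uptake"), " mmol/(h.gDCW), ",
      length(attr(x, "ratio_constraints")), " ratio constraint(s)\n", sep = "")
  NextMethod()
}

#' Long-format fluxes of an SPF scan
#'
#' @param x An `fbr_scan`.
#' @param ... Unused.
#' @return A tibble with columns `spf`, `status`, `growth`, `reaction`,
#'   `flux` (feasible rows only).
#' @export
tidy.fbr_scan <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::all_of(attr(x, "tracked")),
                      names_to = "reaction", values_to = "flux") |>
    dplyr::filter(.data$status == "optimal")
}

#' Plot exchange fluxes and growth across an SPF scan
#'
#' @param object An `fbr_scan`.
#' @param reactions Reactions to draw; defaults to the main fermentation
#'   product exchanges present in the scan.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fbr_scan <- function(object, reactions = NULL, ...) {
  reactions <- reactions %||% intersect(
    c("EX_AC", "EX_BUT", "EX_LAC", "EX_ETOH", "EX_BTOH", "EX_ACETONE",
      "EX_H2", "EX_CO2"),
    attr(object, "tracked")
  )
  df <- tidy(object) |> dplyr::filter(.data$reaction %in% reactions)
  ggplot2::ggplot(df, ggplot2::aes(.data$spf, .data$flux,
                                   colour = .data$reaction)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "specific proton flux (mmol H+/h/gDCW)",
      y = "flux (mmol/h/gDCW)",
      colour = NULL,
      title = "Flux response across the acidogenesis-solventogenesis range"
    )
}
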