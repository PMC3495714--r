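#' Solver options for flux balance problems
#'
#' @param growth_fix_tolerance Relative slack used when fixing the stage-1
#'   growth optimum before the total-flux minimization (default `1e-6`).
#' @param lp_tolerance Feasibility tolerance used when auditing `S v = 0` and
#'   the bounds of a returned solution (default `1e-9`).
#' @param stage2_enabled Run the second (parsimonious, minimize total flux)
#'   stage (default `TRUE`).
#' @param stage2_exchanges Count exchange reactions in the total flux being
#'   minimized (default `TRUE`, i.e. all columns).
#' @param max_iter Simplex iteration cap per stage.
#' @return A list of class `fbr_solve_options`.
#' @export
solve_options <- function(growth_fix_tolerance = 1e-6, lp_tolerance = 1e-9,
                          stage2_enabled = TRUE, stage2_exchanges = TRUE,
                          max_iter = 20000L) {
  stopifnot(growth_fix_tolerance > 0, lp_tolerance > 0)
  structure(
    list(growth_fix_tolerance = growth_fix_tolerance,
         lp_tolerance = lp_tolerance,
         stage2_enabled = stage2_enabled,
         stage2_exchanges = stage2_exchanges,
         max_iter = as.integer(max_iter)),
    class = "fbr_solve_options"
  )
}

#' Solve the flux balance problem of a model
#'
#' Solves `S v = 0` (metabolite rows and flux-ratio rows alike) subject to the
#' reaction bounds, with the two-stage objective used throughout clostridial
#' flux modeling: first maximize the biomass (growth) flux, then fix growth to
#' at least `(1 - growth_fix_tolerance)` of its optimum and minimize the total
#' flux `sum(|v|)`. The second stage is the standard parsimonious-FBA
#' construction: each flux is split into non-negative forward and reverse
#' parts so the problem stays a pure linear program.
#'
#' @param model An `fbr_model` with `biomass_id` set.
#' @param options A [solve_options()] list.
#' @return An `fbr_solution` with fields `status` (`"optimal"`,
#'   `"infeasible"`, or `"unbounded"`), `fluxes` (named vector, empty unless
#'   optimal), `growth_rate`, and `total_flux`.
#' @examples
#' m <- build_toy_model()
#' m <- set_spf(m, -10)
#' sol <- solve_fba(m)
#' glance(sol)
#' @export
solve_fba <- function(model, options = solve_options()) {
  stopifnot(inherits(model, "fbr_model"))
  if (is.na(model$biomass_id)) {
    abort("Set `biomass_id` on the model before solving.")
  }
  S <- stoich_matrix(model, ratio_rows = TRUE)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  rxns <- model$reactions$id
  n <- length(rxns)
  b_idx <- match(model$biomass_id, rxns)

  prob <- split_problem(S, lb, ub)
  signed_cols <- function(i) {
    row <- numeric(prob$n_var)
    if (!is.na(prob$fwd[i])) row[prob$fwd[i]] <- 1
    if (!is.na(prob$rev[i])) row[prob$rev[i]] <- -1
    row
  }
  obj1 <- signed_cols(b_idx)

  s1 <- lp_stage(prob, obj1, maximize = TRUE, options)
  if (s1$status != "optimal") {
    return(new_solution(s1$status, rxns, NULL, model, options))
  }
  mu <- s1$value + prob$fixed_values[b_idx]
  x <- s1$x

  if (options$stage2_enabled && prob$n_var > 0) {
    obj2 <- rep(1, prob$n_var)
    if (!options$stage2_exchanges) {
      excl <- which(model$reactions$is_exchange)
      obj2[stats::na.omit(prob$fwd[excl])] <- 0
      obj2[stats::na.omit(prob$rev[excl])] <- 0
    }
    growth_floor <- s1$value - options$growth_fix_tolerance * max(abs(mu), 1e-9)
    s2 <- lp_stage(prob, obj2, maximize = FALSE, options,
                   extra_ge = obj1, extra_ge_rhs = growth_floor)
    if (s2$status == "optimal") x <- s2$x
  }

  take <- function(idx) {
    out <- numeric(length(idx))
    ok <- !is.na(idx)
    out[ok] <- x[idx[ok]]
    out
  }
  v <- prob$fixed_values + take(prob$fwd) - take(prob$rev)
  v[abs(v) < 1e-11] <- 0
  names(v) <- rxns
  new_solution("optimal", rxns, v, model, options, stage1_growth = mu)
}

# Forward/reverse variable splitting with presolve: v_i = f_i - r_i with
# f_i in [0, ub+], r_i in [0, (-lb)+]. Variables fixed by lb == ub are
# substituted into the right-hand side, zero-capacity parts are dropped, and
# rows are sign-normalized so every right-hand side stays non-negative (a
# requirement of the simplex backend). This keeps the tableau small and
# avoids the worst pivoting degeneracies.
split_problem <- function(S, lb, ub) {
  n <- ncol(S)
  fixed <- lb == ub
  rhs <- as.numeric(-S[, fixed, drop = FALSE] %*% lb[fixed])

  fup <- pmax(ub, 0); fup[fixed] <- 0
  rup <- pmax(-lb, 0); rup[fixed] <- 0
  fwd <- rep(NA_integer_, n)
  rev <- rep(NA_integer_, n)
  fwd[fup > 0] <- seq_len(sum(fup > 0))
  rev[rup > 0] <- sum(fup > 0) + seq_len(sum(rup > 0))
  n_var <- sum(fup > 0) + sum(rup > 0)

  A3 <- matrix(0, nrow(S), n_var)
  A3[, fwd[!is.na(fwd)]] <- S[, !is.na(fwd), drop = FALSE]
  A3[, rev[!is.na(rev)]] <- -S[, !is.na(rev), drop = FALSE]
  flip <- rhs < 0
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]

  up <- numeric(n_var)
  up[fwd[!is.na(fwd)]] <- fup[!is.na(fwd)]
  up[rev[!is.na(rev)]] <- rup[!is.na(rev)]

  ge_rows <- list(); ge_rhs <- numeric(0)
  for (i in which(lb > 0 & !fixed)) {
    row <- numeric(n_var); row[fwd[i]] <- 1
    ge_rows[[length(ge_rows) + 1]] <- row; ge_rhs <- c(ge_rhs, lb[i])
  }
  for (i in which(ub < 0 & !fixed)) {
    row <- numeric(n_var); row[rev[i]] <- 1
    ge_rows[[length(ge_rows) + 1]] <- row; ge_rhs <- c(ge_rhs, -ub[i])
  }
  list(n_var = n_var, fwd = fwd, rev = rev, A3 = A3, b3 = rhs, up = up,
       ge_rows = ge_rows, ge_rhs = ge_rhs,
       fixed = fixed, fixed_values = ifelse(fixed, lb, 0))
}

lp_stage <- function(prob, obj, maximize, options,
                     extra_ge = NULL, extra_ge_rhs = numeric(0)) {
  ge <- prob$ge_rows
  rhs <- prob$ge_rhs
  if (!is.null(extra_ge)) {
    ge <- c(ge, list(extra_ge))
    rhs <- c(rhs, extra_ge_rhs)
  }
  n_ge <- length(ge)
  A <- prob$A3
  b <- prob$b3
  u <- prob$up
  cost <- if (maximize) -obj else obj
  if (n_ge > 0) {
    # row . x - s = rhs with surplus s >= 0 turns each >= row into an equality
    A <- rbind(A, do.call(rbind, ge))
    A <- cbind(A, rbind(matrix(0, nrow(prob$A3), n_ge), -diag(n_ge)))
    b <- c(b, rhs)
    u <- c(u, rep(Inf, n_ge))
    cost <- c(cost, numeric(n_ge))
  }
  if (ncol(A) == 0) {  # fully determined by fixed bounds
    feasible <- all(abs(b) <= options$lp_tolerance * max(1, max(abs(b), 0)))
    return(if (feasible) list(status = "optimal", x = numeric(0), value = 0)
           else list(status = "infeasible"))
  }
  res <- fbr_simplex(cost, A, b, u, max_iter = options$max_iter)
  if (res$status == "optimal") {
    list(status = "optimal", x = res$x[seq_len(prob$n_var)],
         value = if (maximize) -res$value else res$value)
  } else {
    list(status = res$status)
  }
}

new_solution <- function(status, rxns, fluxes, model, options,
                         stage1_growth = NA_real_) {
  if (status == "optimal") {
    growth <- unname(fluxes[model$biomass_id])
    total <- sum(abs(fluxes))
  } else {
    fluxes <- setNames(numeric(0), character(0))
    growth <- NA_real_
    total <- NA_real_
  }
  structure(
    list(status = status, fluxes = fluxes, growth_rate = growth,
         total_flux = total, stage1_growth = stage1_growth,
         biomass_id = model$biomass_id,
         reactions = tibble(
           reaction = model$reactions$id,
           lower_bound = model$reactions$lower_bound,
           upper_bound = model$reactions$upper_bound,
           is_exchange = model$reactions$is_exchange
         ),
         ratio_ids = names(model$ratio_constraints)),
    class = "fbr_solution"
  )
}

#' Build a flux solution from a hand-specified flux vector
#'
#' Mainly useful for auditing printed flux tables with [realized_ratio()] and
#' [ratio_residual()] without re-solving anything.
#'
#' @param fluxes Named numeric vector of fluxes in mmol/(h.gDCW).
#' @param growth_rate Optional growth rate.
#' @return An optimal `fbr_solution` carrying exactly these fluxes.
#' @examples
#' sol <- as_flux_solution(c(CoAT_ACETATE = 2.03, CoAT_BUTYRATE = 1.28,
#'                           BHBD = 3.04))
#' realized_ratio(sol, c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD")
#' @export
as_flux_solution <- function(fluxes, growth_rate = NA_real_) {
  stopifnot(is.numeric(fluxes), !is.null(names(fluxes)))
  structure(
    list(status = "optimal", fluxes = fluxes, growth_rate = growth_rate,
         total_flux = sum(abs(fluxes)), stage1_growth = growth_rate,
         biomass_id = NA_character_,
         reactions = tibble(reaction = names(fluxes),
                            lower_bound = -Inf, upper_bound = Inf,
                            is_exchange = FALSE),
         ratio_ids = character(0)),
    class = "fbr_solution"
  )
}

#' @export
print.fbr_solution <- function(x, ...) {
  cat("<fbr_solution> status:", x$status)
  if (x$status == "optimal") {
    cat(sprintf("  growth: %.6g 1/h  total flux: %.6g", x$growth_rate,
                x$total_flux))
  }
  cat("\n")
  invisible(x)
}

#' Fluxes of a solution as a tibble
#'
#' @param x An `fbr_solution`.
#' @param ... Unused.
#' @return One row per reaction with its flux and bounds; zero rows for
#'   non-optimal solutions.
#' @export
tidy.fbr_solution <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble(reaction = character(), flux = double(),
                  lower_bound = double(), upper_bound = double(),
                  is_exchange = logical()))
  }
  dplyr::mutate(x$reactions, flux = unname(x$fluxes[.data$reaction]),
                .after = "reaction")
}

#' One-row summary of a solution
#'
#' @param x An `fbr_solution`.
#' @param ... Unused.
#' @return A tibble with status, growth rate, total flux and problem size.
#' @export
glance.fbr_solution <- function(x, ...) {
  tibble(
    status = x$status,
    growth_rate = x$growth_rate,
    total_flux = x$total_flux,
    n_reactions = nrow(x$reactions),
    n_ratio_constraints = length(x$ratio_ids)
  )
}
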