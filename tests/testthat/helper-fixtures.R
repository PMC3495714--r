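# Shared fixtures: built in code, no data files.

# A -> B -> drain chain: uptake capped at 10, everything else forced through.
chain_model <- function(cap = 10) {
  metabolic_model(
    metabolites = tibble::tibble(
      id = c("a", "b"),
      name = c("metabolite A", "metabolite B"),
      compartment = "cytosol"
    ),
    reactions = tibble::tibble(
      id = c("uptake", "conv", "drain"),
      stoichiometry = list(c(a = 1), c(a = -1, b = 1), c(b = -1)),
      lower_bound = 0,
      upper_bound = c(cap, 1000, 1000),
      is_exchange = c(TRUE, FALSE, TRUE)
    ),
    biomass_id = "drain"
  )
}

# The bundled clostridial core model, built once per test file.
toy <- build_toy_model()
toy_wt <- add_wildtype_ratios(toy)

# Random small irreversible network for the encoding-equivalence oracle:
# a handful of metabolites, every reaction bounded in [0, ub], always
# feasible (v = 0) and bounded (finite ub).
random_small_model <- function(n_rxns = 6, n_mets = 3) {
  repeat {
    S <- matrix(0, n_mets, n_rxns)
    for (j in seq_len(n_rxns)) {
      rows <- sample(n_mets, sample(1:2, 1))
      S[rows, j] <- sample(c(-2, -1, 1, 2), length(rows), replace = TRUE)
    }
    # two exchange-like columns so nonzero flux is possible
    S[, 1] <- 0; S[1, 1] <- 1
    S[, n_rxns] <- 0; S[n_mets, n_rxns] <- -1
    if (all(rowSums(S != 0) > 0)) break
  }
  mets <- paste0("m", seq_len(n_mets))
  rownames(S) <- mets
  rxns <- paste0("r", seq_len(n_rxns))
  metabolic_model(
    metabolites = tibble::tibble(id = mets, name = mets, compartment = "c"),
    reactions = tibble::tibble(
      id = rxns,
      stoichiometry = lapply(seq_len(n_rxns), function(j) {
        s <- S[, j]; s[s != 0]
      }),
      lower_bound = 0,
      upper_bound = stats::runif(n_rxns, 5, 20),
      is_exchange = c(TRUE, rep(FALSE, n_rxns - 2), TRUE)
    ),
    biomass_id = rxns[n_rxns]
  )
}

# Independent route for the same ratio constraint: impose v_num = k * v_den
# by variable substitution (the numerator column is eliminated) and solve the
# reduced stage-1 LP. Tries the boot::simplex implementation first for solver
# independence; falls back to the package simplex on the rare numerically
# degenerate instance (the substitution route itself stays independent of the
# matrix-row encoding either way).
substitution_optimum <- function(model, num_id, den_id, k) {
  S <- stoich_matrix(model, ratio_rows = FALSE)
  i <- match(num_id, colnames(S))
  j <- match(den_id, colnames(S))
  b_idx <- match(model$biomass_id, colnames(S))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound

  S2 <- S[, -i, drop = FALSE]
  j2 <- match(den_id, colnames(S2))
  S2[, j2] <- S2[, j2] + k * S[, i]
  lb2 <- lb[-i]; ub2 <- ub[-i]
  if (k > 0) {
    lb2[j2] <- max(lb[j], lb[i] / k)
    ub2[j2] <- min(ub[j], ub[i] / k)
  }
  if (lb2[j2] > ub2[j2]) return(list(status = "infeasible", value = NA_real_))
  obj <- numeric(ncol(S2))
  if (num_id == model$biomass_id) {
    obj[j2] <- k
  } else if (den_id == model$biomass_id) {
    obj[j2] <- 1
  } else {
    obj[match(model$biomass_id, colnames(S2))] <- 1
  }

  via_boot <- tryCatch({
    res <- boot::simplex(a = obj, A1 = diag(ncol(S2)), b1 = ub2,
                         A3 = S2, b3 = rep(0, nrow(S2)), maxi = TRUE)
    if (res$solved == 1) list(status = "optimal", value = res$value)
    else if (res$solved == -1) list(status = "infeasible", value = NA_real_)
    else NULL
  }, error = function(e) NULL)
  if (!is.null(via_boot)) return(via_boot)

  res <- fbratio:::fbr_simplex(-obj, S2, rep(0, nrow(S2)), ub2)
  if (res$status == "optimal") list(status = "optimal", value = -res$value)
  else list(status = res$status, value = NA_real_)
}

# One encoding-vs-substitution comparison on a fresh random instance;
# returns TRUE when both routes agree (status, and optimum within tol).
encoding_matches_substitution <- function(tol = 1e-6) {
  m <- random_small_model(n_rxns = sample(5:8, 1))
  ids <- m$reactions$id
  pick <- sample(setdiff(seq_along(ids), 1), 2)
  k <- sample(c(0.5, 1, 2), 1)
  m2 <- add_flux_ratio(m, flux_ratio("rc", ids[pick[1]], ids[pick[2]], k))
  enc <- solve_fba(m2, solve_options(stage2_enabled = FALSE))
  sub <- substitution_optimum(m, ids[pick[1]], ids[pick[2]], k)
  if (enc$status != sub$status) return(FALSE)
  if (enc$status != "optimal") return(TRUE)
  ok_val <- abs(enc$growth_rate - sub$value) <= tol * max(1, abs(sub$value))
  ratio_ok <- {
    den <- enc$fluxes[[ids[pick[2]]]]
    num <- enc$fluxes[[ids[pick[1]]]]
    abs(num - k * den) <= 1e-6 * (1 + abs(den))
  }
  ok_val && ratio_ok
}
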