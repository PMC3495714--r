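test_that("model validation enforces the structural invariants", {
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = c("a", "a"), name = "x",
                                   compartment = "c"),
      reactions = NULL
    ),
    "Duplicate metabolite"
  )
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = "a", name = "a", compartment = "c"),
      reactions = tibble::tibble(
        id = "r", stoichiometry = list(c(missing_met = 1)),
        lower_bound = 0, upper_bound = 10, is_exchange = FALSE
      )
    ),
    "unknown metabolite"
  )
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = c("a", "b"), name = "x",
                                   compartment = "c"),
      reactions = tibble::tibble(
        id = "ex", stoichiometry = list(c(a = -1, b = 1)),
        lower_bound = 0, upper_bound = 10, is_exchange = TRUE
      )
    ),
    "exactly one metabolite"
  )
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = "a", name = "a", compartment = "c"),
      reactions = tibble::tibble(
        id = "r", stoichiometry = list(c(a = 1)),
        lower_bound = 5, upper_bound = 1, is_exchange = TRUE
      )
    ),
    "lower_bound > upper_bound"
  )
})

test_that("a hand-written chain model assembles the expected matrix", {
  m <- chain_model()
  S <- stoich_matrix(m)
  expect_identical(dim(S), c(2L, 3L))
  expect_equal(S["a", ], c(uptake = 1, conv = -1, drain = 0))
  expect_equal(S["b", ], c(uptake = 0, conv = 1, drain = -1))
})

test_that("matrix dimensions grow by one row per ratio constraint", {
  m <- chain_model()
  expect_identical(nrow(stoich_matrix(m)), 2L)
  m2 <- add_flux_ratio(m, flux_ratio("rc", "uptake", "conv", 1))
  expect_identical(nrow(stoich_matrix(m2)), 3L)
  expect_identical(ncol(stoich_matrix(m2)), 3L)
  expect_identical(rownames(stoich_matrix(m2))[3], "rc")
})

test_that("missing bounds default to the conventional box", {
  m <- metabolic_model(
    metabolites = tibble::tibble(id = "a", name = "a", compartment = "c"),
    reactions = tibble::tibble(
      id = c("r1", "r2"),
      stoichiometry = list(c(a = 1), c(a = -1)),
      lower_bound = c(NA_real_, -Inf),
      upper_bound = c(NA_real_, Inf),
      is_exchange = TRUE
    )
  )
  expect_equal(m$reactions$lower_bound, c(0, -1000))
  expect_equal(m$reactions$upper_bound, c(1000, 1000))
})

test_that("an irreversibility table overwrites exactly the listed bounds", {
  m <- chain_model()
  m2 <- apply_irreversibility_table(
    m, tibble::tibble(reaction = "conv", lower = 0, upper = 50))
  expect_equal(m2$reactions$upper_bound[m2$reactions$id == "conv"], 50)
  expect_equal(m2$reactions$upper_bound[m2$reactions$id == "uptake"], 10)
  # empty table is the identity
  expect_identical(apply_irreversibility_table(m, tibble::tibble(
    reaction = character(), lower = double(), upper = double())), m)
  expect_error(
    apply_irreversibility_table(
      m, tibble::tibble(reaction = "nope", lower = 0, upper = 1)),
    "nope"
  )
})

test_that("blocking the hydrogenase zeroes hydrogen export", {
  m <- apply_irreversibility_table(
    toy, tibble::tibble(reaction = "HYDA", lower = 0, upper = 0))
  sol <- solve_at_spf(m, -10)
  expect_identical(sol$status, "optimal")
  expect_equal(unname(sol$fluxes["EX_H2"]), 0)
})

test_that("ferredoxin reactions carry the irreversibility bounds", {
  tab <- ferredoxin_bounds_table()
  idx <- match(tab$reaction, toy$reactions$id)
  expect_equal(toy$reactions$lower_bound[idx], rep(0, 4))
  expect_equal(toy$reactions$upper_bound[idx], rep(1000, 4))
})

test_that("optimal fluxes respect reaction bounds and all matrix rows", {
  sol <- solve_at_spf(toy_wt, -8)
  td <- tidy(sol)
  expect_true(all(td$flux >= td$lower_bound - 1e-6))
  expect_true(all(td$flux <= td$upper_bound + 1e-6))
  m <- set_spf(set_glucose_uptake(toy_wt, 10), -8)
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes[colnames(S)])), 1e-8)
})
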