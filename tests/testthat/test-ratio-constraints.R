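test_that("the appended row encodes +w and -k*w in the right columns", {
  m <- add_flux_ratio(toy, flux_ratio("thl_pta", "THL", "PTA", 2))
  row <- stoich_matrix(m)["thl_pta", ]
  expect_identical(unname(row["THL"]), 1)
  expect_identical(unname(row["PTA"]), -2)
  expect_identical(sum(row != 0), 2L)

  # unit ratio between two arbitrary reactions: +1 / -1
  m2 <- add_flux_ratio(toy, flux_ratio("sym", "LDH", "PFO", 1))
  row2 <- stoich_matrix(m2)["sym", ]
  expect_equal(unname(row2[c("LDH", "PFO")]), c(1, -1))

  # multi-reaction numerator with fractional k
  m3 <- add_flux_ratio(toy, flux_ratio(
    "coat_bhbd", c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD", 1.09))
  row3 <- stoich_matrix(m3)["coat_bhbd", ]
  expect_equal(unname(row3[c("CoAT_ACETATE", "CoAT_BUTYRATE", "BHBD")]),
               c(1, 1, -1.09))
})

test_that("constructor rejects malformed constraints", {
  expect_error(flux_ratio("x", "THL", "THL", 2), "disjoint")
  expect_error(flux_ratio("x", character(0), "PTA", 2), "non-empty")
  expect_error(flux_ratio("x", c(THL = -1), "PTA", 2), "positive")
  expect_error(flux_ratio("x", "THL", "PTA", -1), "non-negative")
  expect_error(add_flux_ratio(toy, flux_ratio("x", "NOPE", "PTA", 2)),
               "NOPE")
  m <- add_flux_ratio(toy, flux_ratio("dup", "THL", "PTA", 2))
  expect_error(add_flux_ratio(m, flux_ratio("dup", "LDH", "PFO", 1)),
               "already exists")
})

test_that("reversible participants trigger a net-flux warning", {
  expect_warning(add_flux_ratio(toy, flux_ratio("p", "PTB", "AAD_2", 0.25)),
                 "net signed fluxes")
})

test_that("removal restores the original matrix and preserves sibling order", {
  m <- toy
  m <- add_flux_ratio(m, flux_ratio("r1", "THL", "PTA", 2))
  m <- add_flux_ratio(m, flux_ratio("r2", "LDH", "PFO", 1))
  m <- add_flux_ratio(m, flux_ratio("r3", "HYDA", "FNO", 3))
  m2 <- remove_flux_ratio(m, "r2")
  S <- stoich_matrix(m2)
  expect_identical(tail(rownames(S), 2), c("r1", "r3"))
  expect_equal(S["r1", ], stoich_matrix(m)["r1", ])
  expect_equal(S["r3", ], stoich_matrix(m)["r3", ])
  m3 <- remove_flux_ratio(remove_flux_ratio(m2, "r1"), "r3")
  expect_equal(stoich_matrix(m3), stoich_matrix(toy))
  expect_error(remove_flux_ratio(m3, "r1"), "No ratio constraint")
})

test_that("the residual is the scaled linear-constraint violation", {
  sol <- as_flux_solution(c(num = 3, den = 1))
  rc <- flux_ratio("rc", "num", "den", 2)
  expect_equal(ratio_residual(sol, rc), 0.5)  # |3 - 2*1| / (1 + 1)
  zero <- as_flux_solution(c(num = 0, den = 0))
  expect_equal(ratio_residual(zero, rc), 0)
  expect_error(
    ratio_residual(structure(list(status = "infeasible"),
                             class = "fbr_solution"), rc),
    "optimal"
  )
})

test_that("realized_ratio reproduces hand-computed quotients and guards zero", {
  sol <- as_flux_solution(c(CoAT_ACETATE = 2.03, CoAT_BUTYRATE = 1.28,
                            BHBD = 3.04))
  expect_equal(
    round(realized_ratio(sol, c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD"), 2),
    1.09
  )
  expect_equal(round(realized_ratio(sol, "CoAT_BUTYRATE", "CoAT_ACETATE"), 2),
               0.63)
  none <- as_flux_solution(c(a = 1, b = 0))
  expect_true(is.na(realized_ratio(none, "a", "b")))
})

test_that("solutions of a constrained model satisfy the constraint to 1e-6", {
  m <- add_flux_ratio(toy, flux_ratio("thl_pta", "THL", "PTA", 2))
  for (spf in c(-12, -6, 0, 5)) {
    sol <- solve_at_spf(m, spf)
    expect_identical(sol$status, "optimal")
    expect_lt(ratio_residual(sol, m$ratio_constraints$thl_pta), 1e-6)
  }
})

test_that("a zero-valued ratio forces the numerator to zero", {
  m <- add_flux_ratio(toy, flux_ratio("ldh_off", "LDH", "PFO", 0))
  sol <- solve_at_spf(m, -10)
  expect_identical(sol$status, "optimal")
  expect_equal(unname(sol$fluxes["LDH"]), 0)
})

test_that("adding a ratio constraint never increases optimal growth", {
  base <- solve_at_spf(toy, -8)
  for (k in c(0.5, 2, 10)) {
    m <- add_flux_ratio(toy, flux_ratio("rc", "THL", "PTA", k))
    sol <- solve_at_spf(m, -8)
    if (sol$status == "optimal") {
      expect_lte(sol$growth_rate, base$growth_rate + 1e-8)
    }
  }
})

test_that("an impossible ratio yields infeasibility, not a wrong answer", {
  m <- chain_model()
  # the chain forces uptake == conv, so a 2:1 ratio with forced flux through
  # the drain is contradictory
  m <- set_bounds(m, "drain", lower = 1)
  m <- add_flux_ratio(m, flux_ratio("bad", "uptake", "conv", 2))
  sol <- solve_fba(m)
  expect_identical(sol$status, "infeasible")
  expect_length(sol$fluxes, 0)
})
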