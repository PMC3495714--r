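test_that("the core model contains every required reaction and exchange", {
  required <- c(
    "GLC_UPTAKE", "GLYCOLYSIS", "LDH", "PFO", "FNO", "FNPO", "HYDA", "PTA",
    "AK", "AAD_1", "AAD_2", "AAD_3", "BDH", "THL", "BHBD", "CRO", "BCD",
    "PTB", "BK", "CoAT_ACETATE", "CoAT_BUTYRATE", "AADC", "CO2_EXPORT",
    "CO2_TO_HCO3", "PYR_TO_OAA", "SUCC_EXPORT", "H_EXCHANGE", "BIOMASS",
    "EX_GLC", "EX_AC", "EX_BUT", "EX_LAC", "EX_ETOH", "EX_BTOH",
    "EX_ACETONE", "EX_H2", "EX_CO2", "EX_SUCC"
  )
  expect_true(all(required %in% toy$reactions$id))
  expect_identical(toy$biomass_id, "BIOMASS")
  expect_identical(toy$proton_exchange_id, "H_EXCHANGE")
})

test_that("branch-point stoichiometries match the textbook reactions", {
  thl <- toy$reactions$stoichiometry[[match("THL", toy$reactions$id)]]
  expect_equal(thl[c("accoa", "aacoa", "coa")], c(accoa = -2, aacoa = 1, coa = 1))
  pta <- toy$reactions$stoichiometry[[match("PTA", toy$reactions$id)]]
  expect_equal(pta[c("accoa", "pi", "actp", "coa")],
               c(accoa = -1, pi = -1, actp = 1, coa = 1))
  hyda <- toy$reactions$stoichiometry[[match("HYDA", toy$reactions$id)]]
  expect_equal(hyda[c("h_c", "fdred", "h2", "fdox")],
               c(h_c = -2, fdred = -1, h2 = 1, fdox = 1))
})

test_that("acid secretion is unidirectional with re-uptake only via CoAT", {
  for (r in c("AC_SECRETION", "BUT_SECRETION", "LAC_SECRETION")) {
    i <- match(r, toy$reactions$id)
    expect_gte(toy$reactions$lower_bound[i], 0)
  }
  # the only consumers of extracellular acetate/butyrate besides the
  # exchanges are the two CoA-transferase reactions
  consumers <- function(met) {
    uses <- vapply(toy$reactions$stoichiometry,
                   function(s) isTRUE(s[met] < 0), logical(1))
    setdiff(toy$reactions$id[uses], c("EX_AC", "EX_BUT"))
  }
  expect_identical(consumers("ac_e"), "CoAT_ACETATE")
  expect_identical(consumers("but_e"), "CoAT_BUTYRATE")
})

test_that("every internal reaction balances carbon and conserved moieties", {
  audit <- audit_toy_balances(toy)
  expect_equal(max(abs(as.matrix(audit[, -1]))), 0)
})

test_that("the wild-type ratio set matches the published five constraints", {
  wt <- wildtype_ratio_set()
  expect_length(wt, 5)
  vals <- setNames(vapply(wt, `[[`, 0, "ratio"),
                   vapply(wt, `[[`, "", "id"))
  expect_equal(unname(vals["coat_butyrate_acetate"]), 0.63)
  expect_equal(unname(vals["pfo_ldh"]), 10)
  expect_equal(unname(vals["co2_export_conversion"]), 5)
  expect_equal(unname(vals["thl_pta"]), 2)
  expect_equal(unname(vals["thl_aad1"]), 10)
})

test_that("the unconstrained fixture grows at a mid-acidogenic proton flux", {
  sol <- solve_at_spf(toy, -10)
  expect_identical(sol$status, "optimal")
  expect_gt(sol$growth_rate, 0)
})

test_that("solventogenic orderings hold at SPF +5 under the wild-type ratios", {
  sol <- solve_at_spf(toy_wt, 5)
  expect_identical(sol$status, "optimal")
  f <- sol$fluxes
  expect_gt(f[["EX_BTOH"]], f[["EX_ETOH"]])
  expect_lte(f[["EX_AC"]], 1e-6)
  expect_lte(f[["EX_BUT"]], 1e-6)
  expect_lte(f[["EX_SUCC"]], 0.05 * 10)
  # lactate is pinned to a tenth of the PFO flux by the pyruvate-node ratio
  expect_equal(f[["EX_LAC"]], f[["PFO"]] / 10, tolerance = 1e-6)
})

test_that("acidogenic orderings hold at strongly negative SPF", {
  sol <- solve_at_spf(toy_wt, -15)
  expect_identical(sol$status, "optimal")
  f <- sol$fluxes
  expect_gt(f[["EX_BUT"]], f[["EX_AC"]])
  expect_gt(f[["EX_AC"]], f[["EX_LAC"]])
  expect_gt(f[["EX_H2"]] / f[["EX_CO2"]], 0.8)
  expect_lt(f[["EX_H2"]] / f[["EX_CO2"]], 1.2)
})

test_that("the succinate branch is optional", {
  m <- build_toy_model(toy_model_config(include_tca_to_succinate = FALSE))
  expect_false("OAA_TO_SUCC" %in% m$reactions$id)
  expect_false("succ" %in% m$metabolites$id)
  sol <- solve_at_spf(add_wildtype_ratios(m), -10)
  expect_identical(sol$status, "optimal")
})
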