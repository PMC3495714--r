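test_that("knockdown arithmetic reproduces the published mappings", {
  expect_equal(knockdown_ratio(10, 0.8, "denominator"), 50)
  expect_equal(knockdown_ratio(0.25, 0.8, "denominator"), 1.25)
  expect_equal(knockdown_ratio(1.09, 0.8, "numerator"), 0.218)
  expect_equal(knockdown_ratio(7, 0, "numerator"), 7)
  expect_equal(knockdown_ratio(7, 0, "denominator"), 7)
  expect_equal(knockdown_ratio(5, 1, "numerator"), 0)
  expect_error(knockdown_ratio(5, 1, "denominator"), "knockout")
})

test_that("over-expression arithmetic follows the doubling convention", {
  expect_equal(overexpress_ratio(10, 100, "denominator"), 5)
  expect_equal(overexpress_ratio(10, 200, "denominator"), 2.5)
  expect_equal(overexpress_ratio(10, 500, "denominator"), 0.3125)
  expect_equal(overexpress_ratio(10, 0, "denominator"), 10)
  expect_equal(overexpress_ratio(10, 0, "numerator"), 10)
  expect_equal(overexpress_ratio(2, 100, "numerator"), 4)
  # the linear convention is available as an alternative
  expect_equal(overexpress_ratio(10, 100, "denominator", "linear"), 5)
  expect_equal(overexpress_ratio(10, 300, "denominator", "linear"), 2.5)
})

test_that("knockdown and over-expression are mutually inverse", {
  for (p in c(50, 100, 250, 500)) {
    f <- 1 - 2^(-p / 100)
    expect_equal(
      knockdown_ratio(overexpress_ratio(3.7, p, "denominator"), f,
                      "denominator"),
      3.7, tolerance = 1e-12
    )
    expect_equal(
      knockdown_ratio(overexpress_ratio(3.7, p, "numerator"), f, "numerator"),
      3.7, tolerance = 1e-12
    )
  }
})

test_that("the assumed solventogenic PTB:AAD_2 reference is exposed", {
  expect_equal(FBR_WT_PTB_AAD2, 0.25)
  expect_equal(knockdown_ratio(FBR_WT_PTB_AAD2, 0.8, "denominator"), 1.25)
})

test_that("a wild-type profile interpolates realized ratios across the scan", {
  scan <- scan_spf(toy_wt, spf_values = seq(-4, 5, by = 3))
  prof <- wildtype_ratio_profile(scan, c("CoAT_ACETATE", "CoAT_BUTYRATE"),
                                 "BHBD")
  expect_s3_class(prof, "fbr_profile")
  # knots reproduce the rows exactly; interpolation passes through them
  sol <- solve_at_spf(toy_wt, 5)
  expect_equal(
    profile_value(prof, 5),
    realized_ratio(sol, c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD"),
    tolerance = 1e-8
  )
  expect_error(
    wildtype_ratio_profile(scan, "THL", "NOPE"),
    "does not track"
  )
})

test_that("a profile under an active constraint is flat at the target", {
  m <- suppressWarnings(add_flux_ratio(
    toy_wt, flux_ratio("cb", c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD", 0.5)))
  scan <- scan_spf(m, spf_values = c(1, 3, 5))
  prof <- wildtype_ratio_profile(scan, c("CoAT_ACETATE", "CoAT_BUTYRATE"),
                                 "BHBD")
  expect_equal(prof$ratio, rep(0.5, nrow(prof)), tolerance = 1e-6)
})

test_that("profile scaling is pointwise and keeps the knots", {
  prof <- ratio_profile(spf = c(-2, 0, 5), ratio = c(0.4, 0.8, 1.09))
  s <- scale_profile(prof, 0.25)
  expect_equal(s$spf, prof$spf)
  expect_equal(s$ratio, prof$ratio * 0.25)
  expect_equal(profile_value(s, 5), 0.2725)
  expect_true(all(s$ratio <= prof$ratio))
  expect_identical(scale_profile(prof, 1), prof)
})

test_that("an empty edit list reproduces the wild-type scan", {
  grid <- c(-10, -2, 5)
  a <- simulate_strategy(toy, wildtype_ratio_set(), spf_values = grid)
  b <- scan_spf(toy_wt, spf_values = grid)
  expect_equal(as.data.frame(a)[names(b)], as.data.frame(b),
               ignore_attr = TRUE)
  expect_identical(attr(a, "strategy"), "wild type")
})

test_that("conflicting edits on one constraint are rejected with names", {
  expect_error(
    simulate_strategy(toy, wildtype_ratio_set(), edits = list(
      engineering_edit("thl_aad1", "denominator", "knockdown", 0.8),
      engineering_edit("thl_aad1", "denominator", "overexpression", 100)
    ), spf_values = 0),
    "thl_aad1"
  )
  expect_error(
    simulate_strategy(toy, wildtype_ratio_set(), edits = list(
      engineering_edit("nope", "denominator", "knockdown", 0.5)
    ), spf_values = 0),
    "unknown ratio constraint"
  )
})

test_that("a knockout edit zeroes every target-side flux", {
  scan <- simulate_strategy(
    toy, wildtype_ratio_set(),
    edits = list(engineering_edit("coat_butyrate_acetate", "numerator",
                                  "knockout")),
    spf_values = c(-8, -2, 4)
  )
  ok <- scan$status == "optimal"
  expect_true(any(ok))
  expect_equal(scan$CoAT_BUTYRATE[ok], rep(0, sum(ok)))
})

test_that("an 80% denominator knockdown rewrites the ratio to 50", {
  m <- add_wildtype_ratios(toy)
  m2 <- fbratio:::apply_edits(m, list(
    engineering_edit("thl_aad1", "denominator", "knockdown", 0.8)))
  expect_equal(m2$ratio_constraints$thl_aad1$ratio, 50)
})

test_that("CoAT knockdown trades acetone for butanol selectivity", {
  # fixed CoAT:BHBD values imposed on top of the wild-type set, solved in
  # the solventogenic regime; deeper knockdown must not raise acetone and
  # must not lower butanol:acetone selectivity
  ks <- c(1, 0.5, 0.1)
  res <- vapply(ks, function(k) {
    m <- suppressWarnings(add_flux_ratio(
      toy_wt, flux_ratio("cb", c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD", k)))
    sol <- solve_at_spf(m, 5)
    expect_identical(sol$status, "optimal")
    c(sol$fluxes[["EX_ACETONE"]], sol$fluxes[["EX_BTOH"]])
  }, numeric(2))
  expect_true(all(diff(res[1, ]) <= 1e-6))
  selectivity <- res[2, ] / pmax(res[1, ], 1e-9)
  expect_true(all(diff(selectivity) >= -1e-6))
})

test_that("joint CoAT and AAD knockdown suppresses ethanol", {
  # the 80% bundle: THL:AAD_1 10 -> 50, new PTB:AAD_2 at 1.25, CoAT:BHBD at
  # 0.2. The acetaldehyde-routing ratio (AAD_3:AAD_1) is satisfied by
  # construction here: the core model has a single acetaldehyde source and
  # sink, so no futile acetaldehyde production exists to correct.
  wt <- solve_at_spf(toy_wt, 3)
  scan <- suppressWarnings(simulate_strategy(
    toy, wildtype_ratio_set(),
    edits = list(engineering_edit("thl_aad1", "denominator", "knockdown", 0.8)),
    extra_ratios = list(
      flux_ratio("ptb_aad2", "PTB", "AAD_2",
                 knockdown_ratio(FBR_WT_PTB_AAD2, 0.8, "denominator")),
      flux_ratio("coat_bhbd", c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD", 0.2)
    ),
    spf_values = 3
  ))
  expect_identical(scan$status, "optimal")
  expect_lt(scan$EX_ETOH, wt$fluxes[["EX_ETOH"]])
  expect_gt(scan$EX_BTOH, 0)
})

test_that("AAD over-expression raises ethanol production monotonically", {
  etoh <- vapply(c(10, 5, 2.5, 0.3125), function(v) {
    m <- set_ratio_value(toy_wt, "thl_aad1", v)
    sol <- solve_at_spf(m, 5)
    expect_identical(sol$status, "optimal")
    sol$fluxes[["EX_ETOH"]]
  }, numeric(1))
  expect_true(all(diff(etoh) > 0))
})

test_that("profile-driven constraints re-target each SPF point", {
  prof <- ratio_profile(spf = c(0, 5), ratio = c(0.6, 1.0))
  scan <- suppressWarnings(simulate_strategy(
    toy, wildtype_ratio_set(),
    extra_ratios = list(flux_ratio(
      "cb", c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD", 1)),
    profile_ratios = list(cb = prof),
    spf_values = c(0, 5)
  ))
  ok <- scan$status == "optimal"
  realized <- (scan$CoAT_ACETATE + scan$CoAT_BUTYRATE) / scan$BHBD
  expect_equal(realized[ok], profile_value(prof, scan$spf[ok]),
               tolerance = 1e-6)
})
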