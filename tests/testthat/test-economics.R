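test_that("per-cycle state costs assemble the right price components", {
  us <- us_scenario()
  # mid-treatment PFS cycle, drug components only: durvalumab + gem + cis
  expect_equal(cycle_cost("pfs", "durva", 3, us, components = "drug"),
               11730 + 15.06 + 8.72)
  # chemotherapy beyond its 8-cycle cap has no drug cost left
  expect_equal(cycle_cost("pfs", "chemo", 8, us, components = "drug"), 0)
  expect_gt(cycle_cost("pfs", "chemo", 7, us, components = "drug"), 0)
  # death costs nothing, ever
  expect_identical(cycle_cost("death", "durva", 0, us), 0)
  expect_identical(cycle_cost("death", "chemo", 100, us), 0)
  # first-hospitalization items only at cycle 0
  c0 <- cycle_cost("pfs", "chemo", 0, us)
  c1 <- cycle_cost("pfs", "chemo", 1, us)
  expect_gt(c0 - c1, 482.07 + 1457.11 - 1e-9)
  expect_error(cycle_cost("remission", "durva", 0, us))
})

test_that("adverse-event burden is the risk-weighted sum over Table events", {
  us <- us_scenario()
  bd <- ae_burden("durva", us)
  # 0.207*466 + 0.192*354 + 0.189*531 + 0.08*1814, by hand
  expect_equal(bd$cost, 409.909, tolerance = 1e-9)
  expect_equal(bd$decrement,
               0.207 * 0.09 + 0.192 * 0.09 + 0.189 * 0.125 + 0.08 * 0.20,
               tolerance = 1e-12)
  expect_equal(bd$qaly_loss, bd$decrement * 21 / 365.25, tolerance = 1e-12)
  bc <- ae_burden("chemo", us)
  expect_equal(bc$cost, 427.033, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(bd$cost, bc$cost)))
  # zero risks give a zero burden
  zero <- setNames(
    rep(0, 4), paste0("ae.", names(us$adverse_events), ".risk_durva"))
  expect_equal(ae_burden("durva", us, params = as.list(zero))$cost, 0)
})

test_that("incremental statistics follow their definitions", {
  cea <- compute_cea(chemo = list(cost = 100, ly = 1, qaly = 1),
                     durva = list(cost = 200, ly = 2, qaly = 2),
                     wtp = 150)
  expect_equal(cea$icer_qaly, 100)
  expect_equal(cea$icer_ly, 100)
  expect_equal(cea$incremental_nmb, 150 * 1 - 100)
  # NMB arithmetic at the published US totals
  cea2 <- compute_cea(chemo = list(cost = 0, ly = 0, qaly = 0),
                      durva = list(cost = 217069.25, ly = 2.3, qaly = 1.52),
                      wtp = 150000)
  expect_equal(cea2$strategies$nmb[2], 10930.75)
  # zero incremental effect is a dominance category, not an ICER
  cea3 <- compute_cea(chemo = list(cost = 100, ly = 1, qaly = 1),
                      durva = list(cost = 200, ly = 1, qaly = 1), wtp = 150)
  expect_true(is.na(cea3$icer_qaly))
  expect_false(is.na(cea3$dominance))
})

test_that("the ICER divides unrounded totals", {
  us <- us_scenario()
  cea <- run_base_case(us)
  expect_equal(cea$icer_qaly, cea$delta_cost / cea$delta_qaly)
  expect_equal(cea$icer_ly, cea$delta_cost / cea$delta_ly)
})

test_that("total cost is linear in the cost parameters", {
  us <- us_scenario()
  pt <- param_table(us)
  cost_names <- pt$name[pt$dist == "gamma"]
  base <- as.list(base_params(us))
  doubled <- base
  doubled[cost_names] <- lapply(doubled[cost_names], `*`, 2)
  w <- arm_weights(us, "durva")
  a1 <- arm_outcomes(us, "durva", w = w)
  a2 <- arm_outcomes(us, "durva", w = w, params = doubled)
  expect_equal(a2$cost, 2 * a1$cost, tolerance = 1e-12)
  expect_equal(a2$qaly, a1$qaly)
  # and hence the ICER doubles too
  wc <- arm_weights(us, "chemo")
  c1 <- arm_outcomes(us, "chemo", w = wc)
  c2 <- arm_outcomes(us, "chemo", w = wc, params = doubled)
  icer1 <- compute_cea(c1, a1, us$wtp)$icer_qaly
  icer2 <- compute_cea(c2, a2, us$wtp)$icer_qaly
  expect_equal(icer2, 2 * icer1, tolerance = 1e-12)
})

test_that("unit utilities and no disutility make QALYs equal life-years", {
  us <- us_scenario()
  # both utilities 1, all disutilities 0
  overrides <- c(list(utility.pfs = 1, utility.pd = 1),
                 setNames(as.list(rep(0, length(us$adverse_events))),
                          paste0("ae.", names(us$adverse_events),
                                 ".disutility")))
  for (arm in c("durva", "chemo")) {
    a <- arm_outcomes(us, arm, params = overrides)
    expect_equal(a$qaly, a$ly, tolerance = 1e-12)
  }
})

test_that("total cost is monotone in every individual cost parameter", {
  us <- us_scenario()
  pt <- param_table(us)
  cost_names <- pt$name[pt$dist == "gamma"]
  w <- arm_weights(us, "durva")
  base_cost <- arm_outcomes(us, "durva", w = w)$cost
  for (nm in cost_names) {
    bumped <- setNames(list(unname(base_params(us)[nm] * 1.1)), nm)
    expect_gte(arm_outcomes(us, "durva", w = w, params = bumped)$cost,
               base_cost - 1e-9)
  }
})

test_that("arm cost breakdown components are all charged", {
  us <- us_scenario()
  a <- arm_outcomes(us, "durva")
  expect_true(all(a$breakdown > 0))
  expect_equal(a$cost, sum(a$breakdown))
  b <- arm_outcomes(us, "chemo")
  # no durvalumab in first-line chemotherapy costs
  expect_lt(b$breakdown["first_line_drugs"], 1000)
})
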