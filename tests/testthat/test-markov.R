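test_that("model settings derive the cycle grid of the base case", {
  st <- model_settings()
  expect_equal(st$n_cycles, 173L)  # floor(10 * 365.25 / 21)
  expect_equal(st$cycle_months, 21 / 30.4375)
  expect_error(model_settings(discount_cost = 0.5), "discount")
})

test_that("per-cycle death probability matches the closed form at cycle 0", {
  mods <- btc_survival_models()
  sched <- transition_schedule(mods$durva_os, mods$durva_pfs,
                               method = "os-matched")
  # 1 - S_os(one cycle) for the durvalumab-arm log-logistic OS model
  expect_equal(sched$p_pfs_death[1],
               1 - 1 / (1 + ((21 / 30.4375) / 13.55)^1.81),
               tolerance = 1e-9)
  expect_equal(sched$p_pfs_death[1], 0.004544, tolerance = 1e-3)
})

test_that("coinciding OS and PFS curves imply no progression (os-matched)", {
  sp <- surv_spec("exponential", rate = 0.05)
  sched <- transition_schedule(sp, sp, method = "os-matched")
  expect_true(all(sched$p_pfs_pd == 0))
})

test_that("transition rows are proper probabilities for random model pairs", {
  set.seed(161)
  for (r in 1:10) {
    os <- surv_spec("loglogistic", shape = runif(1, 1, 3),
                    scale = runif(1, 8, 20))
    pfs <- surv_spec("gamma", shape = runif(1, 1, 4), rate = runif(1, 0.1, 1))
    for (m in c("pd-routed", "os-matched")) {
      sched <- suppressWarnings(transition_schedule(os, pfs, method = m))
      p <- as.matrix(sched[, c("p_pfs_pd", "p_pfs_death", "p_pd_death")])
      expect_true(all(p >= 0 & p <= 1))
      expect_true(all(p[, 1] + p[, 2] <= 1 + 1e-12))
    }
  }
})

test_that("occupancy is conserved and death is absorbing over the horizon", {
  mods <- btc_survival_models()
  for (m in c("pd-routed", "os-matched")) {
    sched <- transition_schedule(mods$chemo_os, mods$chemo_pfs, method = m)
    tr <- run_trace(sched)
    expect_equal(nrow(tr), 174)
    expect_true(all(abs(tr$pfs + tr$pd + tr$death - 1) < 1e-9))
    expect_true(all(tr$pfs >= 0 & tr$pd >= 0 & tr$death >= 0))
    expect_true(all(diff(tr$death) >= -1e-12))
  }
})

test_that("a single idle cycle accrues exactly one cycle of life", {
  st <- short_settings(n_cycles = 1, discount = 0)
  expect_equal(st$n_cycles, 1L)
  sched <- manual_schedule(0, 0, 0)
  tr <- run_trace(sched, utilities = list(pfs = 1, pd = 1), settings = st)
  tot <- trace_totals(tr)
  expect_equal(unname(tot["ly"]), 21 / 365.25)
  expect_equal(unname(tot["qaly"]), unname(tot["ly"]))
  expect_equal(unname(tot["dly"]), unname(tot["ly"]))  # r = 0
})

test_that("out-of-bounds transition rows are rejected", {
  st <- short_settings(n_cycles = 1)
  expect_error(run_trace(manual_schedule(0.7, 0.5, 0), settings = st),
               "out of bounds")
  expect_error(run_trace(manual_schedule(-0.1, 0, 0), settings = st),
               "out of bounds")
})

test_that("the os-matched trace reproduces both input curves to 1e-6", {
  mods <- btc_survival_models()
  for (arm in c("durva", "chemo")) {
    os <- mods[[paste0(arm, "_os")]]
    pfs <- mods[[paste0(arm, "_pfs")]]
    sched <- transition_schedule(os, pfs, method = "os-matched")
    expect_false(attr(sched, "clipped"))
    tr <- run_trace(sched)
    expect_lte(validate_against_curves(tr, os, pfs), 1e-6)
  }
})

test_that("a PFS curve above OS triggers the clipping warning", {
  mods <- btc_survival_models()
  expect_warning(transition_schedule(mods$durva_pfs, mods$durva_os,
                                     method = "os-matched"),
                 "clipping")
})

test_that("discounting can only shrink totals and vanishes at r = 0", {
  mods <- btc_survival_models()
  st5 <- model_settings(discount_effect = 0.05)
  st0 <- model_settings(discount_effect = 0)
  sched <- transition_schedule(mods$durva_os, mods$durva_pfs, st5)
  t5 <- trace_totals(run_trace(sched, settings = st5))
  t0 <- trace_totals(run_trace(sched, settings = st0))
  expect_lt(t5["dly"], t5["ly"])
  expect_equal(unname(t0["dly"]), unname(t0["ly"]))
  expect_equal(unname(t5["ly"]), unname(t0["ly"]))
})

test_that("the trace is stable under cycle-length refinement", {
  mods <- btc_survival_models()
  ly_for <- function(cycle_days) {
    st <- model_settings(cycle_days = cycle_days, discount_effect = 0)
    sched <- transition_schedule(mods$durva_os, mods$durva_pfs, st,
                                 method = "os-matched")
    unname(trace_totals(run_trace(sched, settings = st))["ly"])
  }
  expect_equal(ly_for(21), ly_for(10.5), tolerance = 0.01)
})

test_that("undiscounted life-years equal the restricted mean survival", {
  mods <- btc_survival_models()
  for (arm in c("durva", "chemo")) {
    os <- mods[[paste0(arm, "_os")]]
    pfs <- mods[[paste0(arm, "_pfs")]]
    st <- model_settings(discount_effect = 0)
    sched <- transition_schedule(os, pfs, st, method = "os-matched")
    ly <- unname(trace_totals(run_trace(sched, settings = st))["ly"])
    # trapezoid restricted mean of the OS curve over the modelled horizon
    tg <- seq(0, 173 * 21 / 30.4375, length.out = 4001)
    s <- survival_at(os, tg)
    rmst <- sum((s[-1] + s[-length(s)]) / 2 * diff(tg)) / 12
    expect_equal(ly, rmst, tolerance = 0.01)
  }
})

test_that("traces export in the documented CSV layout", {
  mods <- btc_survival_models()
  sched <- transition_schedule(mods$chemo_os, mods$chemo_pfs)
  tr <- run_trace(sched)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read.csv(path)
  expect_true(all(c("cycle", "t_years", "pfs", "pd", "death", "ly_inc",
                    "qaly_inc", "dly_inc", "dqaly_inc") %in% names(back)))
  expect_equal(nrow(back), 174)
})
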