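test_that("closed-form survival matches hand-computed values", {
  ll <- surv_spec("loglogistic", shape = 1.81, scale = 13.55)
  expect_identical(survival_at(ll, 0), 1)
  # median of the log-logistic equals its scale under this parameterization
  expect_equal(survival_at(ll, 13.55), 0.5, tolerance = 1e-12)
  # direct evaluation 1/(1 + (24/13.55)^1.81)
  expect_equal(survival_at(ll, 24), 0.262170, tolerance = 1e-5)

  # gamma survival checked against numerical integration of its own density
  ga <- surv_spec("gamma", shape = 2.76, rate = 0.38)
  f <- function(x) 0.38^2.76 / gamma(2.76) * x^(2.76 - 1) * exp(-0.38 * x)
  s6 <- 1 - integrate(f, 0, 6)$value
  expect_equal(survival_at(ga, 6), s6, tolerance = 1e-6)
})

test_that("invalid constructions and domains are rejected", {
  expect_error(surv_spec("loglogistic", shape = -1, scale = 13.55),
               "strictly")
  expect_error(surv_spec("gompertz", shape = -0.1, rate = 0.2), "strictly")
  expect_error(surv_spec("weibull", shape = 1), "requires parameters")
  ll <- surv_spec("loglogistic", shape = 1.81, scale = 13.55)
  expect_error(survival_at(ll, -1), "negative time")
  expect_error(density_at(ll, -0.5), "negative time")
})

test_that("every family gives a proper monotone survival with non-negative hazard", {
  set.seed(11)
  fams <- list(
    function() surv_spec("exponential", rate = runif(1, 0.01, 1)),
    function() surv_spec("weibull", shape = runif(1, 0.3, 4),
                         scale = runif(1, 1, 30)),
    function() surv_spec("gamma", shape = runif(1, 0.3, 5),
                         rate = runif(1, 0.05, 1)),
    function() surv_spec("lognormal", meanlog = runif(1, -1, 3),
                         sdlog = runif(1, 0.2, 1.5)),
    function() surv_spec("loglogistic", shape = runif(1, 0.5, 4),
                         scale = runif(1, 1, 30)),
    function() surv_spec("gompertz", shape = runif(1, 0.01, 0.5),
                         rate = runif(1, 0.01, 0.3)))
  tg <- seq(0, 120, by = 0.5)
  for (mk in fams) {
    for (rep in 1:5) {
      sp <- mk()
      s <- survival_at(sp, tg)
      expect_identical(s[1], 1)
      expect_true(all(s >= 0 & s <= 1))
      expect_true(all(diff(s) <= 1e-12))
      expect_lt(survival_at(sp, 1e5), 0.01)  # S(t) -> 0
      h <- hazard_at(sp, tg[s > 1e-12])
      expect_true(all(h >= 0, na.rm = TRUE))
    }
  }
})

test_that("information criteria follow their definitions", {
  f <- btcea:::new_surv_fit(surv_spec("weibull", shape = 1.2, scale = 10),
                            loglik = -102, n = 37, converged = TRUE,
                            diagnostics = "")
  expect_equal(f$aic, 2 * 2 - 2 * (-102))
  expect_equal(f$bic, 2 * log(37) - 2 * (-102))
})

test_that("exponential MLE equals its closed form", {
  f <- fit_mle(c(1, 2, 3), c(1, 1, 1), "exponential")
  expect_identical(unname(f$spec$params["rate"]), 0.5)  # 3 events / 6 time
  expect_true(f$converged)

  set.seed(21)
  t <- rexp(1000, 0.1)
  f2 <- fit_mle(t, rep(1, 1000), "exponential")
  expect_equal(unname(f2$spec$params["rate"]), 1000 / sum(t), tolerance = 1e-12)
  expect_equal(unname(f2$spec$params["rate"]), 0.1, tolerance = 0.1)
})

test_that("fit log-likelihood matches the independent closed-form computation", {
  set.seed(31)
  t <- rweibull(300, 1.4, 12)
  cens <- runif(300, 0, 40)
  times <- pmin(t, cens); events <- as.integer(t <= cens)
  for (fam in c("exponential", "weibull", "loglogistic", "gamma")) {
    f <- fit_mle(times, events, fam)
    expect_equal(f$loglik, loglik_surv(f$spec, times, events),
                 tolerance = 1e-6)
    # the MLE cannot be beaten by the generating parameters on the same data
    if (fam == "weibull") {
      truth <- surv_spec("weibull", shape = 1.4, scale = 12)
      expect_gte(f$loglik, loglik_surv(truth, times, events) - 1e-6)
    }
  }
})

test_that("all-censored input raises a no-events error", {
  expect_error(fit_mle(c(1, 2, 3), c(0, 0, 0), "exponential"), "no events")
})

test_that("log-logistic parameters are recovered from censored samples", {
  set.seed(41)
  truth <- surv_spec("loglogistic", shape = 1.81, scale = 13.55)
  t <- rsurv(5000, truth)
  cens <- runif(5000, 0, quantile(t, 0.9))
  keep_event <- runif(5000) > 0.3
  times <- ifelse(keep_event, t, pmin(t, cens))
  events <- as.integer(keep_event | t <= cens)
  f <- fit_mle(times, events, "loglogistic")
  expect_true(f$converged)
  expect_equal(unname(f$spec$params["shape"]), 1.81, tolerance = 0.1)
  expect_equal(unname(f$spec$params["scale"]), 13.55, tolerance = 0.1)
})

test_that("select_best applies AIC then the stated tie-breaks", {
  mk <- function(aic, bic, k = 2) {
    f <- btcea:::new_surv_fit(surv_spec("weibull", shape = 1, scale = 1),
                              loglik = 0, n = 10, converged = TRUE,
                              diagnostics = "")
    f$aic <- aic; f$bic <- bic; f$k <- k
    f
  }
  expect_equal(select_best(list(mk(204, 1), mk(210, 0)))$aic, 204)
  expect_equal(select_best(list(mk(200, 300), mk(200, 290)))$bic, 290)
  expect_equal(select_best(list(mk(200, 290, k = 3), mk(200, 290, k = 1)))$k, 1)
  expect_error(select_best(list()), "empty")
})

test_that("model selection recovers the generating log-logistic family", {
  set.seed(51)
  truth <- surv_spec("loglogistic", shape = 2.19, scale = 7.07)
  hits <- 0; reps <- 50
  for (r in seq_len(reps)) {
    t <- rsurv(2000, truth)
    fits <- fit_all_families(t, rep(1, 2000))
    best <- suppressWarnings(select_best(fits))
    if (best$family == "loglogistic") hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("fit summaries export as JSON records", {
  set.seed(61)
  t <- rsurv(200, surv_spec("weibull", shape = 1.3, scale = 10))
  fits <- fit_all_families(t, rep(1, 200), families = c("exponential", "weibull"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fits, path)
  rec <- jsonlite::read_json(path)
  expect_length(rec, 2)
  expect_equal(rec[[2]]$family, "weibull")
  expect_equal(rec[[2]]$aic, fits$weibull$aic, tolerance = 1e-8)
})
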