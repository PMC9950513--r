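#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the incremental cost-effectiveness ratio with each uncertain
#' parameter set to its lower and upper bound in turn, all other parameters
#' held at base, and ranks parameters by the induced ICER span (tornado
#' order). Survival model parameters are fixed in the model and are not
#' varied.
#'
#' @param scenario A `btc_scenario`.
#' @param parameters Optional subset of parameter names (see
#'   [param_table()]); default all.
#' @param method Transition scheme.
#' @return A `btc_owsa` data frame: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span`, sorted by decreasing span. The
#'   base-case ICER is attached as `attr(, "icer_base")`.
#' @export
owsa <- function(scenario, parameters = NULL, method = "pd-routed") {
  stopifnot(inherits(scenario, "btc_scenario"))
  pt <- param_table(scenario)
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, pt$name)
    if (length(missing))
      stop("unknown parameters: ", paste(missing, collapse = ", "), call. = FALSE)
    pt <- pt[pt$name %in% parameters, ]
  }
  w_c <- arm_weights(scenario, "chemo", method = method)
  w_d <- arm_weights(scenario, "durva", method = method)
  icer_with <- function(params) {
    cea <- compute_cea(
      arm_outcomes(scenario, "chemo", w = w_c, params = params),
      arm_outcomes(scenario, "durva", w = w_d, params = params),
      scenario$wtp)
    cea$icer_qaly
  }
  base <- icer_with(NULL)
  res <- lapply(seq_len(nrow(pt)), function(i) {
    lo <- setNames(pt$min[i], pt$name[i])
    hi <- setNames(pt$max[i], pt$name[i])
    il <- icer_with(as.list(lo)); ih <- icer_with(as.list(hi))
    data.frame(parameter = pt$name[i], low = pt$min[i], high = pt$max[i],
               icer_low = il, icer_high = ih, span = abs(ih - il))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- base
  class(out) <- c("btc_owsa", "data.frame")
  out
}

#' Durvalumab price reduction reaching a target ICER
#'
#' Bisection on a multiplicative durvalumab price factor until the
#' recomputed ICER matches `target_icer` to within $1/QALY. The factor
#' applies to the first-line price and to durvalumab's share of subsequent
#' immunotherapy cost in both arms.
#'
#' @param scenario A `btc_scenario`.
#' @param target_icer Target ICER ($/QALY); must lie below the base-case
#'   ICER and above the ICER at a free drug, otherwise an error reports the
#'   reachable floor.
#' @param method Transition scheme.
#' @return List with `reduction` (1 - price multiplier), `multiplier`,
#'   `icer` (achieved) and `icer_base`.
#' @export
price_threshold <- function(scenario, target_icer, method = "pd-routed") {
  stopifnot(inherits(scenario, "btc_scenario"))
  w_c <- arm_weights(scenario, "chemo", method = method)
  w_d <- arm_weights(scenario, "durva", method = method)
  icer_at <- function(m) {
    compute_cea(
      arm_outcomes(scenario, "chemo", w = w_c, durva_price_mult = m),
      arm_outcomes(scenario, "durva", w = w_d, durva_price_mult = m),
      scenario$wtp)$icer_qaly
  }
  icer1 <- icer_at(1)
  if (target_icer >= icer1)
    return(list(reduction = 0, multiplier = 1, icer = icer1,
                icer_base = icer1))
  icer0 <- icer_at(0)
  if (target_icer < icer0)
    stop(sprintf(
      "target ICER %.2f unreachable: ICER floor at zero price is %.2f",
      target_icer, icer0), call. = FALSE)
  lo <- 0; hi <- 1
  repeat {
    m <- (lo + hi) / 2
    ic <- icer_at(m)
    if (abs(ic - target_icer) < 1 || hi - lo < 1e-12) break
    if (ic > target_icer) hi <- m else lo <- m
  }
  list(reduction = 1 - m, multiplier = m, icer = ic, icer_base = icer1)
}

#' Distribution parameters for probabilistic sensitivity draws
#'
#' Moment-matches a parameter's sampling distribution to its base value and
#' its (min, max) range read as a central 95% interval: the standard
#' deviation is (max - min)/3.92, then gamma shape/rate or beta
#' alpha/beta follow from mean and SD. A beta whose implied variance is
#' infeasible for its mean (mean too close to 0 or 1 for the range) falls
#' back to the largest feasible variance with a warning. A zero-width range
#' gives a point mass.
#'
#' @param base,min,max Base value and range.
#' @param dist `"gamma"` or `"beta"`.
#' @return List with `dist` and its shape parameters (or
#'   `dist = "point"`).
#' @export
psa_dist <- function(base, min, max, dist = c("gamma", "beta")) {
  dist <- match.arg(dist)
  sd <- (max - min) / 3.92
  if (sd == 0 || base == 0) return(list(dist = "point", value = base))
  if (dist == "gamma") {
    shape <- base^2 / sd^2
    return(list(dist = "gamma", shape = shape, rate = shape / base))
  }
  v_max <- base * (1 - base)
  if (sd^2 >= v_max) {
    warning(sprintf(
      "infeasible beta variance for mean %.4g; clamping to feasible maximum",
      base), call. = FALSE)
    sd <- sqrt(v_max) * 0.95
  }
  nu <- v_max / sd^2 - 1
  list(dist = "beta", alpha = base * nu, beta = (1 - base) * nu)
}

psa_draw <- function(n, d) {
  switch(d$dist,
         point = rep(d$value, n),
         gamma = rgamma(n, shape = d$shape, rate = d$rate),
         beta  = rbeta(n, d$alpha, d$beta))
}

#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter from its assigned distribution (gamma
#' for costs, beta for probabilities, utilities and disutility magnitudes;
#' see [psa_dist()]), re-evaluates the incremental comparison per draw
#' (survival parameters fixed), and summarises cost-effectiveness
#' acceptability over a willingness-to-pay grid. Seeded runs are
#' bit-reproducible.
#'
#' @param scenario A `btc_scenario`.
#' @param n Number of Monte-Carlo samples (>= 100).
#' @param seed RNG seed.
#' @param wtp_grid WTP grid for the acceptability curve (default 0 to
#'   500,000 by 10,000, always including the scenario WTP).
#' @param method Transition scheme.
#' @return A `btc_psa` list: `samples` (per-draw parameters, incremental
#'   cost/QALY and incremental NMB at the scenario WTP), `ceac` (columns
#'   `wtp`, `prob_ce`), and `prob_ce` at the scenario WTP.
#' @export
psa <- function(scenario, n = 1000, seed = 42, wtp_grid = NULL,
                method = "pd-routed") {
  stopifnot(inherits(scenario, "btc_scenario"), n >= 100)
  if (is.null(wtp_grid)) wtp_grid <- seq(0, 500000, by = 10000)
  wtp_grid <- sort(unique(c(wtp_grid, scenario$wtp)))
  pt <- param_table(scenario)
  set.seed(as.integer(seed))
  draws <- vapply(seq_len(nrow(pt)), function(i) {
    psa_draw(n, psa_dist(pt$base[i], pt$min[i], pt$max[i], pt$dist[i]))
  }, numeric(n))
  colnames(draws) <- pt$name

  w_c <- arm_weights(scenario, "chemo", method = method)
  w_d <- arm_weights(scenario, "durva", method = method)
  d_cost <- d_qaly <- numeric(n)
  for (s in seq_len(n)) {
    pars <- as.list(draws[s, ])
    ch <- arm_outcomes(scenario, "chemo", w = w_c, params = pars)
    du <- arm_outcomes(scenario, "durva", w = w_d, params = pars)
    d_cost[s] <- du$cost - ch$cost
    d_qaly[s] <- du$qaly - ch$qaly
  }
  nmb <- scenario$wtp * d_qaly - d_cost
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_ce = vapply(wtp_grid, function(l) mean(l * d_qaly - d_cost > 0),
                     numeric(1)))
  structure(list(
    samples = cbind(as.data.frame(draws),
                    data.frame(delta_cost = d_cost, delta_qaly = d_qaly,
                               inmb = nmb)),
    ceac = ceac,
    prob_ce = mean(nmb > 0),
    wtp = scenario$wtp, n = n, seed = seed), class = "btc_psa")
}

#' @export
print.btc_psa <- function(x, ...) {
  cat("<btc_psa> ", x$n, " samples (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  mean incremental cost %s, mean incremental QALY %.4f\n",
              formatC(mean(x$samples$delta_cost), format = "f", digits = 2,
                      big.mark = ","),
              mean(x$samples$delta_qaly)))
  cat(sprintf("  P(cost-effective) at WTP %s: %.1f%%\n",
              formatC(x$wtp, format = "d", big.mark = ","),
              100 * x$prob_ce))
  invisible(x)
}
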