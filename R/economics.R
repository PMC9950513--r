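#' Discounted accrual weights for one strategy arm
#'
#' Runs the arm's transition schedule and trace once and condenses it into
#' the discounted person-time weights that every cost and QALY total is
#' linear in. Splitting the model this way lets the deterministic and
#' probabilistic sensitivity analyses re-price thousands of parameter draws
#' without re-running the trace (survival parameters are fixed in the
#' sensitivity analyses).
#'
#' Cost-side weights (discounted at the cost rate, units: person-cycles,
#' half-cycle corrected):
#' `w_durva` (PFS occupancy while durvalumab continues), `w_gp` (PFS
#' occupancy while gemcitabine/cisplatin continues), `w_pfs`, `w_pd` (state
#' occupancy over the full horizon) and `w_sub` (subsequent-therapy
#' exposure: each PD entrant accrues up to `subsequent_max_cycles` cycles,
#' counted from progression, without attrition adjustment but never
#' exceeding current PD occupancy).
#' Effect-side weights (discounted at the effect rate, units: person-years):
#' `e_pfs`, `e_pd`, `e_alive`.
#'
#' @param scenario A `btc_scenario`.
#' @param arm `"durva"` or `"chemo"`.
#' @param method Transition scheme passed to [transition_schedule()].
#' @return List of weights plus the undiscounted/discounted life-years and
#'   the cohort trace.
#' @export
arm_weights <- function(scenario, arm = c("durva", "chemo"),
                        method = "pd-routed") {
  stopifnot(inherits(scenario, "btc_scenario"))
  arm <- match.arg(arm)
  st <- scenario$settings
  os <- scenario$survival[[paste0(arm, "_os")]]
  pfs <- scenario$survival[[paste0(arm, "_pfs")]]
  sched <- transition_schedule(os, pfs, st, method = method)
  trace <- run_trace(sched, utilities = list(pfs = 1, pd = 1), settings = st)

  n <- st$n_cycles
  occ <- as.matrix(trace[, c("pfs", "pd", "death")])
  w_start <- if (st$half_cycle) 0.5 else 0
  pf_m <- w_start * occ[-(n + 1), 1] + (1 - w_start) * occ[-1, 1]
  pd_m <- w_start * occ[-(n + 1), 2] + (1 - w_start) * occ[-1, 2]
  ty <- trace$t_years
  mid <- (ty[-1] + ty[-(n + 1)]) / 2
  dc <- 1 / (1 + st$discount_cost)^mid
  de <- 1 / (1 + st$discount_effect)^mid
  k <- seq_len(n)

  # new PD entrants during cycle k
  entrants <- occ[-(n + 1), 1] * sched$p_pfs_pd
  n_sub <- scenario$treatment_rules$subsequent_max_cycles
  sub_occ <- numeric(n)
  if (n_sub > 0) {
    for (j in k) {
      idx <- j:min(n, j + n_sub - 1)
      sub_occ[idx] <- sub_occ[idx] + entrants[j]
    }
    sub_occ <- pmin(sub_occ, pd_m)
  }

  n_durva <- scenario$treatment_rules$durvalumab_max_cycles
  n_gp <- scenario$treatment_rules$gp_max_cycles
  list(arm = arm,
       w_durva = if (arm == "durva") sum(pf_m[k <= n_durva] * dc[k <= n_durva]) else 0,
       w_gp = sum(pf_m[k <= n_gp] * dc[k <= n_gp]),
       w_pfs = sum(pf_m * dc), w_pd = sum(pd_m * dc),
       w_sub = sum(sub_occ * dc),
       e_pfs = st$cycle_years * sum(pf_m * de),
       e_pd = st$cycle_years * sum(pd_m * de),
       e_alive = st$cycle_years * sum((pf_m + pd_m) * de),
       ly = st$cycle_years * sum(pf_m + pd_m),
       dly = st$cycle_years * sum((pf_m + pd_m) * de),
       trace = trace, sched = sched)
}

submix_cost <- function(scenario, arm, params, durva_price_mult = 1) {
  regs <- scenario$subsequent_therapy$regimens
  total <- 0
  for (reg in names(regs)) {
    p <- params[[paste0("subsequent.", arm, ".", reg)]]
    price <- 0
    for (drug in regs[[reg]]) {
      c_d <- params[[paste0("drug.", drug)]]
      if (drug == "durvalumab") c_d <- c_d * durva_price_mult
      price <- price + c_d
    }
    total <- total + p * price
  }
  total
}

ae_vectors <- function(scenario, arm, params) {
  aes <- names(scenario$adverse_events)
  list(risk = vapply(aes, function(a) params[[paste0("ae.", a, ".risk_", arm)]],
                     numeric(1)),
       cost = vapply(aes, function(a) params[[paste0("ae.", a, ".cost")]],
                     numeric(1)),
       disutility = vapply(aes, function(a) params[[paste0("ae.", a, ".disutility")]],
                           numeric(1)))
}

#' One-time adverse-event burden of an arm
#'
#' Expected one-time cost (sum of risk times unit cost over the four
#' modelled grade >= 3 adverse events) and the expected QALY decrement were
#' the disutilities applied for a single cycle
#' (sum of risk times disutility magnitude times the cycle length in
#' years). Both refer to model entry (cycle 0).
#'
#' @param arm `"durva"` or `"chemo"`.
#' @param scenario A `btc_scenario`.
#' @param params Optional parameter overrides (named as in [param_table()]).
#' @return List with `cost`, `qaly_loss` and the per-cycle utility
#'   `decrement` (sum of risk times disutility).
#' @export
ae_burden <- function(arm, scenario, params = NULL) {
  arm <- match.arg(arm, c("durva", "chemo"))
  p <- as.list(base_params(scenario))
  if (!is.null(params)) p[names(params)] <- params
  v <- ae_vectors(scenario, arm, p)
  dec <- sum(v$risk * v$disutility)
  list(cost = sum(v$risk * v$cost),
       qaly_loss = dec * scenario$settings$cycle_years,
       decrement = dec)
}

#' Per-cycle cost of occupying a state
#'
#' Recurring cost charged per person occupying `state` during (0-based)
#' cycle `cycle`: in PFS, on-treatment drug costs (durvalumab up to its cap
#' in the durvalumab arm; gemcitabine/cisplatin up to the chemotherapy cap)
#' plus PFS follow-up items; in PD, PD follow-up items plus the
#' mixture-weighted subsequent-therapy drug cost (the per-entrant duration
#' cap is enforced at the cohort level, see [arm_weights()]); death costs
#' nothing. First-hospitalization laboratory and imaging charges and the
#' one-time adverse-event cost are added at cycle 0.
#'
#' @param state `"pfs"`, `"pd"` or `"death"`.
#' @param arm `"durva"` or `"chemo"`.
#' @param cycle 0-based cycle index.
#' @param scenario A `btc_scenario`.
#' @param components Which pieces to include: any of `"drug"`,
#'   `"followup"`, `"subsequent"`, `"onetime"`.
#' @return Cost in scenario currency.
#' @export
cycle_cost <- function(state, arm, cycle, scenario,
                       components = c("drug", "followup", "subsequent",
                                      "onetime")) {
  state <- match.arg(state, c("pfs", "pd", "death"))
  arm <- match.arg(arm, c("durva", "chemo"))
  components <- match.arg(components, several.ok = TRUE)
  if (state == "death") return(0)
  p <- as.list(base_params(scenario))
  tr <- scenario$treatment_rules
  bc <- p$followup.bed + p$followup.care
  total <- 0
  if (state == "pfs") {
    if ("drug" %in% components) {
      if (cycle < tr$gp_max_cycles)
        total <- total + p$drug.gemcitabine + p$drug.cisplatin
      if (arm == "durva" && cycle < tr$durvalumab_max_cycles)
        total <- total + p$drug.durvalumab
    }
    if ("followup" %in% components) {
      total <- total + p$followup.lab_pfs + p$followup.imaging_pfs +
        if (tr$bed_care_states %in% c("both", "pfs")) bc else 0
    }
  } else {
    if ("followup" %in% components) {
      total <- total + p$followup.lab_pd + p$followup.imaging_pd +
        if (tr$bed_care_states %in% c("both", "pd")) bc else 0
    }
    if ("subsequent" %in% components) {
      total <- total + submix_cost(scenario, arm, p)
    }
  }
  if ("onetime" %in% components && cycle == 0 && state == "pfs") {
    total <- total + p$followup.lab_first + p$followup.imaging_first +
      ae_burden(arm, scenario)$cost
  }
  total
}

#' Total discounted cost and effects of one arm
#'
#' Combines the arm's [arm_weights()] with a parameter vector into total
#' discounted cost, life-years and QALYs. The QALY total subtracts the
#' adverse-event burden either as a chronic per-cycle utility decrement
#' over all living person-time (`ae_disutility_mode = "chronic"`, the
#' default) or as the one-time single-cycle loss of [ae_burden()]
#' (`"once"`).
#'
#' @param w An [arm_weights()] result (or `NULL` to compute it here).
#' @param scenario A `btc_scenario`.
#' @param arm `"durva"` or `"chemo"`.
#' @param params Named parameter overrides (defaults: [base_params()]).
#' @param durva_price_mult Multiplier on the durvalumab unit price (price
#'   threshold analysis); applies to first-line and subsequent use.
#' @param method Transition scheme (used only when `w` is `NULL`).
#' @return List with `cost`, `ly`, `qaly` (discounted), `ly_undiscounted`,
#'   and a cost `breakdown`.
#' @export
arm_outcomes <- function(scenario, arm = c("durva", "chemo"), w = NULL,
                         params = NULL, durva_price_mult = 1,
                         method = "pd-routed") {
  arm <- match.arg(arm)
  if (is.null(w)) w <- arm_weights(scenario, arm, method = method)
  p <- as.list(base_params(scenario))
  if (!is.null(params)) p[names(params)] <- params
  tr <- scenario$treatment_rules

  bc <- p$followup.bed + p$followup.care
  fu_pfs <- p$followup.lab_pfs + p$followup.imaging_pfs +
    if (tr$bed_care_states %in% c("both", "pfs")) bc else 0
  fu_pd <- p$followup.lab_pd + p$followup.imaging_pd +
    if (tr$bed_care_states %in% c("both", "pd")) bc else 0
  ae <- ae_vectors(scenario, arm, p)

  breakdown <- c(
    first_line_drugs = (p$drug.gemcitabine + p$drug.cisplatin) * w$w_gp +
      p$drug.durvalumab * durva_price_mult * w$w_durva,
    subsequent_drugs = submix_cost(scenario, arm, p, durva_price_mult) * w$w_sub,
    followup = fu_pfs * w$w_pfs + fu_pd * w$w_pd,
    first_hospitalization = p$followup.lab_first + p$followup.imaging_first,
    adverse_events = sum(ae$risk * ae$cost))
  cost <- sum(breakdown)

  dec <- sum(ae$risk * ae$disutility)
  qaly <- p$utility.pfs * w$e_pfs + p$utility.pd * w$e_pd
  qaly <- if (tr$ae_disutility_mode == "chronic") {
    qaly - dec * w$e_alive
  } else {
    qaly - dec * scenario$settings$cycle_years
  }
  list(arm = arm, cost = cost, ly = w$dly, qaly = qaly,
       ly_undiscounted = w$ly, breakdown = breakdown)
}

#' Incremental cost-effectiveness statistics
#'
#' Computes the incremental comparison of the durvalumab + chemotherapy
#' strategy against chemotherapy: incremental cost, life-years and QALYs,
#' ICER per QALY and per life-year (from unrounded internals), and net
#' monetary benefit (`wtp * QALY - cost`) per strategy. A zero incremental
#' effect yields an `NA` ICER with a dominance label instead.
#'
#' @param chemo,durva [arm_outcomes()]-style lists with `cost`, `ly`,
#'   `qaly`.
#' @param wtp Willingness-to-pay threshold per QALY.
#' @return A `btc_cea` object.
#' @export
compute_cea <- function(chemo, durva, wtp) {
  d_cost <- durva$cost - chemo$cost
  d_ly <- durva$ly - chemo$ly
  d_qaly <- durva$qaly - chemo$qaly
  icer_qaly <- if (d_qaly == 0) NA_real_ else d_cost / d_qaly
  icer_ly <- if (d_ly == 0) NA_real_ else d_cost / d_ly
  dominance <- if (d_qaly > 0 && d_cost <= 0) "dominant"
  else if (d_qaly <= 0 && d_cost >= 0 && !(d_qaly == 0 && d_cost == 0)) "dominated"
  else if (d_qaly == 0) "equal effect"
  else NA_character_
  structure(list(
    strategies = data.frame(
      strategy = c("chemotherapy", "durvalumab + chemotherapy"),
      cost = c(chemo$cost, durva$cost),
      ly = c(chemo$ly, durva$ly),
      qaly = c(chemo$qaly, durva$qaly),
      nmb = wtp * c(chemo$qaly, durva$qaly) - c(chemo$cost, durva$cost)),
    delta_cost = d_cost, delta_ly = d_ly, delta_qaly = d_qaly,
    icer_qaly = icer_qaly, icer_ly = icer_ly,
    incremental_nmb = wtp * d_qaly - d_cost,
    dominance = dominance, wtp = wtp), class = "btc_cea")
}

#' Run the base-case analysis of a scenario
#'
#' Evaluates both strategy arms at the scenario's base parameter values and
#' returns the incremental comparison.
#'
#' @param scenario A `btc_scenario`.
#' @param method Transition scheme, see [transition_schedule()].
#' @return A `btc_cea` object; the per-arm evaluations are attached as
#'   `attr(, "arms")`.
#' @export
run_base_case <- function(scenario, method = "pd-routed") {
  stopifnot(inherits(scenario, "btc_scenario"))
  chemo <- arm_outcomes(scenario, "chemo", method = method)
  durva <- arm_outcomes(scenario, "durva", method = method)
  out <- compute_cea(chemo, durva, scenario$wtp)
  attr(out, "arms") <- list(chemo = chemo, durva = durva)
  attr(out, "label") <- scenario$label
  out
}

#' @export
print.btc_cea <- function(x, ...) {
  lbl <- attr(x, "label")
  if (!is.null(lbl)) cat(lbl, "\n")
  s <- x$strategies
  cat(sprintf("%-28s %12s %6s %6s %14s\n", "Strategy", "Cost", "LY", "QALY",
              "NMB"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%-28s %12s %6.2f %6.2f %14s\n", s$strategy[i],
                formatC(s$cost[i], format = "f", digits = 2, big.mark = ","),
                s$ly[i], s$qaly[i],
                formatC(s$nmb[i], format = "f", digits = 2, big.mark = ",")))
  }
  cat(sprintf("Incremental: cost %s, %0.3f LY, %0.3f QALY\n",
              formatC(x$delta_cost, format = "f", digits = 2, big.mark = ","),
              x$delta_ly, x$delta_qaly))
  if (!is.na(x$icer_qaly)) {
    cat(sprintf("ICER: %s/QALY, %s/LY (WTP %s)\n",
                formatC(x$icer_qaly, format = "f", digits = 2, big.mark = ","),
                formatC(x$icer_ly, format = "f", digits = 2, big.mark = ","),
                formatC(x$wtp, format = "d", big.mark = ",")))
  } else cat("ICER undefined: ", x$dominance, "\n")
  invisible(x)
}

#' Export a base-case result as a results table CSV
#'
#' Writes the per-strategy totals and incremental columns in the layout of
#' a standard base-case results table.
#'
#' @param cea A `btc_cea`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(cea, path) {
  s <- cea$strategies
  out <- data.frame(
    strategy = s$strategy,
    cost = round(s$cost, 2),
    incr_cost = c(NA, round(cea$delta_cost, 2)),
    ly = round(s$ly, 2),
    incr_ly = c(NA, round(cea$delta_ly, 2)),
    icer_per_ly = c(NA, round(cea$icer_ly, 2)),
    qaly = round(s$qaly, 2),
    incr_qaly = c(NA, round(cea$delta_qaly, 2)),
    icer_per_qaly = c(NA, round(cea$icer_qaly, 2)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
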