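#' Specification of a synthetic two-endpoint trial arm set
#'
#' Describes a TOPAZ-1-like two-arm trial for the synthetic data generator:
#' per-arm sample sizes, true OS and PFS parametric models, a uniform
#' accrual window and an administrative data cutoff. Defaults mirror the
#' modelled trial: 198 experimental and 226 control subjects, the base-case
#' survival models of [btc_survival_models()], 12 months of accrual and a
#' 24-month cutoff (a follow-up figure of about two years).
#'
#' @param n Named integer vector of arm sizes.
#' @param os,pfs Named lists of [surv_spec()] per arm (names matching `n`).
#' @param accrual_months Length of the uniform accrual window (months).
#' @param cutoff_months Data cutoff since first accrual (months); a
#'   subject accrued at `a` is administratively censored at
#'   `cutoff_months - a`.
#' @param grid_size Number of coordinates used by [digitize_km()].
#' @return A `trial_sim_spec` list.
#' @export
trial_sim_spec <- function(n = c(durva = 198L, chemo = 226L),
                           os = NULL, pfs = NULL,
                           accrual_months = 12, cutoff_months = 24,
                           grid_size = 60) {
  mods <- btc_survival_models()
  if (is.null(os)) os <- list(durva = mods$durva_os, chemo = mods$chemo_os)
  if (is.null(pfs)) pfs <- list(durva = mods$durva_pfs, chemo = mods$chemo_pfs)
  stopifnot(all(n > 0), cutoff_months > 0, accrual_months >= 0,
            setequal(names(n), names(os)), setequal(names(n), names(pfs)))
  structure(list(n = n, os = os, pfs = pfs,
                 accrual_months = accrual_months,
                 cutoff_months = cutoff_months, grid_size = grid_size),
            class = "trial_sim_spec")
}

#' Simulate trial-like individual patient data
#'
#' Draws, per subject, a death time from the arm's OS model and a
#' progression time from the arm's PFS model (independent draws: only the
#' marginal curves are modelled, no dependence structure is imposed), sets
#' the PFS endpoint time to the minimum of the two so progression never
#' follows death, and censors both endpoints administratively at
#' `cutoff - accrual offset` with accrual uniform over the accrual window.
#' Runs are bit-reproducible for a given `seed`.
#'
#' @param spec A [trial_sim_spec()].
#' @param seed Integer RNG seed.
#' @return Named list (one element per arm) of lists with data frames `os`
#'   and `pfs`, each with columns `time`, `event`.
#' @export
simulate_ipd <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  set.seed(as.integer(seed))
  out <- lapply(names(spec$n), function(arm) {
    n <- spec$n[[arm]]
    t_death <- rsurv(n, spec$os[[arm]])
    t_prog <- rsurv(n, spec$pfs[[arm]])
    t_pfs <- pmin(t_prog, t_death)
    accrual <- runif(n, 0, spec$accrual_months)
    fup <- pmax(spec$cutoff_months - accrual, 0)
    mk <- function(tt) {
      ev <- as.integer(tt <= fup)
      data.frame(time = pmin(tt, fup), event = ev)
    }
    os <- mk(t_death); pfs <- mk(t_pfs)
    attr(os, "arm") <- arm; attr(pfs, "arm") <- arm
    list(os = os, pfs = pfs)
  })
  names(out) <- names(spec$n)
  out
}

#' Emulate digitization of a KM figure
#'
#' Computes the Kaplan-Meier estimate of an IPD set, samples it on an even
#' time grid, optionally perturbs the probabilities with Gaussian jitter
#' (emulating manual point-picking error), and tabulates numbers at risk at
#' six evenly spaced boundaries starting at 0.
#'
#' @param ipd Data frame with `time`, `event`.
#' @param grid_size Number of grid points (default 60).
#' @param t_max Upper end of the grid; defaults to the largest observed time.
#' @param jitter_sd Standard deviation of the jitter (default 0.005; 0 gives
#'   the exact KM values).
#' @param seed RNG seed for the jitter.
#' @return List with `curve` (a [digitized_curve()]) and `risk`
#'   (a [risk_table()], first entry equal to the number of subjects).
#' @export
digitize_km <- function(ipd, grid_size = 60, t_max = NULL,
                        jitter_sd = 0.005, seed = 1L) {
  stopifnot(nrow(ipd) > 0)
  km <- km_estimate(ipd)
  if (is.null(t_max)) t_max <- max(ipd$time)
  grid <- seq(0, t_max, length.out = grid_size)
  s <- km_at(km, grid)
  if (jitter_sd > 0) {
    set.seed(as.integer(seed))
    s <- s + rnorm(length(s), 0, jitter_sd)
    s[1] <- 1
    s <- pmin(pmax(s, 0), 1)
    s <- cummin(s)  # repair jitter before constructing the curve
  }
  curve <- digitized_curve(grid, s, arm = attr(ipd, "arm"))
  rt_times <- seq(0, t_max, length.out = 6)
  n_risk <- vapply(rt_times, function(b) sum(ipd$time >= b - 1e-9), numeric(1))
  list(curve = curve, risk = risk_table(rt_times, n_risk))
}

#' @importFrom stats rnorm
NULL
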