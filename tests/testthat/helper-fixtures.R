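# Shared fixtures: everything is built in code at test time.

us_scenario <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- default_scenario("us")
    s
  }
})

china_scenario <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- default_scenario("china")
    s
  }
})

# Set min = max = base for every uncertain parameter (degenerate PSA).
collapse_ranges <- function(scenario) {
  squash <- function(x) {
    if (is.list(x) && !is.null(x$base)) { x$min <- x$max <- x$base; return(x) }
    if (is.list(x)) return(lapply(x, squash))
    x
  }
  for (block in c("utilities", "drug_costs", "followup_costs",
                  "adverse_events", "subsequent_therapy")) {
    scenario[[block]] <- squash(scenario[[block]])
  }
  attr(scenario, "param_table") <- btcea:::build_param_table(scenario)
  scenario
}

# Edit one {base,min,max} record in place and refresh the cached registry.
set_param_range <- function(scenario, path, base = NULL, min = NULL,
                            max = NULL) {
  node <- scenario[[path]]  # recursive indexing with a character vector
  if (!is.null(base)) node$base <- base
  if (!is.null(min)) node$min <- min
  if (!is.null(max)) node$max <- max
  scenario[[path]] <- node
  attr(scenario, "param_table") <- btcea:::build_param_table(scenario)
  scenario
}

# A short, hand-checkable settings object.
short_settings <- function(n_cycles = 1, discount = 0) {
  model_settings(cycle_days = 21,
                 horizon_years = n_cycles * 21 / 365.25 + 1e-9,
                 discount_cost = discount, discount_effect = discount)
}

# Build a transition_schedule data frame by hand (for identity cases).
manual_schedule <- function(p_pfs_pd, p_pfs_death, p_pd_death) {
  n <- length(p_pfs_pd)
  sched <- data.frame(cycle = 0:(n - 1),
                      t_months = (0:(n - 1)) * 21 / 30.4375,
                      p_pfs_pd = p_pfs_pd, p_pfs_death = p_pfs_death,
                      p_pd_death = p_pd_death)
  attr(sched, "method") <- "manual"
  attr(sched, "clipped") <- FALSE
  class(sched) <- c("transition_schedule", "data.frame")
  sched
}
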