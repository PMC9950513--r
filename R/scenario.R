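#' Load a scenario configuration
#'
#' Reads a YAML scenario file (see the bundled `us.yaml` / `china.yaml`
#' under `inst/extdata` for the schema), validates every block, and returns
#' a `btc_scenario` with parsed [surv_spec()] survival models and
#' [model_settings()] attached.
#'
#' Every uncertain parameter is a `{base, min, max, dist}` record with
#' `min <= base <= max` and `dist` either `"gamma"` (costs) or `"beta"`
#' (probabilities, utilities, disutility magnitudes). Disutilities are
#' stored as positive magnitudes. The `treatment_rules` block holds the cost
#' mechanics the published model leaves open: the on-treatment caps for
#' durvalumab and for gemcitabine/cisplatin, the per-patient
#' subsequent-therapy duration cap, which living states accrue bed and care
#' costs, and whether the expected adverse-event disutility burden is
#' applied as a chronic per-cycle decrement (`"chronic"`) or as a one-time
#' QALY loss of one cycle's duration (`"once"`).
#'
#' @param path Path to a YAML scenario file.
#' @return A `btc_scenario` list.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_scenario(cfg)
  cfg$survival <- lapply(cfg$survival, function(s) {
    do.call(surv_spec, c(list(s$family), s[setdiff(names(s), "family")]))
  })
  cfg$settings <- do.call(model_settings, cfg$settings)
  out <- structure(cfg, class = "btc_scenario")
  # cache the flattened parameter registry; rebuilding it per PSA draw
  # dominates runtime otherwise
  attr(out, "param_table") <- build_param_table(out)
  out
}

#' Bundled base-case scenarios
#'
#' The two shipped payer-perspective configurations encoding the published
#' model inputs: drug and follow-up costs, utilities, adverse-event risks,
#' disutilities and one-time costs, subsequent-therapy mixtures, discounting
#' and the willingness-to-pay threshold ($150,000/QALY for the US; three
#' times 2021 China GDP per capita, $38,334/QALY, for China). The two files
#' differ only in label, WTP and the drug-cost block.
#'
#' @param perspective `"us"` or `"china"`.
#' @return A `btc_scenario`.
#' @export
default_scenario <- function(perspective = c("us", "china")) {
  perspective <- match.arg(perspective)
  load_scenario(system.file("extdata", paste0(perspective, ".yaml"),
                            package = "btcea", mustWork = TRUE))
}

#' @export
print.btc_scenario <- function(x, ...) {
  cat("<btc_scenario> ", x$label, "\n", sep = "")
  cat("  WTP: $", format(x$wtp, big.mark = ","), "/QALY;  discounting: ",
      100 * x$settings$discount_cost, "% costs, ",
      100 * x$settings$discount_effect, "% effects\n", sep = "")
  cat("  ", x$settings$n_cycles, " cycles of ", x$settings$cycle_days,
      " days over ", x$settings$horizon_years, " years\n", sep = "")
  invisible(x)
}

check_pmm <- function(x, field, prob = FALSE) {
  for (f in c("base", "min", "max", "dist")) {
    if (is.null(x[[f]])) stop("missing '", f, "' in ", field, call. = FALSE)
  }
  if (!(x$min <= x$base && x$base <= x$max))
    stop("violated min <= base <= max in ", field, call. = FALSE)
  if (x$min < 0) stop("negative value in ", field, call. = FALSE)
  if (prob && x$max > 1)
    stop("probability/utility above 1 in ", field, call. = FALSE)
  if (!x$dist %in% c("gamma", "beta"))
    stop("unknown distribution '", x$dist, "' in ", field, call. = FALSE)
  invisible(TRUE)
}

#' Validate a raw scenario configuration
#'
#' Schema check for a parsed (but not yet constructed) scenario list;
#' errors name the offending field.
#'
#' @param cfg A list as returned by [yaml::read_yaml()] on a scenario file.
#' @return `TRUE`, invisibly.
#' @export
validate_scenario <- function(cfg) {
  for (block in c("label", "wtp", "settings", "survival", "utilities",
                  "drug_costs", "followup_costs", "adverse_events",
                  "subsequent_therapy", "treatment_rules")) {
    if (is.null(cfg[[block]])) stop("missing block '", block, "'", call. = FALSE)
  }
  if (cfg$wtp <= 0) stop("wtp must be positive", call. = FALSE)
  for (e in c("durva_os", "durva_pfs", "chemo_os", "chemo_pfs")) {
    if (is.null(cfg$survival[[e]]))
      stop("missing survival model '", e, "'", call. = FALSE)
  }
  for (u in c("pfs", "pd")) {
    check_pmm(cfg$utilities[[u]], paste0("utilities.", u), prob = TRUE)
  }
  for (d in names(cfg$drug_costs)) {
    check_pmm(cfg$drug_costs[[d]], paste0("drug_costs.", d))
  }
  for (f in names(cfg$followup_costs)) {
    check_pmm(cfg$followup_costs[[f]], paste0("followup_costs.", f))
  }
  for (ae in names(cfg$adverse_events)) {
    rec <- cfg$adverse_events[[ae]]
    check_pmm(rec$cost, paste0("adverse_events.", ae, ".cost"))
    check_pmm(rec$disutility, paste0("adverse_events.", ae, ".disutility"),
              prob = TRUE)
    check_pmm(rec$risk_durva, paste0("adverse_events.", ae, ".risk_durva"),
              prob = TRUE)
    check_pmm(rec$risk_chemo, paste0("adverse_events.", ae, ".risk_chemo"),
              prob = TRUE)
  }
  st <- cfg$subsequent_therapy
  if (is.null(st$regimens)) stop("missing subsequent_therapy.regimens", call. = FALSE)
  for (arm in c("durva", "chemo")) {
    tot <- 0
    for (reg in names(st$regimens)) {
      fld <- paste0("subsequent_therapy.", arm, ".", reg)
      if (is.null(st[[arm]][[reg]])) stop("missing ", fld, call. = FALSE)
      check_pmm(st[[arm]][[reg]], fld, prob = TRUE)
      tot <- tot + st[[arm]][[reg]]$base
      for (drug in st$regimens[[reg]]) {
        if (is.null(cfg$drug_costs[[drug]]))
          stop("subsequent_therapy regimen drug '", drug,
               "' missing from drug_costs", call. = FALSE)
      }
    }
    if (tot > 1) stop("subsequent_therapy.", arm, " proportions sum above 1",
                      call. = FALSE)
  }
  tr <- cfg$treatment_rules
  for (f in c("durvalumab_max_cycles", "gp_max_cycles",
              "subsequent_max_cycles")) {
    if (is.null(tr[[f]]) || tr[[f]] < 0)
      stop("treatment_rules.", f, " missing or negative", call. = FALSE)
  }
  if (!(tr$bed_care_states %in% c("both", "pfs", "pd", "none")))
    stop("treatment_rules.bed_care_states must be both/pfs/pd/none", call. = FALSE)
  if (!(tr$ae_disutility_mode %in% c("chronic", "once")))
    stop("treatment_rules.ae_disutility_mode must be chronic/once", call. = FALSE)
  invisible(TRUE)
}

#' Table of uncertain parameters
#'
#' Flattens every `{base, min, max, dist}` record of a scenario into one
#' registry used by the sensitivity analyses. Parameter names are
#' dot-separated paths, e.g. `drug.durvalumab`, `utility.pfs`,
#' `ae.anemia.risk_durva`, `subsequent.chemo.targeted`.
#'
#' @param scenario A `btc_scenario`.
#' @return Data frame with columns `name`, `base`, `min`, `max`, `dist`.
#' @export
param_table <- function(scenario) {
  stopifnot(inherits(scenario, "btc_scenario"))
  cached <- attr(scenario, "param_table")
  if (!is.null(cached)) return(cached)
  build_param_table(scenario)
}

build_param_table <- function(scenario) {
  rows <- list()
  add <- function(name, rec) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, base = rec$base, min = rec$min, max = rec$max,
      dist = rec$dist, stringsAsFactors = FALSE)
  }
  for (u in names(scenario$utilities))
    add(paste0("utility.", u), scenario$utilities[[u]])
  for (d in names(scenario$drug_costs))
    add(paste0("drug.", d), scenario$drug_costs[[d]])
  for (f in names(scenario$followup_costs))
    add(paste0("followup.", f), scenario$followup_costs[[f]])
  for (ae in names(scenario$adverse_events)) {
    rec <- scenario$adverse_events[[ae]]
    for (f in c("cost", "disutility", "risk_durva", "risk_chemo"))
      add(paste0("ae.", ae, ".", f), rec[[f]])
  }
  for (arm in c("durva", "chemo")) {
    for (reg in names(scenario$subsequent_therapy$regimens))
      add(paste0("subsequent.", arm, ".", reg),
          scenario$subsequent_therapy[[arm]][[reg]])
  }
  do.call(rbind, rows)
}

#' Base values of all uncertain parameters
#'
#' @param scenario A `btc_scenario`.
#' @return Named numeric vector (names as in [param_table()]).
#' @export
base_params <- function(scenario) {
  pt <- param_table(scenario)
  setNames(pt$base, pt$name)
}
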