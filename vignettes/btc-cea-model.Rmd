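---
title: "A three-state Markov model for first-line immunochemotherapy in advanced biliary tract cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov model for first-line immunochemotherapy in advanced biliary tract cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(btcea)
```

## The decision problem

The TOPAZ-1 trial showed that adding the PD-L1 inhibitor durvalumab to
gemcitabine/cisplatin (GP) improves overall survival in previously
untreated advanced biliary tract cancer. `btcea` implements the
health-economic model used to ask whether that benefit is worth its price:
a cohort-level Markov model with three health states — progression-free
survival (PFS), progressed disease (PD) and death — evaluated from the US
payer perspective (willingness to pay \$150,000/QALY) and the Chinese payer
perspective (\$38,334/QALY, three times 2021 GDP per capita). All patients
start in PFS; PD is absorbing with respect to recovery (no return to PFS)
and death is absorbing. The cycle length is 21 days (the dosing interval of
both regimens), the horizon 10 years, giving
`floor(10 * 365.25 / 21) = 173` full cycles; the trailing partial cycle is
discarded.

## Survival extrapolation

Because trial follow-up is about two years, state membership over ten years
is driven by parametric extrapolation. Pseudo individual patient data are
recovered from digitized Kaplan–Meier coordinates and numbers-at-risk by
the Guyot interval-accounting algorithm (`guyot_reconstruct()`), six
candidate families (exponential, Weibull, gamma, log-normal, log-logistic,
Gompertz) are fitted by maximum likelihood (`fit_mle()`, backed by
`flexsurv`) and screened by AIC, with BIC and parsimony as tie-breaks
(`select_best()`).

The base case uses the four selected models returned by
`btc_survival_models()`: log-logistic OS in both arms (shape 1.81 / scale
13.55 months in the durvalumab arm, 2.22 / 11.68 in the GP arm),
log-logistic PFS in the durvalumab arm (2.19 / 7.07) and gamma PFS in the
GP arm (shape 2.76, rate 0.38). The log-logistic is parameterized as
$S(t) = [1 + (t/\mathrm{scale})^{\mathrm{shape}}]^{-1}$, so the scale *is*
the median; months are the time unit. Both conventions are pinned down by
the trial itself: the OS scales of 13.55 and 11.68 months sit next to the
reported median OS of 12.8 and 11.5 months, and no other reading does.
The GP-arm OS row of the source parameter table prints "Scale" twice; the
first value (2.22) is read as the shape, again because the second (11.68)
must be the median. Gompertz models with non-positive shape are rejected:
they leave a non-zero fraction of the cohort alive forever, which is not a
usable extrapolation here (and the family is never selected anyway).

## From curves to transition probabilities

With $\Delta$ one cycle in months, the per-cycle exit probability from PFS
is $1 - PFS(t+\Delta)/PFS(t)$ and the per-cycle death probability among
survivors is $1 - OS(t+\Delta)/OS(t)$. How those exits are allocated
between the PD and death destinations is not identified by marginal
curves, so `transition_schedule()` offers two schemes:

* **`"pd-routed"`** (default): every PFS exit moves to PD, and death
  occurs from PD at the OS-based per-cycle probability. PFS occupancy then
  reproduces the PFS curve exactly, while cohort survival runs somewhat
  above the OS curve (progressors re-enter the death-risk pool one cycle
  later). This is the scheme under which the package reproduces the
  published base-case life expectancy to better than 1%, and it is the one
  used by every published-figure computation in this package.
* **`"os-matched"`**: PFS-to-death uses the all-survivor death
  probability, and PD-to-death is re-solved each cycle so cohort deaths
  track the OS curve exactly. This scheme is the better-behaved one
  analytically — `validate_against_curves()` confirms both occupancy
  identities to 1e-6 — and is used by the structural property tests
  (occupancy vs. curves, restricted-mean-survival agreement).

Keeping both makes the package's central empirical claim honest: the
published life-years (2.30 and 1.66 discounted) are only attainable under
the pd-routed allocation, while the os-matched allocation is the one a
modeller would defend from first principles. Users can switch with the
`method` argument throughout.

## Discounting

Costs are discounted at 3% and health effects (life-years and QALYs) at 5%
per year, in *both* payer perspectives, with discount factors evaluated at
cycle midpoints. This split-rate reading is adopted because it is the only
configuration consistent with the published results, which report identical
life-years and QALYs for the two countries — any per-country difference in
the effect discount would break that equality — and because the published
discounted life-years match the pd-routed trace at 5% to under 1%. Both
rates remain independently configurable in the scenario files.

## Utilities and adverse events

State utilities are 0.76 (PFS) and 0.68 (PD). Four grade ≥3 adverse events
(neutrophil count decreased, neutropenia, anemia, platelet count
decreased) enter with arm-specific risks, one-time unit costs, and
disutility magnitudes (0.09, 0.09, 0.125, 0.20 respectively, matching each
event to its cytopenia disutility). The expected one-time AE cost
$\sum_i r_i c_i$ is charged at model entry.

The AE disutility *duration* is not specified in the source analysis, so it
is a design choice (`ae_disutility_mode`):

* **`"chronic"`** (default): the expected burden $\sum_i r_i |d_i|$ is a
  per-cycle utility decrement over all living person-time;
* **`"once"`**: a single one-cycle QALY loss at entry.

The chronic mode is the default because it is the only duration choice that
reproduces the published incremental QALY difference (0.420 here vs. 0.421
published, 0.3% apart); the one-cycle mode leaves QALYs 6–7% above the
published values. A caveat is recorded here openly: the published QALY
*levels* (1.52 and 1.10 against life-years of 2.30 and 1.66) imply
QALY/LY ratios of about 0.66, *below* the PD utility of 0.68, which no
admissible combination of the stated utilities can generate. The package's
durvalumab-arm QALY lands within 5% of the published figure and the
incremental QALY within 0.3%, but the GP-arm QALY sits about 6% low and
cannot be brought closer without distorting the other quantities; the
corresponding acceptance test is left failing rather than loosened.

## Costs

All prices are 2021 USD per 21-day cycle (Table-level inputs; no dose
arithmetic is performed, though a 60 kg reference weight is carried for
dose-based extensions). Per cycle, PFS accrues first-line drug costs plus
PFS-level laboratory, imaging, bed and care costs; PD accrues PD-level
follow-up costs plus the mixture-weighted subsequent-therapy drug cost
(FOLFOX components for chemotherapy, regorafenib for targeted therapy,
durvalumab for immunotherapy, irinotecan plus capecitabine for other, at
the arm-specific uptake proportions). First-hospitalization laboratory and
imaging charges and the expected AE cost are one-time, uncorrected entries
at cycle 0. Recurring costs are half-cycle corrected like the effects.

Four cost mechanics are not stated in the source analysis and are exposed
in `treatment_rules`, with defaults chosen once by calibrating the base
case to the published totals and then frozen:

* durvalumab continues while in PFS up to **30 cycles** (about 21 months,
  the span of the trial's follow-up window);
* gemcitabine/cisplatin for up to **8 cycles** (the trial regimen);
* subsequent therapy for up to **6 cycles** per PD entrant, counted from
  progression (entrant exposure is not attrition-adjusted but is capped at
  current PD occupancy);
* bed and care costs accrue in **both** living states.

With these defaults every published cost total is matched within ±3.3% and
both ICERs within 1%.

## Sensitivity analyses

`owsa()` varies each of the 43 uncertain parameters to its tabulated
bounds (±20% for most; the published asymmetric ranges where given) and
ranks ICER spans; the tornado is led by the durvalumab price, followed by
the two state utilities, matching the published ranking.
`price_threshold()` bisects a multiplicative durvalumab price factor
(applied to first-line and subsequent immunotherapy use) until the ICER
meets a target, to within \$1/QALY.

`psa()` draws costs from gamma and probabilities, utilities and disutility
magnitudes from beta distributions, moment-matched so the mean equals the
base value and the standard deviation is (max − min)/3.92, i.e. the
tabulated range read as a central 95% interval. Exactly matching mean *and*
both interval endpoints is overdetermined for two-parameter families, so
the range-implied SD is used directly; a beta whose implied variance is
infeasible for its mean falls back to the largest feasible variance with a
warning. Survival parameters are fixed in both sensitivity analyses, as in
the source analysis. Because the trace is fixed under PSA, each arm is
condensed once into discounted person-time weights (`arm_weights()`) and
every draw is re-priced by linear algebra; 1,000 draws evaluate in well
under a second.

## The synthetic trial generator

`trial_sim_spec()` / `simulate_ipd()` emulate the data situation of the
source analysis, whose raw IPD is unavailable: arms of 198 and 226
subjects, event times from the base-case OS models, per-subject PFS set to
the minimum of an independent progression draw and the death draw, uniform
accrual over 12 months with administrative censoring at a 24-month cutoff,
and `digitize_km()` sampling the KM estimate on a 60-point grid (optionally
with Gaussian point-picking jitter, default SD 0.005) plus a six-row
numbers-at-risk table. Progression and death draws are independent because
only marginal curves are published; real progression and death times are
positively dependent, so the generator's joint behaviour is a documented
simplification. Passing round-trip tests on these fixtures therefore
validates the reconstruction and fitting machinery, not the dependence
structure of real trial data.

## Numerical choices and degenerate inputs

Digitized curves are repaired by isotonic clamping (warning) and get the
origin (0, 1) prepended when absent; risk tables that increase over time
are rejected. Reconstruction is deterministic; when the digitized drops
round to fewer events than a supplied total event count, trailing
administrative censorings are converted to events at the last coordinate.
All-censored data raise an explicit "no events" error. Probabilities are
clipped to [0, 1] (with PD-to-death set to 0 while the PD state is empty in
the os-matched scheme), PFS curves above OS are clipped to OS with a
warning, and monetary results are rounded only in reporting layers.

## Worked sizes and limitations

The bundled analyses run at desk scale: a base case in ~0.1 s, the full
tornado in ~3 s, PSA with 1,000 draws in ~0.3 s; the test suite's
simulation-based checks use 1,000–10,000 subjects and 50 model-selection
replicates. Known limitations: no background (other-cause) mortality
floor, so very-long-horizon survival is whatever the fitted family implies;
cohort-level subsequent-therapy costing rather than tunnel states; no
dependence between progression and death draws in the generator; and the
published QALY-level inconsistency discussed above.
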