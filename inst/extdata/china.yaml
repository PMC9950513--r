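# Chinese payer perspective scenario.
# Uncertain parameters carry {base, min, max, dist}; min/max are the
# deterministic sensitivity bounds and, read as a central 95% interval,
# parameterize the probabilistic sensitivity distributions.
# All costs are 2021 USD per 21-day cycle unless marked one-time.
label: Chinese payer perspective
perspective: china
currency: 2021 USD
wtp: 38334
settings:
  cycle_days: 21
  horizon_years: 10
  discount_cost: 0.03
  discount_effect: 0.05
  half_cycle: true
  weight_kg: 60
survival:
  durva_os:  {family: loglogistic, shape: 1.81, scale: 13.55}
  durva_pfs: {family: loglogistic, shape: 2.19, scale: 7.07}
  chemo_os:  {family: loglogistic, shape: 2.22, scale: 11.68}
  chemo_pfs: {family: gamma, shape: 2.76, rate: 0.38}
utilities:
  pfs: {base: 0.76, min: 0.61, max: 0.91, dist: beta}
  pd:  {base: 0.68, min: 0.54, max: 0.82, dist: beta}
drug_costs:
  gemcitabine:     {base: 5.92, min: 4.74, max: 7.11, dist: gamma}
  cisplatin:       {base: 4.96, min: 3.96, max: 5.95, dist: gamma}
  durvalumab:      {base: 11225.18, min: 8980.15, max: 13470.22, dist: gamma}
  oxaliplatin:     {base: 112.14, min: 89.71, max: 134.57, dist: gamma}
  calcium_folinate: {base: 22.24, min: 17.79, max: 26.69, dist: gamma}
  fluorouracil:    {base: 140.97, min: 112.77, max: 169.16, dist: gamma}
  irinotecan:      {base: 547.28, min: 437.83, max: 656.74, dist: gamma}
  capecitabine:    {base: 43.2, min: 11.94, max: 99.73, dist: gamma}
  regorafenib:     {base: 1495.21, min: 1196.17, max: 1794.25, dist: gamma}
followup_costs:
  lab_first:     {base: 482.07, min: 45.60, max: 662.13, dist: gamma}
  lab_pfs:       {base: 266.00, min: 91.96, max: 446.06, dist: gamma}
  lab_pd:        {base: 390.57, min: 142.19, max: 626.12, dist: gamma}
  imaging_first: {base: 1457.11, min: 1221.95, max: 1832.77, dist: gamma}
  imaging_pfs:   {base: 246.91, min: 11.75, max: 622.57, dist: gamma}
  imaging_pd:    {base: 466.62, min: 246.83, max: 1832.77, dist: gamma}
  bed:           {base: 349.12, min: 49.46, max: 1219.47, dist: gamma}
  care:          {base: 404.74, min: 71.10, max: 1030.49, dist: gamma}
adverse_events:
  neutrophil_count_decreased:
    cost:       {base: 466, min: 373, max: 559, dist: gamma}
    disutility: {base: 0.09, min: 0.072, max: 0.108, dist: beta}
    risk_durva: {base: 0.207, min: 0.1656, max: 0.2484, dist: beta}
    risk_chemo: {base: 0.254, min: 0.2032, max: 0.3048, dist: beta}
  neutropenia:
    cost:       {base: 354, min: 283, max: 425, dist: gamma}
    disutility: {base: 0.09, min: 0.072, max: 0.108, dist: beta}
    risk_durva: {base: 0.192, min: 0.1536, max: 0.2304, dist: beta}
    risk_chemo: {base: 0.202, min: 0.1616, max: 0.2424, dist: beta}
  anemia:
    cost:       {base: 531, min: 425, max: 638, dist: gamma}
    disutility: {base: 0.125, min: 0.100, max: 0.150, dist: beta}
    risk_durva: {base: 0.189, min: 0.1512, max: 0.2268, dist: beta}
    risk_chemo: {base: 0.187, min: 0.1496, max: 0.2244, dist: beta}
  platelet_count_decreased:
    cost:       {base: 1814, min: 1451, max: 2177, dist: gamma}
    disutility: {base: 0.20, min: 0.160, max: 0.240, dist: beta}
    risk_durva: {base: 0.08, min: 0.064, max: 0.096, dist: beta}
    risk_chemo: {base: 0.076, min: 0.0608, max: 0.0912, dist: beta}
subsequent_therapy:
  regimens:
    chemotherapy: [oxaliplatin, calcium_folinate, fluorouracil]
    targeted: [regorafenib]
    immunotherapy: [durvalumab]
    other: [irinotecan, capecitabine]
  durva:
    chemotherapy:  {base: 0.417, min: 0.334, max: 0.500, dist: beta}
    targeted:      {base: 0.035, min: 0.028, max: 0.042, dist: beta}
    immunotherapy: {base: 0.009, min: 0.007, max: 0.011, dist: beta}
    other:         {base: 0.044, min: 0.035, max: 0.053, dist: beta}
  chemo:
    chemotherapy:  {base: 0.479, min: 0.383, max: 0.575, dist: beta}
    targeted:      {base: 0.047, min: 0.038, max: 0.056, dist: beta}
    immunotherapy: {base: 0.047, min: 0.038, max: 0.056, dist: beta}
    other:         {base: 0.081, min: 0.065, max: 0.097, dist: beta}
treatment_rules:
  durvalumab_max_cycles: 30
  gp_max_cycles: 8
  subsequent_max_cycles: 6
  bed_care_states: both
  ae_disutility_mode: chronic
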