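# Default model configuration: scalar inputs with uncertainty (2012 NZ$)
# plus shape specs for the synthetic age-sex curves. Curves are anchored at
# the published age-65 example values; their shapes are synthetic defaults,
# not national data (see gen_age_curve).

settings:
  discount_rate: 0.035
  wtp_threshold: 20000
  horizon_age: 100
  start_age: 40
  tunnel_years: 5
  quit_memory_years: 15
  ppp:
    USD: 0.68
    EUR: 0.53

quit_rate:
  # 24-week point-prevalence abstinence, adherent intervention vs usual care
  intervention:
    male:   {mean: 0.352, se: 0.047, family: beta}
    female: {mean: 0.298, se: 0.040, family: beta}
  usual_care:
    male:   {mean: 0.242, se: 0.030, family: beta}
    female: {mean: 0.197, se: 0.025, family: beta}

relapse:
  to_12mo: {mean: 0.21, family: fixed}              # 24 weeks -> 12 months
  after_12mo_cumulative: {mean: 0.30, family: fixed} # cumulative over 3 years
  years_after_12mo: 3

lc:
  early_prop: 0.20
  adv_prop: 0.80
  rr_smoker: {mean: 1.771, family: fixed}  # vs general population, at quit
  rr_decay_years: 15                        # linear decay to 1.0
  # stage-specific annual tunnel probabilities (synthetic defaults; chosen so
  # 5-year survival is worse for advanced than early stage)
  death_prob_early: 0.12
  death_prob_adv: 0.45
  progression_early_to_adv: 0.10

cvd:
  rr_smoker:             {mean: 1.42, se: 0.031, family: lognormal}
  rr_exsmoker_vs_smoker: {mean: 0.71, se: 0.036, family: lognormal}
  prehospital_fatality:  {mean: 0.181, family: fixed}
  fatality_28day:        {mean: 0.071, family: fixed}

utility:
  well_smoking: {mean: 0.800, family: fixed}
  well_quit:    {mean: 0.830, family: fixed}
  lc_early:     {mean: 0.73, se: 0.020, family: beta}
  lc_adv:       {mean: 0.56, se: 0.043, family: beta}
  # utility.cvd is composed from cvd_utility_components at load time

cvd_utility_components:
  - {condition: coronary_artery_disease,     utility: 0.629, weight: 0.549}
  - {condition: stroke,                      utility: 0.649, weight: 0.219}
  - {condition: congestive_heart_failure,    utility: 0.493, weight: 0.176}
  - {condition: peripheral_vascular_disease, utility: 0.657, weight: 0.056}

programme:
  trainer_hours: 9
  trainer_rate: 125
  psp_salary_total: 150000   # incl. 25% overhead
  gp_visit: 65.00
  pedometer: 30.44
  quitline_per_participant: 195.33
  n_intervention: 455
  n_control: 451
  n_adherent: 236

curve_specs:
  background_mortality:
    family: exponential
    anchor_age: 65
    anchor: {male: 0.01071, female: 0.00715}
    log_slope: 0.09
    kind: probability
  lc_incidence:
    family: exponential
    anchor_age: 65
    anchor: {male: 0.00180, female: 0.00165}
    log_slope: 0.085
    kind: probability
  cvd_incidence:
    family: exponential
    anchor_age: 65
    anchor: {male: 0.03095, female: 0.01843}
    log_slope: 0.07
    kind: probability
  cost_lc_first_year:
    family: flat
    anchor_age: 65
    anchor: {male: 23970, female: 22256}
    kind: cost
  cost_lc_subsequent:
    family: flat
    anchor_age: 65
    anchor: {male: 5375, female: 4341}
    kind: cost
  cost_lc_terminal:
    family: flat
    anchor_age: 65
    anchor: {male: 16615, female: 20300}
    kind: cost
  cost_cvd_first_year:
    family: flat
    anchor_age: 65
    anchor: {male: 11327, female: 10189}
    kind: cost
  cost_cvd_terminal:
    family: flat
    anchor_age: 65
    anchor: {male: 17573, female: 11048}
    kind: cost
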