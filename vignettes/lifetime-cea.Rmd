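---
title: "Methods: within-trial and lifetime cost-effectiveness of smoking-cessation support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial and lifetime cost-effectiveness of smoking-cessation support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quitcea)
```

## What the package models

`quitcea` implements the economic evaluation of an exercise-counselling
add-on to telephone quitline support for adult smokers, from the New Zealand
health-system perspective in 2012 NZ$. It has two stages:

1. a **within-trial analysis** at 24 weeks: programme costing, the
   incremental cost per participant, the ICER per additional quitter
   (7-day point prevalence), and the ICER per QALY from EQ-5D utilities;
2. a **lifetime Markov cohort model** comparing the adherent intervention
   group with usual care, tracking sex-specific cohorts of smokers in annual
   cycles from a start age (40 by default) to age 100 through smoking,
   quitting, relapse, cardiovascular disease (CVD) and lung cancer, with
   discounting, probabilistic sensitivity analysis (PSA), one-way sensitivity
   analysis and scenario analysis.

All monetary quantities are stored in 2012 NZ$; conversion to US$ or € via
purchasing-power-parity rates (NZ$1 = US$0.68 = €0.53) is purely a display
operation (`convert_currency()`).

## Within-trial analysis

Programme costs are the only costs at 24 weeks (no other health-sector
resource use is assumed to be attributable to the programme over that
window). One-off set-up costs (facilitator training, NZ$1,125; staff salary
including 25% overhead, NZ$150,000) are amortised over the 455 intervention
participants; per-participant components (GP referral NZ$65, pedometer
NZ$30.44, quitline NZ$195.33) are added, giving NZ$622.91 per intervention
participant versus NZ$195.33 under usual care and an incremental cost of
NZ$427.58. Costing is exact decimal arithmetic to the cent.

The ICER per quitter divides the incremental cost by the difference in
24-week point-prevalence quit proportions. Note that ratios computed from
*printed, rounded* quit rates (23.1% vs 21.7%, and 32.2% in the adherent
subgroup) differ by a few percent from ratios computed on unrounded trial
data; `icer()` reports the exact ratio of whatever inputs it is given.

QALYs over the 24-week window are computed per participant by the trapezoid
rule between baseline and follow-up EQ-5D utilities
(`qaly_accrual(u0, u1, 24/52)`). The between-arm difference is estimated with
baseline utility as a linear covariate (ANCOVA on the individual QALYs with a
normal-approximation CI). The adjustment estimator is a design choice: it is
the standard way to "adjust for baseline HRQoL" but other estimators exist.
Records missing either utility are excluded listwise; participants with
missing smoking status are counted as smokers.

## The lifetime Markov model

### State space

```{r}
build_state_space(tunnel_years = 5, quit_memory_years = 15)
```

* **well, smoking** — the whole cohort starts here;
* **well, quit** — expanded into 15 one-year sub-states tracking time since
  quitting, so lung-cancer risk can decay and relapse can be confined to the
  first post-quit years; the 15th sub-state self-loops;
* **CVD** — a single living state entered after a non-fatal cardiovascular
  event; occupants keep a permanently reduced utility and face only
  background mortality afterwards;
* **lung cancer**, early and advanced stage — each a 5-year tunnel so
  progression and death risk depend on years since diagnosis; the final
  tunnel year self-loops (long-term survivors remain in the disease state
  with its utility and subsequent annual costs);
* **dead** — absorbing, disaggregated by cause (other / CVD / lung cancer)
  for cost bookkeeping.

### Cycle structure and event order

Cycles are annual (all incidence inputs are annual probabilities). Within a
cycle events apply in a fixed order: **mortality** (background for all
living states from the age-sex life-table curve, plus stage-specific
lung-cancer death and early-to-advanced progression within the tunnels),
then **disease incidence** from the well states, then **smoking-status
flows**. Ordering mortality first means a person cannot die and acquire a
disease in the same cycle; CVD and lung cancer are mutually exclusive — an
individual in one disease state never transitions to the other.

Quit dynamics: in the first cycle the arm- and sex-specific quit probability
applies to smokers (adherent intervention: 35.2% male / 29.8% female; usual
care: 24.2% / 19.7%), and 21% of new quitters relapse before the end of that
cycle. Over post-quit years 1–3 quitters relapse at the constant annual
hazard `1 - 0.70^(1/3) ≈ 0.112`, whose cumulative effect is the reported
30%; how that 30% is spread over the three years is not specified anywhere,
and a constant hazard is the least-informative choice. From year 4 on,
relapse is zero. Relapsers return to the full smoker risk profile (their
risk-decay clock resets).

Disease risk: smokers face the smoker relative risks for lung cancer (1.771
versus the general population) and CVD (1.42). On quitting, CVD risk falls
immediately by the ex-smoker relative risk (0.71 versus smokers — no decay
horizon is published for CVD), while the lung-cancer relative risk decays
*linearly* from the smoker level to 1.0 over 15 years
(`lc_rr_exsmoker()`). Two interpretation choices here are deliberate
defaults rather than published facts: the decay shape (linear versus
stepwise) and reading 1.771 as the value *at quit*; both are configurable
inputs.

CVD events split into 18.1% pre-hospital deaths, 7.1% 28-day deaths among
the hospitalised 81.9%, and survivors (≈76.1% of events) who enter the CVD
state. The lung-cancer stage split at diagnosis is 20% early / 80% advanced.
Stage-specific annual tunnel probabilities (early: death 0.12, progression
0.10; advanced: death 0.45) are synthetic defaults chosen so that five-year
survival is markedly worse for advanced than early disease; they are config
inputs, not published values.

### Utilities, costs, discounting

State utilities per cycle: 0.800 well-smoking, 0.830 well-quit (a 0.03 gain
on abstinence), 0.73 early lung cancer, 0.56 advanced lung cancer, and 0.611
for CVD — the incidence-weighted composite of coronary artery disease
(0.629 at 54.9%), stroke (0.649 at 21.9%), congestive heart failure (0.493
at 17.6%) and peripheral vascular disease (0.657 at 5.6%).

Each cycle's QALYs use the occupancy at the **end** of the cycle, so deaths
during a cycle accrue nothing for it (conservative) and the quit utility
first applies in the cycle of the quit attempt. A half-cycle correction flag
(`accumulate(..., half_cycle = TRUE)`, averaging start- and end-of-cycle
occupancy) is available for exploration but off by default, since the
original analysis does not describe one.

Costs per cycle: the programme cost in the first cycle (NZ$622.91 vs
NZ$195.33 — the full-arm intervention cost is used for the adherent-group
comparison, matching the published arithmetic); lung-cancer first-year costs
for incident cases; lung-cancer subsequent annual costs for tunnel occupants
beyond their first year; CVD first-year costs for hospitalised events
(including 28-day deaths); and terminal six-month costs charged as a lump
sum in the cycle of cause-specific death — an annual-cycle model cannot
place half-years, and the deliberate convention is that event-time CVD
deaths (pre-hospital and 28-day) are CVD deaths, while later deaths from the
CVD state count as background deaths without a CVD terminal cost.

Costs and QALYs for cycle *t* are discounted by \(1/(1+r)^{t-1}\) with
*r* = 3.5% by default (0% and 5% in scenarios); the first cycle is
undiscounted.

## Parameters and configuration

Parameters live in a YAML file plus one CSV per age-sex curve
(`age,sex,value`); the packaged defaults reproduce the published scalar
table exactly (`default_parameters()`, `write_parameters()`,
`load_parameters()` round-trip). Each uncertain scalar is a
`(mean, se, family)` triple fitted by method of moments
(`fit_distribution()`): beta for probabilities, gamma for costs, lognormal
for relative risks with natural-scale moments
(\(\sigma^2 = \log(1 + cv^2)\), \(\mu = \log(m) - \sigma^2/2\)), because
means and standard errors are reported on the natural scale. Utilities with
no printed standard error (0.800 / 0.830 / 0.611) are fixed; the lung-cancer
utilities (0.73 ± 0.020, 0.56 ± 0.043) are sampled.

## The synthetic age-sex curves

Only single age-65 example values are published for the age-dependent
inputs (background mortality 0.01071 M / 0.00715 F; lung-cancer incidence
0.00180 / 0.00165; CVD incidence 0.03095 / 0.01843; and the five cost
curves). The generator (`gen_age_curve()`) extends each anchor into a full
curve: exponential in age (Gompertz-like) for mortality and incidence with
documented default log-slopes of 0.09, 0.085 and 0.07 per year — shapes a
demographer would call plausible for adult mortality and chronic-disease
incidence — and flat for costs. Probability curves are clipped to [0, 1] and
the anchor is reproduced exactly.

These curves are **anchored fixtures, not national data**. Consequently:

* quantities that do not touch the curves (all cost arithmetic, the
  composite CVD utility, within-trial ICERs, relapse dynamics) are exact
  reproductions;
* lifetime *levels* (per-person costs and QALYs, incremental QALYs, ICERs,
  probabilities of cost-effectiveness) are qualitatively comparable but not
  numerically identical to the published ones — the engine is validated
  instead by properties: probability conservation, closed-form geometric
  reductions, a zero-risk limit, and agreement with an independent
  per-individual microsimulation (10^5 individuals) within four binomial
  standard errors at every cycle;
* one published qualitative pattern does **not** emerge under these
  fixtures: ICERs becoming more favourable with older cohort start ages.
  In this implementation incremental costs do fall with age (same direction
  as published) and the disease-related QALY component rises to a hump
  around age 50, but the 0.03 quit-utility annuity shrinks with remaining
  lifespan faster, so total incremental QALYs fall and ICERs rise slightly
  with age. The published pattern implies a much heavier (and more
  age-concentrated) disease burden than single-anchor exponential curves
  produce — visible in the published cost offsets of NZ$175–300 per person
  versus roughly NZ$60 here. With real national incidence, mortality and
  cost curves supplied as inputs, the ordering is expected to flip back;
  the corresponding test documents the discrepancy rather than hiding it.

The trial-record generator (`gen_trial_cohort()`) draws quit status
Bernoulli at the arm rate and utilities from [0, 1]-bounded beta
distributions matched to the arm mean and individual-level spread
(se·√n with the reported arm size n). Baseline and follow-up utilities, and
quitting and utility, are drawn independently — the joint distributions are
unpublished — so the generator matches arm-level moments but not
individual-level correlation; baseline-adjusted analyses on generated data
therefore estimate a true adjusted difference of ≈0.23 × (follow-up mean
difference).

## Sensitivity analyses

* **PSA** (`run_psa()`): every uncertain scalar drawn independently (no
  correlation structure is published; in particular the two arms' quit rates
  are independent betas). Drawn probabilities are clipped to [0, 1] with a
  warning rather than redrawn, keeping draw counts exact. Age-sex curves are
  not sampled by default; `sample_curves = TRUE` perturbs each curve by one
  multiplicative mean-1 factor with configurable CV. One root seed spawns
  per-repetition child seeds, so extending the repetition count preserves
  earlier draws. The CEAC reports, per threshold λ, the fraction of draws
  with positive net monetary benefit λ·ΔQALY − ΔCost.
* **One-way** (`one_way()`, `one_way_all()`): each parameter moved to
  mean ± 2 se (±20% when no se is available), everything else bit-identical
  to base. Under the defaults the quit rates dominate the ICER range, as
  published.
* **Scenarios** (`run_scenarios()`): discount rates 0% and 5%, start ages
  30/50/60, for both sexes, alongside the base case.

## Problem sizes and runtime choices

The test suite validates the engine with a 10^5-individual microsimulation
over a 20-cycle window (start age 60), a 2,000-repetition PSA for the
base-case consistency check, and 10^5-draw moment checks for the fitted
distributions; the acceptance script runs 1,000 PSA repetitions per sex.
These sizes keep Monte-Carlo error well below the asserted tolerances (four
standard errors) while the whole suite completes in a few minutes on one
CPU.

## Known limitations

* Sex is the only source of heterogeneity; no other cancers or respiratory
  disease are modelled, and CVD/lung cancer are mutually exclusive — both
  understate the benefit of quitting.
* The lifetime comparison concerns the *adherent* intervention subgroup,
  which was not prospectively defined; the full-arm programme cost is used
  for it.
* Lung-cancer tunnel transition probabilities and the synthetic curve slopes
  are fixtures; supply real registry/life-table curves via
  `load_parameters()` for substantive use.
* No productivity costs, no EVPI analysis, and no within-trial bootstrap
  CIs.
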