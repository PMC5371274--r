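# quitcea

Economic evaluation of smoking-cessation support: a within-trial
cost-effectiveness analysis of an exercise-counselling add-on to telephone
quitline support, and a lifetime Markov cohort model of smoking, quitting and
relapse with cardiovascular disease (CVD) and lung-cancer health states.

The package is written for health economists and modellers who need a
transparent, fully tested reimplementation of this class of analysis:
every model input is an inspectable `(mean, se, distribution)` triple in a
plain-text configuration, every age-dependent input is a swappable
`age,sex,value` table, and every stage — costing, cohort simulation,
probabilistic/one-way/scenario sensitivity analysis — is an ordinary R
function operating on data frames.

## The model in brief

**Within-trial (24 weeks).** Programme costs only. The incremental cost per
participant is ΔC = 622.91 − 195.33 = NZ$427.58 (2012 NZ$), and

ICER = ΔC / Δp,

with Δp the difference in 7-day point-prevalence quit proportions. QALYs are
trapezoid areas under each participant's EQ-5D utility between baseline and
24 weeks; the between-arm QALY difference is estimated by ANCOVA with
baseline utility as covariate.

**Lifetime Markov cohort model.** Sex-specific cohorts of smokers run from
age 40 to 100 in annual cycles over the states {well-smoking; well-quit
(15 one-year time-since-quit sub-states); CVD; early / advanced lung cancer
(5-year tunnels); dead by cause}. Per cycle: background and disease-specific
mortality, then disease incidence (smokers at relative risks 1.771 for lung
cancer and 1.42 for CVD; after quitting CVD risk falls immediately by RR
0.71 while the lung-cancer RR decays linearly to 1 over 15 years), then
quit/relapse flows (21% relapse in the quit year, a further 30% cumulative
over the next three years). CVD events are 18.1% immediately fatal, 7.1% of
the hospitalised die within 28 days, survivors keep utility 0.611
permanently. Discounted (3.5%/yr) per-person costs and QALYs feed

ICER = ΔCost / ΔQALY,

and a 1000-repetition PSA gives the probability of cost-effectiveness at the
NZ$20,000/QALY threshold via the cost-effectiveness acceptability curve.

Only age-65 anchor values of the age-dependent curves are published, so the
package ships a synthetic-curve generator (exponential-in-age, anchored at
those values); lifetime results are therefore qualitative reproductions,
while the cost arithmetic and within-trial ICERs are exact. See the methods
vignette (`vignettes/lifetime-cea.Rmd`) for every modelling choice.

## Worked example

```r
library(quitcea)

# within-trial: costing + ICERs, with a synthetic individual-level cohort
tc <- trial_cea(trial_records = gen_trial_cohort(455, seed = 1))
tc
#> Within-trial cost-effectiveness (24 weeks, 2012 NZ$)
#>   intervention cost/participant: NZ$622.91
#>   usual-care cost/participant:   NZ$195.33
#>   incremental cost:              NZ$427.58 (NZ$428 rounded)
#>   ICER per quitter (ITT):        NZ$30,541
#>   ICER per quitter (adherent):   NZ$4,072
#>   adjusted QALY gain: 0.0033 (-0.0032 to 0.0098)
#>   ICER per QALY: NZ$129,419
```

Adding one extra quitter costs about NZ$30.5k when the whole intervention
arm is counted, but only ≈NZ$4.1k among participants who adhered (≥7
contacts); the 24-week QALY gain is indistinguishable from zero, so
within-trial cost-effectiveness rests on quitters, not short-term HRQoL.

```r
# lifetime model, adherent group vs usual care, 40-year-old male cohort
cs <- compare_strategies(default_parameters(), "male")
cs
#> <ce_result>
#>   incremental cost:   NZ$365.35
#>   incremental effect: 0.0593219 QALYs
#>   ICER: NZ$6,159 per QALY

# probabilistic sensitivity analysis
psa <- run_psa(default_parameters(), "male", n_reps = 500, seed = 1)
psa
#> <psa_result> male, start age 40, 500 draws (seed 1, 0 excluded)
#>   mean incremental cost:  NZ$363
#>   mean incremental QALYs: 0.0612
#>   P(cost-effective at NZ$20,000/QALY): 0.900
```

Over a lifetime the quitters gained in the first year compound into ≈0.06
discounted QALYs per person; disease costs averted offset part of the NZ$428
programme cost, and the ICER sits far below the NZ$20,000/QALY threshold,
cost-effective in ~90% of parameter draws. `autoplot(psa)` draws the
cost-effectiveness plane, `plot_ceac(psa)` the acceptability curve,
`run_scenarios()` the discount-rate and start-age scenario grid, and
`one_way_all()` the tornado table (quit rates dominate).

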