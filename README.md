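# spdsmoke

Compartmental modelling of cigarette-smoking disparities between US adults
with and without serious psychological distress (SPD, a Kessler-6 score of
13 or more).

People with SPD smoke at two to three times the rate of the general
population and quit less successfully, so even as overall smoking declines,
the burden concentrates in this group. `spdsmoke` implements the simulation
machinery needed to study that dynamic: two independent compartmental
models (one per stratum) whose initiation and cessation schedules are
calibrated to survey prevalence, projected forward under counterfactual
tobacco-control scenarios, and summarised as smoking-attributable deaths,
years of life lost, and absolute-versus-relative disparity metrics.

## The model

Each stratum's population is a real-valued count array over single year of
age (0–99, exit at 99), gender, and smoking state: never smoker, current
smoker, and former smoker binned by years since quitting (ysq 1–19 plus a
terminal 20+ bin). One annual time step applies, in order:

1. **mortality** — state-specific death probabilities;
2. **initiation** (never → current) and **cessation** (current → former,
   ysq = 1), with cohort-specific annual probabilities in the style of the
   CISNET transition surfaces: no initiation at ages 35+, no cessation
   before 18, quitting is permanent (no relapse);
3. **ysq increment** for existing former smokers, merging into the 20+ bin;
4. **aging**, with age-99 survivors exiting;
5. **births** entering at age 0 as never smokers.

Mortality composes a baseline death probability `m0(age, gender, year)`
with multiplicative hazard ratios: never smokers `μ_ns = m0 · hr_SPD^[SPD]`,
current smokers `μ_cs = μ_ns · hr_current(age band)`, and former smokers by
exponential interpolation

```
μ_fs(ysq) = μ_ns + (μ_cs − μ_ns) · exp(−λ · ysq)
```

so excess risk decays with time since quitting (default half-life ≈ 5
years).

**Calibration.** Gender × age-band scaling factors multiply the SPD
stratum's initiation and cessation probabilities; they are fitted by
minimising the sum of squared differences between modelled and observed
adult smoking prevalence over the survey years (Nelder–Mead in log-factor
space with a quasi-Newton polish). The no-SPD stratum keeps factors of 1.

**Scenarios.** *Status Quo* freezes the 2018 age profile of all transition
probabilities; *No Initiation* additionally zeroes initiation from 2023;
*MPRPM* (maximum potential reduction in premature mortality) additionally
forces every remaining smoker to quit in 2024.

**Outcomes.** Smoking-attributable deaths follow the excess-mortality
summation

```
SAD = Σ_{a,g} P · ( prev_cs · (μ_cs − μ_ns) + Σ_ysq prev_fs(ysq) · (μ_fs(ysq) − μ_ns) )
```

years of life lost weight each attributable death by never-smoker remaining
life expectancy from a period life table (`YLL = Σ e_ns · SAD`), and the
cessation-vs-initiation split of the MPRPM benefit is the difference
between the MPRPM and No Initiation scenarios. Disparities are reported
both ways: the absolute prevalence gap in percentage points and the SPD /
no-SPD prevalence ratio.

All inputs can be supplied as CSV files; a synthetic-data generator
(`synthetic_config()`, `make_rate_surfaces()`, `make_baseline_population()`,
`make_survey_targets()`) emulates the statistical structure of the real
inputs — declining cohort initiation, rising cohort cessation,
Gompertz–Makeham baseline mortality, published SPD population proportions,
noisy survey targets from a known factor truth — so the whole pipeline is
testable without restricted data.

## Worked example

```r
library(spdsmoke)

cfg    <- synthetic_config(seed = 1)
rates  <- make_rate_surfaces(cfg)
mort   <- make_mortality_model(cfg)
pop    <- make_baseline_population(cfg)   # SPD and no-SPD strata, 1997
births <- synthetic_births(cfg)

spd   <- project(pop$SPD, apply_scaling(rates, spd_true_factors()),
                 mort, scenario_status_quo(), 2100, births$SPD)
nospd <- project(pop$NoSPD, rates, mort, scenario_status_quo(), 2100,
                 births$NoSPD)

smoking_prevalence(spd[["2023"]])    # 0.2662
smoking_prevalence(nospd[["2023"]])  # 0.0841

disparity_report(spd, nospd, years = c(2023, 2060, 2100))
#   gender year spd_prev nospd_prev absolute_difference prevalence_ratio
#   female 2023    0.260      0.079                18.1              3.3
#   female 2060    0.136      0.036                10.0              3.8
#   female 2100    0.127      0.035                 9.1              3.6
#   ...
```

Between 2023 and 2100 both strata decline, the absolute gap narrows (18.1 →
9.1 percentage points) while the prevalence ratio widens (3.3 → 3.6) — the
disparity's direction depends on which metric you consult.

```r
oc <- outcome_series(spd, mort)                      # SAD, SAF, YLL by year
mp <- outcome_series(project(pop$SPD,
        apply_scaling(rates, spd_true_factors()), mort,
        scenario_mprpm(), 2100, births$SPD), mort, "mprpm")
deaths_averted(oc, mp, 2100)
# $deaths_averted     1839.5
# $life_years_gained 45010.8
```

(Counts scale with the synthetic population of one million persons.)

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end, passing
intermediate artifacts through `results/` as CSV/JSON:

```sh
Rscript analysis/01_generate_inputs.R     # synthetic input bundle
Rscript analysis/02_calibrate.R           # SPD scaling factors, least squares
Rscript analysis/03_project_scenarios.R   # 3 scenarios x 2 strata to 2100
Rscript analysis/04_disparity.R           # summary-table-style disparity report
Rscript analysis/05_decomposition.R       # cessation vs initiation split
```

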