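---
title: "Modelling smoking disparities by psychological-distress status: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling smoking disparities by psychological-distress status: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdsmoke)
```

## The problem

Adults with serious psychological distress (SPD; Kessler-6 score ≥ 13)
smoke at several times the rate of the rest of the population and quit less
often. Because the two groups' smoking trajectories decline at different
speeds, the *direction* of the disparity trend depends on the metric: the
absolute prevalence gap can narrow while the prevalence ratio widens.
`spdsmoke` provides a compartmental simulation of both populations so that
calibration, counterfactual projection, mortality accounting, and both
disparity metrics can be computed in one coherent framework.

## Model structure and assumptions

The state space is a deterministic, real-valued count array over single
year of age 0–99, gender, and smoking state: never smoker, current smoker,
and former smoker distinguished by years since quitting (single-year bins
ysq = 1…19 and an open terminal 20+ bin). Twenty bins carry the
former-smoker excess risk well past the point where it has substantially
decayed under the default half-life of about five years; the terminal bin
treats everyone 20+ years quit as equivalent.

One annual step applies transitions in a fixed order — mortality, then
initiation/cessation, then the ysq increment, then aging, then births.
The order is a modelling convention, not an identity; it is documented
here because every downstream number depends on it being applied
consistently:

* transitions during calendar year *t* use age attained in year *t* and
  the rate of birth cohort *t − age*;
* newly quit smokers appear at ysq = 1 in the year-*t+1* state, so the
  ysq increment applies only to people who were already former smokers at
  the start of the year;
* age-99 survivors exit the model; a configurable (default constant)
  birth count enters at age 0 as never smokers.

Structural rules follow the conventions of cohort-resolved tobacco
transition surfaces: no initiation below age 10 or at 35 and older, no
cessation before 18, and quitting is permanent (cessation probabilities
describe quitters of at least two years' standing, so relapse is not
modelled). The two strata never exchange members — SPD onset and remission
are outside scope — so the SPD and no-SPD populations run as two
independent model instances sharing the scenario clock.

Persons are conserved exactly: at every step, inflow equals survivors plus
deaths plus age-99 exits minus births, and the test suite holds this to
1e-9 relative tolerance along full trajectories.

## Mortality and life tables

Baseline all-cause death probabilities `m0(age, gender, year)` are
multiplied by hazard ratios that act multiplicatively and independently:
`hr_current` (current vs never smokers, by age band) and `hr_spd` (SPD vs
no-SPD, applied to every smoking state). Former smokers interpolate
exponentially between the current- and never-smoker rates,

$$\mu_{fs}(ysq) = \mu_{ns} + (\mu_{cs} - \mu_{ns})\,e^{-\lambda\,ysq},$$

which keeps $\mu_{fs}$ inside $[\mu_{ns}, \mu_{cs}]$ and monotone in ysq by
construction. The decay constant λ is a free input; the default
`log(2)/5` halves excess risk every five years. Products that exceed 1 are
capped with a warning. Interaction terms between the smoking and SPD
hazard ratios are not modelled; both ratios are user inputs, so absolute
mortality levels are only as realistic as the ratios supplied.

Never-smoker life tables use the standard period construction with
half-year person-year credit in the year of death, `L(a) = l(a) − 0.5
d(a)`, closed at age 99 (all survivors die in that year, contributing half
a year). Remaining life expectancy `e_ns(a) = T(a)/l(a)` weights each
smoking-attributable death in the YLL sum. With zero mortality this
yields `e(a) = 99.5 − a`, a convenient analytic check.

## Calibration

Scaling factors by gender and adult age band (18–34, 35–54, 55–64, 65–74,
75+) multiply the SPD stratum's initiation and cessation probabilities;
scaled values are clipped to [0, 1] and structural zeros are preserved.
The objective is the unweighted sum of squared differences between
modelled and target adult smoking prevalence over the survey years
(1997–2018 in the synthetic study), with the 1997 baseline population held
fixed — factors act on the forward transitions only.

Two design points deserve comment:

* **Identifiability.** Initiation is structurally zero at ages 35+, so
  only the 18–34 initiation factors can influence the likelihood; ages
  10–17 read the youngest band's factor. The default free-parameter set is
  therefore 2 initiation + 10 cessation factors (12 parameters), the rest
  pinned at 1.
* **Optimizer.** The contract is bounded least-squares minimisation;
  positivity is enforced by searching in log-factor space. The default is
  a Nelder–Mead stage (locating the basin) followed by a BFGS polish with
  numerical gradients, a total budget of about 2,000 objective
  evaluations and relative tolerance 1e-8. On noiseless synthetic targets
  this recovers generating factors to well under 1% relative error with
  final SSE below 1e-12; starting at the optimum returns immediately.
  Non-convergence is flagged in the result object rather than thrown.

With the default 1%-noise targets (additive Gaussian, truncated to (0, 1))
the fitted SSE lands at the noise floor (≈ n·sd²) and factors are
recovered to a few percent *on average*. Band-level identifiability
varies: a 0.01 absolute noise on a 75+ band whose prevalence is ≈ 0.04 is
25% relative noise, so that band's cessation factor is intrinsically
weakly determined — recovery there can err by 20–30% while the
well-populated bands stay within a few percent. Tests therefore assert
the mean relative factor error (≤ 10%), not the maximum.

## Scenarios and outcome accounting

All scenarios freeze transition probabilities at their 2018 age profile:
after the freeze, each age reads its frozen age-specific value, so new
cohorts inherit the youngest frozen cohort's schedule (an age-period view
of the freeze). *No Initiation* zeroes initiation in every transition year
from 2023 on. *MPRPM* additionally forces every current smoker — at all
ages, including minors — to quit so that the 2024 state and all later
states contain exactly zero current smokers. The source study's text is
ambiguous between 2023 and 2024 for the forced quit; this package defaults
to shutoff 2023 / forced cessation 2024 and exposes both years as
configurable fields rather than guessing further.

Smoking-attributable deaths evaluate the excess-mortality summation with
the former-smoker term resolved by ysq bin (terminal bin at ysq = 20).
"Premature deaths" is used interchangeably with SAD. The
smoking-attributable fraction divides SAD by all deaths of the same
stratum, gender and year — the denominator is within-stratum, a choice the
reporting conventions leave implicit. Cumulative windows start at 2023
inclusive and accumulate end-of-year. Averted deaths and life-years gained
are Status Quo minus counterfactual cumulative totals; the
cessation-vs-initiation decomposition reports `no_init / mprpm × 100` and
its complement, reconciled to sum to exactly 100 after 2-decimal rounding
(and undefined when the MPRPM total is zero). Deaths are rounded to the
nearest thousand and life-years reported in millions by the text
formatter only; all stored values are raw.

## Disparity metrics

The absolute metric is the prevalence difference in percentage points; the
relative metrics are the prevalence ratio and the excess relative
prevalence (ratio − 1), which is what a "relative difference" row in a
summary table reproduces. Display rounding (prevalence and gap to 0.1%,
ratio and relative difference to 1 decimal, change-from-base to whole
percent) is applied only in the report builder; `raw = TRUE` returns full
precision, on which the identity `relative_difference = ratio − 1` holds
exactly.

## The synthetic-data generator

The generator emulates the statistical structure of the real inputs
without reproducing any proprietary file:

* **Initiation surface** — a log-normal-shaped age curve peaking at 17
  (zero below 10 and at 35+) whose peak height declines logistically
  across birth cohorts from 0.14 to 0.002 (midpoint 1985, scale 5).
* **Cessation surface** — logistic in age from 18 (1.5% rising to 10% by
  old age) times a cohort multiplier rising from 0.7 to 2.2 (midpoint
  1960, scale 20).
* **Baseline mortality** — Gompertz–Makeham `A·exp(0.095·age) + 5e-4`
  with gender-specific levels, constant over calendar years.
* **Hazard ratios** — current-smoker ratios 2.8/2.8/2.6/2.2/1.7 across the
  five adult bands, SPD ratio 1.3, λ = log(2)/5.
* **Population** — one million persons in 1997 on the stationary age
  pyramid implied by the baseline survivorship, split between strata by
  the published SPD proportions by gender and age band; each cohort's
  smoking-state mix is obtained by replaying its own transition schedule
  up to its 1997 age (ignoring differential mortality by smoking state in
  that replay — the pyramid carries overall mortality).
* **Survey targets** — forward-model prevalences 1997–2018 by gender and
  age band with additive Gaussian noise (sd 0.01, truncated to (0, 1));
  the generating SPD truth is initiation × 2.2 (18–34 band) and cessation
  × 0.45 everywhere.

These defaults were fixed once so that the forward model reproduces the
study conditions the analysis assumes: roughly a quarter of no-SPD adults
smoking in 1997 falling to ~11–14% by 2018, an SPD-to-no-SPD prevalence
ratio of about 2.5–3 in the 2010s, continued Status Quo decline toward a
plateau by 2100, and the signature pattern of a narrowing absolute gap
with a widening ratio. They are study conditions, not tuning knobs.

What the generator does **not** emulate: the survey's complex sampling
design (noise is iid Gaussian on the prevalence scale), calendar trends in
baseline mortality, migration, cohort-size variation (births are
constant), or the exact scale of the US population. Passing tests
therefore demonstrate the machinery's correctness and the qualitative
disparity dynamics, not the published absolute death counts: at the
synthetic scale the cumulative SPD burden is thousands, not hundreds of
thousands, of deaths, and the late-century cessation-vs-initiation split
(≈ 47–53% by 2100) is more initiation-heavy than the published ≈ 82–18%
because the synthetic frozen initiation rates are relatively higher and
the Makeham background mortality gives young prevented initiates a small
but nonzero excess death rate.

## Problem sizes and numerical choices

The default test and analysis configuration uses the one-million-person
population, 131 birth cohorts (1890–2020), and the 1997–2100 horizon; a
full pipeline (generation, calibration, three scenarios for two strata,
all reports) completes in well under a minute on a single core, and the
noiseless recovery experiment in a few tens of seconds. Degenerate inputs
are handled explicitly: empty age ranges raise an undefined-prevalence
error rather than returning 0, zero total deaths flag the SAF as
undefined, a zero MPRPM total yields NA percentages, missing cohorts in a
rate schedule raise a missing-rate error, and negative counts anywhere
abort the step as an internal invariant violation (floating-point dust
below 1e-12 relative is scrubbed to zero).

## Known limitations

* Compartmental counts only — no individual-level heterogeneity beyond the
  age/gender/ysq structure, and no uncertainty intervals on calibrated
  factors.
* SPD status is fixed for life; the strata are closed.
* Non-cigarette products, relapse, and external shocks to smoking trends
  are out of scope.
* Absolute mortality outputs inherit whatever hazard ratios and λ the user
  supplies; the defaults are field-plausible placeholders, not estimates.
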