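---
title: "A lifetime Markov cost-utility model for transplant versus transfusion in severe thalassemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cost-utility model for transplant versus transfusion in severe thalassemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalcea)
```

## The decision problem

Severe (transfusion-dependent) thalassemia can be managed for life with
hypertransfusion plus iron-chelation therapy (BT-ICT), or potentially cured by
hematopoietic stem cell transplantation. Reduced-intensity conditioning
(RI-HSCT) extends transplantation to adolescents and young adults who would
tolerate myeloablative regimens poorly, but at a large upfront cost.
`thalcea` implements a cohort-level Markov model that weighs the two
strategies over a patient's remaining lifetime from a societal perspective:
discounted costs in 2011 US dollars (direct medical, direct non-medical,
indirect) against discounted quality-adjusted life-years (QALYs), summarised
as an incremental cost-effectiveness ratio (ICER) and net monetary benefit.
The default inputs are the base-case estimates of the reference evaluation of
this comparison in Thailand: a cohort entering at mean age 13.7 years,
willingness-to-pay thresholds of one and three times per-capita GDP (4,210
and 12,263 USD/QALY), and 3% annual discounting of both costs and outcomes.

## Model structure

Nine states. The transplant arm passes through four quarterly tunnel states
Q1–Q4 (the first transplant year, 90-day cycles), two annual iron-chelation
years (post-transplant phlebotomy/chelation), then a lifelong
post-transplant state. Graft failure — possible only from Q1 and Q2, since
no failures were observed after six months in the source cohort — moves
patients permanently onto the transfusion path. The transfusion path itself
has two sub-states, with and without cardiac complications, because cardiac
disease is the dominant cause of death under chronic transfusion; death is
absorbing. The comparator arm occupies only the transfusion states, with
annual cycles throughout.

The quarterly-versus-annual cycle question was genuinely open (the source
material describes both three-month first-year states and an annual cycle);
the engine resolves it as four 0.25-year cycles in transplant year one and
annual cycles everywhere else, with every rate/probability conversion
parameterised by an explicit span so both cycle lengths share one code path.
The model year is 360 days (four 90-day quarters), which keeps the survival
model's `t - u` grid aligned; calendar-exact years would complicate the
tunnel arithmetic for no practical gain at these hazards.

## From survival data to transition probabilities

Cohort event times (death, graft failure; competing events censored per
endpoint) are fitted with the parametric cumulative-hazard model

$$H(t) = \lambda t^{\gamma}, \qquad S(t) = e^{-H(t)},$$

exponential in the base case ($\gamma = 1$, MLE
$\hat\lambda = \text{events}/\text{person-days}$) with a free-shape Weibull
alternative. The per-cycle transition probability for a cycle of length $u$
ending at day $t$ is

$$P = 1 - \frac{S(t)}{S(t-u)}.$$

We read the survival expression as $S_t = \exp(-H_t)$, i.e. survival from
the *cumulative* hazard; exponentiating an instantaneous rate would be
dimensionally wrong. With 18 patients the cohort cannot estimate lifetime
mortality, so the per-cycle cohort death probability is blended with
age-specific background mortality on the rate scale: convert both to rates,
add, convert back. The same algebra carries the transfusion arm's excess
mortality (relative risk 3.9 applied to the background *hazard*, never by
probability multiplication) and the cardiac sub-state's additive
cause-specific mortality.

Two parameter sources coexist for the first-year failure probabilities. The
tabulated base case uses per-quarter probabilities of 0.00003 (Q1) and
0.0003 (Q2); these are orders of magnitude below the cohort's observed 2/18
failure frequency, and the derivation behind them is not recoverable. The
package therefore also accepts fitted survival models
(`failure_source = "fitted"`), and neither source is silently corrected —
the choice is explicit in `thal_params()`.

## Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `start_age` | 13.7 | years | cohort mean entry age |
| `horizon_years` | 99 | years | capped by the life table's terminal age |
| `disc_cost`, `disc_qaly` | 0.03 | /year | one-way range 0–6% |
| `q_fail_q1`, `q_fail_q2` | 3e-5, 3e-4 | /quarter | tabulated base case |
| `lambda_death_cohort` | 7.8e-5 | /day | $-\ln(1 - 1/18)/730$: one death among 18 over a mean 2-year follow-up |
| `rr_btict_death` | 3.9 | hazard ratio | transfusion-arm excess mortality |
| `p_cardiac_annual` | 0.0114 | /year | cardiac-complication onset |
| `cardiac_death_rate` | 0.05 | /year | see below |
| `ccr` | 1.37 | — | cost-to-charge ratio, range 0.8–1.5 |
| `thb_per_usd` | 30.50 | THB/USD | 2011 conversion |

The cardiac-cause death rate has no published age schedule we could deposit,
so the default is a constant 0.05/yr — roughly a 20-year mean survival after
cardiac involvement, a plausible middle ground for chronically transfused
patients with cardiomyopathy — and any `data.frame(age, rate)` schedule can
be supplied instead. The cardiac-state utility is derived, not free: the
no-complication utility 0.61 minus a heart-failure disutility of 0.15.
Hospital-database direct medical costs are treated as charges already
converted at a cost-to-charge ratio of 1.37, so varying `ccr` reprices them
by `ccr/1.37`; survey- and literature-sourced costs are unaffected.

## Synthetic inputs

No national life table or patient-level data are shipped; the
`synthetic_data` generators produce statistically faithful stand-ins.

* `generate_life_table()` builds a Gompertz–Makeham table,
  $\mu(x) = A + Bc^x$, with closed-form annual $q_x$ and terminal $q = 1$;
  `calibrate_life_table(74)` bisects on $B$ (log scale, since plausible $B$
  spans decades) to hit a target life expectancy at birth of 74 years, the
  value used throughout tests and the acceptance script.
* `generate_cohort()` draws exponential death and failure times with
  failure restricted to the first 180 days and uniform administrative
  censoring at 1–8 years, emulating the 18-patient cohort's ~11% failure
  and ~5.6% death frequencies.
* `generate_cost_survey()` draws gamma per-respondent costs moment-matched
  to a reported mean and standard error.

What the synthetic table does *not* emulate: real period tables have infant
and young-adult mortality humps and cohort effects; Gompertz–Makeham is
smooth. Consequently the model's absolute results on synthetic inputs are
internally consistent but not nationally calibrated — passing tests show the
engine is correct, not that the numbers transfer to any particular
population.

## Numerical choices

* **Competing exits within a cycle** (failure vs death in Q1–Q2, cardiac
  onset vs death in the transfusion state) are decomposed as independent
  constant rates: total exit mass $1 - e^{-\sum r_i}$ allocated
  proportionally to the $r_i$. Rows stay stochastic by construction and no
  event probability is ever rescaled; inputs that would force a row sum
  above one raise an error rather than being clipped.
* **No half-cycle correction**: costs and QALYs accrue on end-of-cycle
  occupancy, discounted at the cycle's end time with
  $(1+r)^{-t}$ (fractional exponents for quarters). This slightly
  understates both arms symmetrically and keeps the accrual auditable.
* **Age lookup** floors fractional ages onto the annual table; annual
  tables carry no sub-annual information to interpolate.
* **Terminal absorption**: the schedule stops at the earlier of the
  99-year horizon and the table's terminal age, whose $q_x = 1$ row absorbs
  any residual alive mass.
* **Pre-transplant work-up** costs are charged once, undiscounted, at time
  zero, to the transplant arm only.
* **PSA feasibility**: draws that violate model constraints are resampled
  with a count; a resample rate above 1% aborts the analysis.

## Sensitivity analysis

One-way analysis reruns the full two-arm model at each parameter's low and
high value (published ranges where stated — comparator utility 0.3–0.9,
discounting 0–6%, cost-to-charge ratio 0.8–1.5 — and mean ± 1.96 SE
otherwise), and `tornado()` ranks parameters by absolute ICER spread. The
one-way ratio is reported *signed*, so an extreme at which transplantation
becomes dominant (cheaper and more effective) orders below any positive
ICER; the headline `icer()` instead flags dominance explicitly.

The probabilistic analysis assigns beta distributions to probabilities and
utilities, gamma to costs, and log-normal to survival-rate parameters, all
moment-matched to their means and standard errors and sampled independently
(no correlation structure is available). Transition probabilities published
without dispersion take a standard error of half the mean — wide enough to
be honest about their provenance without leaving the (0,1) support. The
cohort death rate's log-scale standard error is the exponential MLE's
asymptotic $1/\sqrt{\text{events}}$. The default run is 1,000 draws; the
acceptability curve reports, per willingness-to-pay value $\lambda$, the
fraction of draws with $\lambda \, \Delta\text{QALY} - \Delta\text{Cost} > 0$.

Discount-rate scenarios follow the usual WHO triplet: both at 0%, outcomes
0% with costs 6%, and both at 6% (`disc_cost` and `disc_qaly` are
independent fields).

## Behaviour of the base case, and a structural caveat

On the calibrated synthetic table the transplant arm is costlier and more
effective — an upper-right cost-effectiveness-plane point with a QALY gain
of order ten — and the ICER falls well below the one-GDP threshold; the
acceptance script recomputes these numbers. Two sensitivity behaviours
deserve comment because they differ from the reference evaluation. First,
with the tabulated per-state costs, the incremental cost is dominated by the
costs of extended survival (decades of post-transplant follow-up) rather
than by front-loaded transplant spending; discounting therefore shrinks
incremental costs at least as fast as incremental QALYs, and the ICER is not
monotone in the discount rate. The reference evaluation's transplant-arm
direct medical total is substantially larger than its own tabulated
per-state inputs can reproduce, consistent with a front-loaded cost
component that was not itemised; with such a component the familiar
"higher discounting, higher ICER" pattern returns. Second, and for the same
reason, the tornado ranking here is led by the comparator's cost and utility
inputs rather than by the comparator utility alone. Both behaviours are
properties of the tabulated inputs, not of the engine, and both are
reproduced deterministically by the test suite.

## Problem sizes

Default analyses use a 101-row life table, ninety-odd cycles per arm, 1,000
PSA draws, 200 replicate cohorts of n = 100 for parameter-recovery checks
and 10^5 draws for distribution-mean checks — sizes at which every analysis
in this vignette and the test suite completes in seconds on a single core.

## Limitations

* Cohort-level simulation only; no microsimulation, no GvHD or infection
  sub-states (complications are folded into state costs and utilities).
* No Cox regression or covariates in the survival fit; competing risks are
  handled by censoring, the only identifiable choice at n = 18.
* Utilities enter as fixed parameters; instrument scoring (EQ-5D value
  sets, SF-6D) is out of scope.
* Costs are used as given in 2011 USD; no CPI re-inflation inside the
  engine, and no friction-cost method for productivity losses.
* Independent PSA sampling can draw a cardiac utility above the
  no-complication utility in a small fraction of draws; the two are related
  only through their base-case derivation.
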