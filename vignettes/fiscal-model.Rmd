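---
title: "Fiscal consequences of uncontrolled osteoarthritis pain: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiscal consequences of uncontrolled osteoarthritis pain: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oafiscal)
```

## The question the model answers

Health-service costing sees only a fraction of what a chronic painful
condition costs a government. For working-age people with hip or knee
osteoarthritis (OA), the larger fiscal consequence is reduced labour-market
participation: lost income-tax and national-insurance revenue, lost
indirect tax on spending, and additional transfer payments. `oafiscal`
prices this difference between a cohort whose OA pain is controlled
(labour-market behaviour of the general population) and an otherwise
identical cohort with uncontrolled moderate or severe pain, from the UK
government's perspective, using a generational-accounting framing. The
result is the *incremental net tax* (INT): discounted taxes minus
transfers and health costs, controlled arm minus uncontrolled arm. A
positive INT is the per-person loss to public finances caused by
uncontrolled pain.

## State space and transition structure

The model is an annual-cycle Markov cohort over eight fiscal states:
employed, unemployed, long-term (LT) sick, disabled, early retired,
retired, a tax-neutral "unknown" state, and dead. The structural rules,
all enforced by `build_transition_matrix()`:

* **Death first.** Each cycle the age- and sex-specific death probability
  is applied from every living state; all remaining rules are conditional
  on survival.
* **Annual reallocation.** Survivors in the employed and tunnel states are
  reallocated over the five labour-market outcomes using the age-banded
  baseline probabilities, so the controlled cohort tracks the published
  participation pattern as it ages.
* **Tunnel states.** Unemployment and LT sickness are one-cycle tunnels:
  every occupant leaves the spell after one cycle and re-enters the
  reallocation draw (re-entry counts as a new spell). This encodes short
  memory without extra state copies.
* **No return after disability or early retirement.** Both are absorbing
  until pension age; early retirees convert to ordinary retirement at the
  state pension age (SPA), and disabled people keep their disabled flag
  past SPA (it changes which benefits they draw).
* **Age rules.** No transitions into unemployment or early retirement at
  or after SPA (default 65); no transitions into employment above the
  maximum working age (default 70); after SPA the reallocation residual
  retires rather than becoming "unknown".
* **Unknown.** Residual probability mass falls into the tax-neutral
  unknown state for one full cycle and is sent to employment the next
  cycle. A config flag (`unknown_recurrent = FALSE`) instead folds the
  residual straight into employment, for users who want the unknown state
  to hold only the entry residual.

The cohort enters at age 50 distributed according to the (arm-specific)
baseline probabilities, with the residual in the unknown state. Both
sexes are simulated separately and weighted by the female share (0.586).
No half-cycle correction is applied: state membership is evaluated at
cycle start, matching the annual-cycle design; with 1-year cycles and a
3.5% discount rate the correction would shift all NPVs by under 2% and
cancels almost entirely in the incremental results.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `start_age` | 50 | years | cohort entry age |
| `horizon` | 15 | cycles | remaining work expectancy of a 50-year-old |
| `state_pension_age` | 65 | years | SPA: benefit switch and transition cut-off |
| `max_working_age` | 70 | years | oldest employable age |
| `discount_rate` | 0.035 | fraction/yr | NPV discounting, cycle 0 undiscounted |
| `female_share` | 0.586 | fraction | cohort sex mix |
| `healthcare_uplift_moderate` | 0.20 | fraction | extra healthcare use, moderate arm |
| `healthcare_uplift_severe` | 0.30 | fraction | extra healthcare use, severe arm |
| `or_threshold` | 0.10 | probability | rarity cut-off for OR-to-RR conversion |
| `oa_excess_hr` | 1.11 (1.06–1.17) | hazard ratio | OA excess mortality, both arms |
| `womac_hr_per_10` | 1.04 (1.01–1.07) | hazard ratio | per 10 WOMAC points, scenario only |

Monetary inputs (2020 UK tariffs, nominal GBP, no inflation indexing):
age-banded labour tax (£10 886 / £10 015 / £8 825 for 50–59 / 60–64 / 65+),
tax wedge 30.9%, indirect tax 13.7%, jobseeker's allowance £3 866, ESA
£4 885, PIP £6 102, basic state pension £9 110, attendance allowance
£3 258 paid to half of post-SPA disabled people. Earnings are back-computed
from the labour-tax amount through the wedge (`earnings = tax / 0.309`);
this is the only bridge consistent with reporting both taxes and earnings
from a single published tax figure. Indirect tax is levied on *disposable*
labour income for the employed and on *gross* benefit income for
recipients, and is booked as tax revenue rather than netted from
transfers. Statutory sick pay (employer-borne, first 28 weeks) is excluded;
LT-sick person-years carry the full annualised ESA amount.

Healthcare: every living person-year costs drugs (£203) + appointments
(£713) + referrals (70.82% × £82) + expected surgery (probability × cost;
primary surgery rates are unpublished and default to 0) + expected
revisions (hip aseptic 0.47% × £12 444, hip septic 0.04% × £22 946, knee
aseptic 0.35% × £10 325, knee septic 0.09% × £32 094). Uncontrolled arms
multiply the total by 1 + uplift.

## Derivations

* `rate_to_probability()` converts a probability over period `t_i` to a
  cycle probability under a constant hazard:
  `1 - exp(log(1 - p_i)/t_i * t)`.
* `odds_ratio_to_relative_risk()` uses the baseline probability `p0`:
  `RR = OR/(1 - p0 + p0*OR)`; applied whenever `p0 >= 0.10` (below that
  the OR is taken as the RR directly, the rare-outcome approximation;
  `convert_or` overrides).
* `derive_inactivity_probabilities()` stratifies the single published
  means for LT sickness and early retirement by multiplying them by each
  band's share neither employed nor unemployed, and forms disability as
  the product of the probability of being disabled and the prevalence of
  economic inactivity among disabled people (zero above SPA, capped at
  the band's remaining mass). The two means are validated to sum to at
  most 1, being shares of the same inactive pool.
* `adjust_mortality()` multiplies lifetable rates by the excess-mortality
  HR (and, in the differential scenario, by
  `womac_hr_per_10^(delta/10)` for the uncontrolled arm), then converts
  via `rate_to_probability()` with both periods equal to one year and
  caps at 1. The WOMAC deltas default to 20 (moderate) and 40 (severe)
  points — the approximate distance between the controlled band (< 7) and
  the middles of the moderate (7–38) and severe (≥ 39) bands; they only
  matter in the differential-mortality scenario.

When effect application pushes a probability past 1 it is clipped with a
warning; when a band's five outcomes come to exceed 1, the excess is first
absorbed by the band's unknown residual and any remainder removed by
proportionally rescaling the non-employment outcomes — employment, the
model's anchor parameter, is never rescaled. Both events are recorded on
the returned table and count as invalid draws in the PSA.

## Sensitivity analysis

One-way analysis (`one_way_sensitivity()`) replaces each uncertain
parameter in turn by its CI bounds and reruns the full model; baseline
participation probabilities and fiscal tariffs are national statistics and
are deliberately not varied. The PSA (`run_psa()`) samples all uncertain
parameters independently: ratio measures from a lognormal with the point
estimate as the *median* and `log(ci_high/ci_low)/3.92` as the log-SD,
probabilities from a moment-matched beta, costs from a moment-matched
gamma. Median-centring for ratios is a deliberate choice: for a CI as wide
as the moderate employment OR (0.21–1.54), a mean-centred lognormal would
shift the median well below the point estimate, and medians are how ratio
CIs are conventionally parameterised. Fit validity is checked at build
time (exact mean match for beta/gamma, exact median match for lognormal).
Each parameter draws from its own seed substream derived from the master
seed and the parameter id, so adding a parameter never perturbs the
others' draws. Draws that would clip or renormalise probabilities are
rejected and resampled; more than 10% rejections is an error. Credible
intervals are empirical 2.5th/97.5th percentiles, not normal
approximations.

Scenarios (`run_scenarios()`) are declarative config overrides:
lifetime horizon (to age 100, by which ~99% of the cohort has died),
SPA 67, healthcare uplifts moved by ±10 percentage points (the published
uplift variations are absolute, which is confirmed by the arithmetic:
halving the 20-point uplift removes exactly half the incremental
healthcare NPV), differential pain mortality, and onset at 45 with a
20-year horizon (ages below the first participation band carry the first
band's values back).

## The synthetic-data generators and the bundled input set

`make_lifetable()` produces a Gompertz lifetable
(`rate = a*exp(b*age)`, defaults `a = 3e-5`, `b = 0.095`, female rates ×
0.85), a deliberate synthetic stand-in for national lifetables, which are
external data the package does not ship. The defaults give a 50-year-old
an annual death rate of ~0.0035 doubling every ~7 years — realistic for a
modern high-income population. `make_baseline_tables()` builds age-banded
participation tables with employment near 0.72 at 50–54 declining with
age, and derives the inactivity columns through the same published-means
mechanism the real tables use; optional multiplicative noise stays within
the validity envelope. `make_effect_set()` generates effect sets with the
reported qualitative directions (employment OR < 1, everything else > 1).

`make_uk_inputs()` assembles the bundled UK set: the published
participation table (both sexes default to the same printed values, since
only one table is published; results are weighted by the female share),
the 2020 tariffs, the healthcare cost table, and the excess-mortality HR.
The relative effects need care: only the employment odds ratios are
reported numerically (0.57 moderate, 0.28 severe, upper moderate bound
1.54; the moderate lower bound is completed log-symmetrically at 0.21 and
the severe CI is synthetic). The secondary effects (unemployment, LT
sickness, disability, early retirement) are **synthetic placeholders**
with the reported direction, sized so that they remain secondary: the
employment OR is reported to be the only parameter that significantly
moves INT, with the rest contributing at most roughly a fifth. The
bundled values reproduce that hierarchy (employment OSA range ~17 500 GBP
against at most ~2 900 for any other parameter).

One structural consequence deserves honesty: because the unknown state
routes its occupants back to employment after one cycle, part of the
employment probability reduction in the uncontrolled arm is recycled into
employment a year later, so the INT swing attributable to the employment
OR is smaller here than in a model without that routing. With the
secondary effects held at their points this leaves the upper-bound INT
slightly positive; with the employment effect alone — the configuration
in which employment is strictly the dominant parameter — the upper CI
bound (OR 1.54 > 1) flips INT negative and the moderate PSA credible
interval spans zero while the severe one does not. The pattern checks in
the test suite therefore use `make_uk_inputs("employment-only")`.

What passing tests on synthetic data do *not* show: agreement with real
national lifetables or sex-specific participation tables, true
relative-effect magnitudes (hence no claim to reproduce published
headline figures), joint-replacement effects on participation, housing
benefit, employer sick pay, or informal-care losses — all outside the
model.

## Numerical choices

* Cohort traces are exact matrix products; occupancy rows are validated
  to sum to 1 within 1e-10 and the dead share to be non-decreasing.
* Transition-matrix rows are validated to sum to 1 within 1e-10 at
  construction; a negative structural residual raises an error naming the
  offending row.
* Discounting uses `1/(1+r)^t` with `t = 0` for the first cycle;
  life-years are the discounted living occupancy summed over cycle
  starts.
* Currency is nominal GBP throughout; rounding to whole pounds happens
  only at report time (`write_report()`).
* All Monte-Carlo code is reproducible from a single integer seed.

## Problem sizes

The test suite exercises the engine at the scale the science needs, not
larger: path-enumeration oracles up to 4 states × 5 cycles, 1 000 random
transition matrices for the row-stochasticity property, 200 random-seed
validation rounds for the generators, PSA determinism/convergence at
150–500 draws, and one full 10 000-draw PSA. The acceptance script runs
the base case, the lifetime scenario and two 10 000-draw PSAs in about
two minutes on one CPU.

## Known limitations

Single participation table for both sexes (the published source is
gender-specific but prints one table); secondary relative effects are
synthetic; the lifetime horizon truncates at age 100; no correlation
structure between PSA parameters (a user-supplied joint sampler can be
passed by substituting draws); benefits modelled as mutually exclusive
per state-year; no behavioural response to benefit generosity.
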