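---
title: "A quarterly Markov cohort model of syncope diagnosis: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quarterly Markov cohort model of syncope diagnosis: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncopeBIA)
```

## The decision problem

Recurrent unexplained syncope — transient loss of consciousness with no
etiology after history, physical examination and 12-lead ECG — is costly to
diagnose: each recurrence triggers a hospital admission, a fresh round of
diagnostic workup, and carries a substantial risk of injury. Two strategies
are compared from a national payer's perspective:

* **ILR**: early implantation of a loop recorder, a subcutaneous ECG
  monitor with a high probability of yielding a diagnosis at each syncope
  recurrence while its battery lasts;
* **CDP**: the conventional diagnostic pathway of repeated standard workup
  (ECG, Holter, tilt testing, electrophysiology, imaging) after each
  recurrence, with a low per-event yield.

The output is a budget impact: total discounted diagnostic and admission
costs per arm, their difference (cohort and per-patient savings), and the
uncertainty around it. No health outcomes are valued; patients are assumed
successfully treated once diagnosed, so the model stops at diagnosis.

## Model structure

A discrete-time Markov cohort model with three states — *undiagnosed
syncope*, *diagnosed* and *dead* — and a cycle length of 3 months. The
quarterly cycle is deliberate: it allows a patient more than one syncope
event per year while keeping at most one event per patient per cycle.
Diagnosed and dead are absorbing; a patient exits the model on either and
accrues no further events or costs.

With $U_t$ the expected undiagnosed-alive occupancy at the start of cycle
$t$, $\sigma_c$ the per-cycle syncope probability, $\delta_t$ the per-event
diagnostic yield at cycle $t$ and $q_t$ the per-cycle death probability:

$$
\text{episodes}_t = U_t\,\sigma_c,\qquad
\text{diagnosed}_t = U_t\,\sigma_c\,\delta_t,\qquad
\text{deaths}_t = U_t\,q_t,
$$
$$
U_{t+1} = U_t\,\bigl(1 - \sigma_c\,\delta_t - q_t\bigr).
$$

Three conventions deserve comment, each configurable:

* **Rate conversion** (`rate_conversion`). The annual syncope rate
  $\sigma = 0.6$ is converted to the quarter linearly,
  $\sigma_c = \sigma/4 = 0.15$, not exponentially
  ($1-e^{-\sigma/4} = 0.1393$). The linear rule is the one consistent with
  the reported 3-year diagnosis shares of the two arms (with the
  exponential rule the conventional arm's 3-year diagnosed share drops to
  about 18.9% instead of 20.3%). The exponential alternative is retained
  behind the flag.
* **Within-cycle competing risks** (`event_order`). Diagnosis and death
  fractions are both computed from the same start-of-cycle pool
  (*simultaneous* convention, the default, and again the one consistent
  with the reported counts). The *death-first* alternative removes deaths
  before events: $\text{episodes}_t = U_t(1-q_t)\sigma_c$, etc.
* **No half-cycle correction.** Events and costs are booked at cycle
  start. With quarterly cycles the half-cycle effect is below the rounding
  resolution of the reported counts.

Expected occupancies are carried unrounded through all computations;
rounding (half away from zero) happens only when counts are presented.

The 30-year "lifetime" horizon is a hard stop: survivors still undiagnosed
at the horizon simply exit, uncosted beyond that point.

## Mortality

Baseline mortality comes from an age-indexed life table of annual death
probabilities $q(a)$, looked up with linear interpolation at the cohort's
(uniformly advancing) age and multiplied by a hazard ratio of 1.32 — the
adjusted all-cause excess mortality observed in unexplained syncope. The
annual probability is converted to the quarter on the survival scale:

$$q_t = 1 - \bigl(1 - \min(1,\; q(a_t)\cdot 1.32)\bigr)^{1/4}.$$

The bundled life table is a **synthetic Gompertz–Makeham fixture**, not an
official national table (that source is external data):
$q(a) = 1-\exp(-(A + B e^{Ca}))$ with Makeham level $A = 5\times10^{-4}$,
slope $C = 0.097$ per year, and $B$ solved so that $q(61) = 0.010$; this
rises to about $0.15$ by age 90, a realistic shape for an adult European
population. It is swappable through the two-column life-table file
interface (`read_life_table()`), and runs against an official table are
the recommended check for lifetime results: the 3-year counts are nearly
insensitive to the mortality fixture (of the order of one patient), but
the 30-year discounted totals — and therefore the lifetime percentage
saving — are the output most sensitive to it, because the conventional
arm keeps patients exposed for decades.

## Parameters

| Parameter | Base value | Units / meaning |
|---|---|---|
| `start_age` | 61 | cohort age at entry, years |
| `cohort_size` | 197 | patients per arm; derived as 1,010 annual syncope admissions × 19.5% unexplained-recurrent, rounded half-up |
| `annual_syncope_rate` | 0.6 | events per undiagnosed person-year |
| `diagnosis_prob_ilr` | 0.628 | per-event yield, ILR arm, during battery life |
| `diagnosis_prob_cdp` | 0.125 | per-event yield, conventional pathway (and ILR arm after battery exhaustion) |
| `battery_life_years` | 3 | ILR battery life; the device is not replaced |
| `mortality_hazard_ratio` | 1.32 | multiplier on the life-table annual death probability |
| `injury_prob_per_event` | 0.522 | injury/trauma probability per syncope event |
| `severe_injury_fraction` | 0.1616 | fraction of injuries that are severe |
| `device_acquisition` | 2,000 € | ILR purchase price |
| `implantation` = `explantation` | 127.80 € | procedure tariffs (explantation set equal to implantation by convention) |
| `followup_visit` | 31 € | device-check consultation, 2 per year |
| `minor_trauma_tariff` / `major_trauma_tariff` | 2,684.83 € / 6,058.25 € | DRG proxy tariffs for injury admissions |
| `trauma_cost_per_event` | 1,687.57 € | canonical expected injury cost per episode |
| `annual_discount_rate` | 0.05 | applied to all cost streams |

### Canonical printed values versus recomputation

Two derived quantities are carried as *canonical inputs* rather than
recomputed on the fly, because the published weighted components do not
sum exactly to their published totals (rounding residuals of up to a few
euro, and ~8 € for the most expensive workup profile):

* the per-event **workup cost** of each scenario
  (`canonical_workup_cost()`, e.g. 164.32 € for the base scenario), and
* the per-event **trauma cost** (1,687.57 €; the tariff-weighted
  recomputation gives 1,686.05 € unrounded, 1,687.88 € from rounded
  weights).

`weighted_workup_cost()` and `expected_trauma_cost()` expose the
recomputations for transparency, and a warning is emitted whenever a
recomputed scenario total deviates from its canonical value by more than
1 €. In the sensitivity analyses, however, whenever a tariff or injury
probability is itself perturbed the per-event trauma cost *is* rederived
from the perturbed tariffs — holding the canonical constant would make
those parameters no-ops. The resulting base-point discrepancy is below
0.1% of total costs.

## Cost accrual

Per cycle and component, booked at cycle start and discounted at 5% per
year:

* **ILR arm**: acquisition and implantation for the whole cohort at cycle
  0; follow-up apportioned as 15.50 € per cycle (2 visits × 31 € / 4) per
  undiagnosed-alive patient during battery life; explantation at the cycle
  of diagnosis, or at the battery-expiry boundary for survivors still
  undiagnosed — never for patients who died with the device; trauma cost
  per expected episode at every cycle; workup cost per episode only after
  battery exhaustion (while the device works, it replaces the workup).
* **CDP arm**: no device components; trauma and workup cost for every
  episode at every cycle, whether or not the episode yields a diagnosis.

The smooth per-cycle apportionment of follow-up visits (rather than lumpy
semi-annual bookings) differs from the alternative by less than one cycle
of discounting.

**Discounting convention.** The published source states an annual rate but
not the intra-year timing, and its printed 3-year cost rows sit between
the two natural conventions, so the timing cannot be pinned down from the
published values. The default is per-cycle compounding,
$(1.05)^{-t/4}$; the annual-boundary alternative
$(1.05)^{-\lfloor t/4\rfloor}$ is a flag (`discount_convention`). The
choice moves the lifetime percentage saving by about half a percentage
point.

## Sensitivity analyses

**One-way / tornado.** Each parameter is moved to its lower and upper
bound with everything else at base, recording per-patient lifetime
savings at both ends; bars are sorted by width, ties broken
alphabetically so the ordering is reproducible. Default bounds halve and
double the base value, except where an external source fixes a bound
(ILR yield upper bound 0.78, syncope rate upper bound 0.81, injury
probability explored down to 0.25) or the support caps it (probabilities
at 1).

**Threshold sweep.** Lifetime savings over a grid of ILR yields; the
break-even yield is found by linear interpolation between the bracketing
grid points (the curve is monotone, so the bracket is unique). Both
threshold statements — the absolute break-even yield and its increment
over the conventional yield — are reported, since the two published
conditions (yield above 0.35, increment at least 0.175) are partially
redundant and their intended joint form is ambiguous.

**Probabilistic sensitivity analysis.** Parameters are drawn
independently — no correlation structure is asserted anywhere in the
source material — from families standard for their support: lognormal
for the hazard ratio and the syncope rate, gamma for costs, beta for
probabilities. The published dispersion settings are not available, so
defaults are derived from the one-way convention of halving/doubling:

* lognormal: median at the base value, $\sigma_{\log} = \log 2 / 1.96$,
  putting the 95% central interval at $[b/2,\,2b]$;
* gamma: mean at the base value, shape solved numerically so the ratio of
  the 97.5th to the 2.5th percentile is 4;
* beta: mean at the base value with effective sample size
  $\alpha+\beta = 100$.

All dispersions are overridable per parameter. Draws are consumed in a
fixed, documented parameter order from a single seeded generator, so a
seed fully reproduces a run. Because the published dispersions are
unknown, the published share of cost-saving draws (91.1%) is treated as
indicative; the package's own checks assert a clear majority under the
default dispersions, not a specific percentage.

## The microsimulation oracle

`simulate_patients()` generates individual patient histories with exactly
the statistical structure the cohort model assumes: per cycle, an
undiagnosed-alive patient draws a syncope event ($\sigma_c$), a diagnosis
given the event ($\delta_t$), an injury given the event (0.522), and
death. One construction detail matters: in the cohort recursion the
diagnosis and death exits are mutually exclusive with additive marginals
($U(1-\sigma_c\delta_t-q_t)$ survivors). Fully independent death and
diagnosis draws would produce a (tiny) overlap and bias the comparison,
so the simulation assesses diagnosis first and applies death to the
not-diagnosed with conditional probability $q_t/(1-\sigma_c\delta_t)$ —
giving exactly the marginals $\sigma_c\delta_t$ and $q_t$. Under this
construction the cohort model is *exactly* the expectation of the
microsimulation, which is what the validation tests assert (agreement
within three Monte-Carlo standard errors), and the same booking rules
applied to simulated histories converge to the cohort cost ledger per
patient.

What the generator does and does not emulate: it reproduces the model's
own assumptions (independent quarterly Bernoulli events, homogeneous
cohort, at most one event per cycle, exit at diagnosis). It does not add
features of real registry data — between-patient heterogeneity in
syncope rates, event clustering, seasonal patterns, post-diagnosis
pathways, or trauma severity beyond the minor/major dichotomy — so
passing oracle checks validates the implementation of the model, not the
model's fidelity to any particular clinical population.

## Numerical choices and degenerate inputs

* Occupancy conservation is enforced in tests to $10^{-9}$ of a patient;
  the zero-mortality trace must match the geometric closed form
  $N(1-(1-\sigma_c\delta)^t)$ to machine precision.
* A cycle in which $\sigma_c\delta_t + q_t > 1$ is an error under the
  simultaneous convention (not silently clamped).
* Zero syncope rate, zero cohort flows, zero unit costs and zero discount
  rates are all valid and produce exact zeros where expected.
* Counts are rounded half away from zero, and only at the presentation
  layer; report files format costs to whole euro and probabilities to
  four decimals.
* The break-even yield is `NA` when the savings curve does not change
  sign on the grid.

## Problem sizes used by the test suite

The shipped checks run the deterministic model at its natural size (12
and 120 quarterly cycles, 197 patients), the microsimulation oracle at
30,000 patients in unit tests and 100,000 in the acceptance check, PSA
convergence at 300 versus 3,000 draws, the full PSA at 10,000 draws, and
the engine-versus-simulation fuzz at 30 random parameter sets of 4,000
patients — sizes at which the Monte-Carlo tolerances (three standard
errors) are informative while the whole suite stays fast.

## Known limitations

* The bundled mortality fixture is synthetic; lifetime (30-year)
  discounted totals inherit its calibration, and should be re-run against
  an official life table for any decision use.
* Costs after diagnosis are out of scope (patients are assumed treated),
  as are cost-effectiveness ratios: this is a budget-impact model only.
* Injury costing uses initial-admission DRG tariffs; long-term sequelae
  of severe trauma are not modelled, which understates the conventional
  arm's true costs.
* PSA draws are independent; any real correlation (e.g. between the two
  trauma tariffs) would widen or narrow the savings distribution.
* No currency conversion or inflation adjustment; all prices are static
  inputs in euro.
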