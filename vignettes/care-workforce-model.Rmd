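---
title: "The care-workforce projection model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The care-workforce projection model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careflow)
```

## The problem and the model

Provincial health providers plan the "care workforce" — Registered
Nurses (RNs, including the small Registered Psychiatric Nurse group),
Licensed Practical Nurses (LPNs) and Health Care Aides (HCAs) — around a
single controllable lever: the size and retention of graduating classes.
careflow implements a deterministic yearly stock-and-flow recursion for
this planning problem. Employee headcount evolves as the difference
between staff demanded and staff supplied each year; there is no
randomness anywhere in the model, so identical inputs always produce
identical projections.

Internally every stock is held in FTE (full-time equivalents, the unit
budgets are written in); demand and supply are reported in persons. The
two are linked by each group's *average FTE* — the mean FTE held per
employee — which is the single conversion factor between "positions to
fill" and "people to hire". Demand for new staff is an additive
decomposition:

* **replacement** — separations, `φ × headcount`, where φ is the yearly
  separation (turnover plus retirement) rate;
* **growth** — service growth in line with the all-sector, age-weighted
  population growth rate ΔPop: `filled FTE × ΔPop / AvgFTE` persons;
* **casual add-on** — γ times the growth component; γ (the additional
  casual requirement) has no published value and defaults to 0;
* **shock** — persons needed to replace FTE withdrawn when a resource-
  sector recovery pulls staff away: `∈ × exposed fraction × filled FTE /
  AvgFTE`;
* **vacancy gap** — persons needed to pull the vacancy rate back to its
  normative target α, *net of* demand already claimed by carryover (see
  below);
* **carryover** — last year's unmet shortfall, carried forward
  undiminished.

Supply for RNs and LPNs is a constant annual stream: the graduating
class reduced by the historical in-province retention rate, rounded
half-up to whole persons (1582 × 0.70 → 1107 RNs; 802 × 0.90 → 722
LPNs). HCA supply is not consistently measurable (HCAs are unregulated
and need no defined program of study), so the HCA group carries a
`mirror_demand` supply rule: supply is set equal to demand and the group
never runs a book deficit.

The yearly update is an exact accounting identity, asserted in the test
suite to 1e-6:

```
filled_fte[t+1] = filled_fte[t] + hires×AvgFTE − separations×AvgFTE − shock_fte
```

with `hires = min(supply, demand)` (a surplus is not banked as extra
staff, and unmet demand cannot hire anyone). Budgeted FTE grows with
ΔPop each year. Shortfalls carry over *undiminished* into next year's
demand; surpluses do not accumulate. This matches the published
behaviour of the baseline projection, where the 2012 RN shortfall of
2137 is simply added to the 2013 demand estimate.

## Parameters

| parameter | symbol | unit | RN | LPN | HCA | rationale |
|---|---|---|---|---|---|---|
| budgeted FTE | — | FTE | 14653 | 3060 | 3039 | funded positions, Dec 2009 |
| separation rate | φ | 1/year | 0.0450 | 0.0579 | 0.0766 | 2009 payroll estimate |
| target vacancy | α | fraction | 0.03 | 0.05 | 0.05 | normative planning rate |
| retention | θ | fraction | 0.70 | 0.90 | — | graduates retained in-province |
| graduates | — | persons/yr | 1582 | 802 | — | 2008–2009 classes |
| average FTE | — | FTE/person | 0.68 | 0.70 | 0.424 | see below |
| casual requirement | γ | fraction | 0 | 0 | 0 | no published value |
| casual active share | — | fraction | 0.526 | 0.526 | 0.526 | worked-hours proxy |
| shock rate | ∈ | fraction of FTE | 0.0663 in the onset year | | | economic-recovery withdrawal |

The growth schedule is the published all-sector series (2.56 % in 2010
declining to 2.25 % by 2020). `aggregate_growth_rate()` derives an
all-sector rate from user-supplied sector rates and weights, but the
packaged fixture uses the published aggregate directly, since only the
aggregate is printed.

**Average FTE.** No average FTE is published for RNs and LPNs. The
fixture estimates them from the 2009 provincial full-time/part-time/
casual mix, counting a part-time employee as half an FTE and excluding
casuals (RN: (0.26 + 0.45/2)/0.71 ≈ 0.68; LPN: (0.29 + 0.44/2)/0.73 ≈
0.70). For HCAs the published casual-inclusive continuing-care proxy is
used: 7567 FTE / 17820 heads = 0.424. These are fixture defaults, not
estimates the engine depends on — any scenario can override them.

**Shock timing and exposure.** The withdrawal rate (6.63 % of FTE,
estimated from the 2008/2009 Foothills Medical Centre experience) is
published, but neither the year it bites nor the share of FTE in the
exposed metropolitan areas is. The fixture applies the full rate
(`shock_exposed_fraction = 1`) once, in 2011 — the first projection year
after the 2010 base — both choices being single configurable numbers
(`load_baseline(shock_onset =)`, the `shock_exposed_fraction` column).

**LPN supply convention.** 802 × 0.90 rounds to 722, yet the published
baseline table shows a constant 799 LPNs supplied per year. The package
does not guess at the source of the difference: the default baseline
uses the formula value, and `load_baseline(lpn_supply_override = 799)`
selects the published convention. Similarly, the published 2010 RN
supply of 1293 (1107 in every later year) is unexplained; calibration
mode or a per-year `supply_override` reproduces it without
interpretation.

## Numerical conventions

* **Rounding.** Person counts round half *up* (`round_half_up()`), not
  half-to-even: 76.6 separations are 77 people and 1107.4 retained
  graduates are 1107, matching the published accounting. Rounding is
  applied at operation boundaries (`retained_graduates()`,
  `separations()`, `active_casual()`) and at row-reporting time
  (`tidy(run, rounded = TRUE)`); the state fold itself runs in floating
  point so repeated rounding cannot drift the stocks. Rounded tables
  recompute the surplus from the rounded demand and supply so the
  identity `surplus = supply − demand` survives presentation.
* **Vacancy gap vs carryover.** Both quantities describe unfilled
  positions. To keep the component breakdown additive without counting
  the same vacancy twice, the vacancy-gap component is defined net of
  carryover: `max(0, unfilled_fte − α·budgeted − carryover·AvgFTE) /
  AvgFTE`. With the projection started at the target vacancy rate
  (filled = (1 − α) × budgeted, the `initial_state()` convention) the
  component stays at zero unless something other than tracked unmet
  demand — for instance a shock — pushes vacancies past target.
* **Degenerate inputs.** An empty workforce produces zero flows; a zero
  average FTE or a zero budget denominator is a configuration error, not
  a silent NaN; reported vacancy rates are clipped to [0, 1];
  `allocate_demand()` conserves rounded totals by largest-remainder
  correction with ties broken toward the first group, deterministically.

## Calibration mode

The published baseline table cannot be reproduced forward from the
published parameters alone: the printed recursion is typographically
garbled, the shock's timing and regional exposure are unstated, and the
vacancy denominator is unrecoverable. The published demand column (e.g.
RN demand jumping 1916 → 3244 between 2011 and 2012 net of carryover)
therefore cannot be uniquely decomposed, and the package does not invent
hidden factors to force a match. Instead `project()` accepts externally
fixed demand and/or supply streams. Feeding it the shipped
`reference_projection()` table replays every downstream computation —
deficits, carryover, cumulative sums, graduate shares, vacancy — on the
published streams, reproducing the printed arithmetic exactly (the 2137
shortfall of 2012, the 8618 cumulative RN deficit and 22 % RN vacancy
rate of 2020, the 1783 cumulative LPN surplus). The forward engine, run
from the parameter fixture, reproduces the qualitative structure — an
RN deficit growing to several thousand with vacancy climbing past 20 %,
a persistent LPN surplus — and its per-component demand breakdown is
exported precisely so users can calibrate against their own data.

## Scenarios

Six scenarios are packaged (`careflow_scenarios()`): baseline; "right
care, right place" (aged-care redesign); "full time work for full time
pay" (higher average FTE); retirement impact (higher separation rates);
and two "right skill" variants expanding the LPN or HCA workforce.
Skill-mix scenarios reallocate budgeted FTE between groups at a constant
total, since the skill mix is defined as the budgeted-FTE split. The
published scenario set states each lever's direction but not its
magnitude, so the packaged overrides are illustrative defaults —
two-point and five-point mix shifts, average FTE raised to 0.80 (0.50
for HCAs), separations up by a quarter — intended to be edited via
`scenario_spec()`. One-at-a-time sweeps (`sensitivity_sweep()`) report
per-group changes in cumulative deficit, cumulative surplus and end-year
vacancy; under the published separation-rate reductions (4.50 → 3.43 %,
5.79 → 4.16 %, 7.66 → 5.93 %) the RN shortfall shrinks and the LPN
surplus widens in every single year, the direction the sensitivity
analysis reports.

## What the tests do and do not show

The projection horizon is the published one — three groups over eleven
years (2010–2020) — and all fixtures are small, so the entire suite runs
in seconds. Property-style tests cover the accounting identity, the
zero-rate fixed point, zero carryover under ample supply, equivalence
with an independently hand-unrolled three-year recursion, monotonicity
of deficits in separation, growth, graduates and retention, and
determinism. Exact-value tests cover every published arithmetic quantity
through the fixtures and calibration mode. None of this validates the
*demand forecast itself* against reality: the model is an accounting
engine over assumed rates, it assumes demand grows technocratically with
population, constant graduating classes, no inter-professional
substitution beyond the three groups, no recruitment-market response to
shortages, and no costing. Those are properties of the planning model
being implemented, and they bound what any passing test can claim about
real workforces.
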