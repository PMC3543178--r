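# careflow

Deterministic stock-and-flow projection of the **care workforce** —
Registered Nurses (RN, with the small Registered Psychiatric Nurse group
folded in), Licensed Practical Nurses (LPN) and Health Care Aides (HCA) —
for provincial workforce planning. The package re-implements, as tested
and scriptable code, the yearly supply–demand recursion used by Alberta
Health Services to project its care workforce over 2010–2020, together
with its policy scenarios and sensitivity sweeps. It is aimed at health
workforce planners and modellers who need transparent, auditable
projections rather than a spreadsheet or a proprietary dashboard.

## The model

Employee headcount `E` evolves year by year as

```
E[t+1] − E[t] = Demanded[t] − Supplied[t]
```

Each year, the demand for *new* staff in each occupation group is an
additive decomposition, with every term traceable to a named parameter:

| component | formula (persons) | parameter |
|---|---|---|
| replacement | `φ · headcount` | separation rate φ |
| growth | `E_fte · ΔPop / AvgFTE` | population growth ΔPop, average FTE |
| casual add-on | `γ ·` growth | additional casual requirement γ |
| shock | `∈ · exposed · E_fte / AvgFTE` | economic-recovery withdrawal ∈ |
| vacancy gap | persons above the target vacancy α not already carried | target vacancy rate α |
| carryover | last year's unmet deficit, undiminished | — |

Supply for pipeline-fed groups is the constant stream of provincial
graduates retained in-province (`θ · NewGraduates`, e.g. 1582 RN
graduates × 70 % retention = 1107/year); HCA supply is set equal to HCA
demand because HCA supply is not consistently measurable. Shortfalls that
are not addressed carry over into next year's demand; surpluses are not
banked. All stocks are kept in FTE internally and converted to persons
through each group's average FTE; person counts round half-up at
reporting time only.

A *calibration mode* lets [`project()`] replay externally fixed demand
and/or supply streams — in particular the published baseline projection
table shipped with the package — so the downstream accounting (deficits,
carryover, vacancy rates, share of graduates hired) can be audited
independently of the demand reconstruction.

## Worked example

```r
library(careflow)

base <- load_baseline()   # the packaged status-quo parameter fixture
run  <- project(base)     # 2010-2020 projection
summary(run)
#> scenario 'baseline', 2010-2020
#> RN: cumulative deficit of 5316 by 2020; vacancy rate 23% (graduate supply cap binding in 11 years)
#> LPN: no shortfall projected; cumulative surplus of 3492 by 2020
#> HCA: no shortfall projected; cumulative surplus of 0 by 2020
```

The status quo cannot staff the projected growth: RN demand outruns the
1107 retained graduates every single year (the supply cap binds in all
11 years), the shortfall compounds through carryover, and the RN vacancy
rate climbs far above its 3 % target. LPNs stay in surplus throughout;
HCA supply mirrors demand by construction.

Replaying the published baseline table through calibration mode
reproduces its arithmetic exactly:

```r
ref <- reference_projection()
cal <- project(base,
  demand_stream = subset(ref, !is.na(demand), c(group, year, demand)),
  supply_stream = subset(ref, !is.na(supply), c(group, year, supply)))
summary(cal)
#> scenario 'baseline', 2010-2020
#> RN: cumulative deficit of 8618 by 2020; vacancy rate 22% (graduate supply cap binding in 11 years)
#> LPN: no shortfall projected; cumulative surplus of 1783 by 2020
#> HCA: no shortfall projected; cumulative surplus of 0 by 2020
```

`render_table(cal, "text")` prints the planning-table layout (deficits in
parentheses, whole percents):

```
Year  RN Demand  RN Supply  Supply Surplus/Deficit  FTE Vacancy Rate  % of Graduates Hired
2010        1381      1293        (88)      4%     70%
2011        1916      1107       (809)     12%     70%
2012        3244      1107      (2137)     13%     70%
...
2020        9725      1107      (8618)     22%     70%
```

Policy analysis goes through scenarios and sweeps:

```r
run_scenarios(base)                      # the six packaged scenarios
sw <- sensitivity_sweep(base, list(
  list(group = "RN",  param = "separation_rate", value = 0.0343),
  list(group = "LPN", param = "separation_rate", value = 0.0416),
  list(group = "HCA", param = "separation_rate", value = 0.0593)))
sw$summary[, c("group", "cumulative_deficit_baseline",
               "cumulative_deficit_adjusted")]
#>   group cumulative_deficit_baseline cumulative_deficit_adjusted
#> 1    RN                        5316                        3310
#> 2   LPN                           0                           0
#> 3   HCA                           0                           0
```

Lower turnover cuts the RN shortfall by roughly forty percent and widens
the LPN surplus in every year. `tidy(run)` returns the full per-group,
per-year table (with the demand-component breakdown), `glance(run)` the
per-group summary, and `autoplot(run)` the three demand/supply trajectory
graphs. A thin command-line wrapper lives in `inst/cli/careflow.R`
(subcommands `project`, `scenarios`, `sensitivity`, `params`).

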