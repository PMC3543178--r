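test_that("deficit is the signed supply-demand balance", {
  expect_equal(deficit(3244, 1107), -2137)
  expect_equal(deficit(250, 799), 549)
  expect_equal(deficit(42, 42), 0)
  expect_error(deficit(-1, 10), class = "careflow_validation_error")
})

test_that("share of graduates hired is capped by retention", {
  expect_equal(pct_graduates_hired(620, 802, 0.90), 0.77)
  expect_equal(pct_graduates_hired(250, 802, 0.90), 0.31)
  expect_equal(pct_graduates_hired(10000, 802, 0.90), 0.90)
  expect_true(is.na(pct_graduates_hired(100, 0, 0.9)))
  expect_true(is.na(pct_graduates_hired(100, NA, 0.9)))
  expect_equal(pct_graduates_hired(620, 802, 0.90, exact = TRUE), 620 / 802)
})

test_that("vacancy rate is unfilled over budgeted, clipped to [0, 1]", {
  expect_equal(vacancy_rate(0, 10000), 0)
  expect_equal(vacancy_rate(500, 10000), 0.05)
  expect_equal(vacancy_rate(12000, 10000), 1)
  expect_error(vacancy_rate(10, 0), class = "careflow_validation_error")
})

test_that("the all-zero-rate system is a fixed point of step", {
  p <- toy_params(rn_sep = 0, growth_rate = 0, shock = 0, graduates = 0)
  s0 <- initial_state(p)
  res <- step(s0, p, 2010)
  expect_equal(res$state, s0)
  expect_true(all(res$rows$demand == 0))
  expect_true(all(res$rows$supply == 0))
  expect_true(all(res$rows$surplus_deficit == 0))
  expect_true(all(res$rows$cumulative_deficit == 0))
})

test_that("mirror-demand groups always balance", {
  run <- project(load_baseline())
  hca <- run$rows[run$rows$group == "HCA", ]
  expect_equal(hca$supply, hca$demand)
  expect_true(all(hca$surplus_deficit == 0))
  expect_true(all(hca$cumulative_deficit == 0))
})

test_that("a toy year produces the hand-computed deficit and carryover", {
  # E = 1000 FTE at avg FTE 1, separation 10%, no growth, supply 50
  p <- toy_params(rn_sep = 0.1, growth_rate = 0, shock = 0,
                  graduates = 50, retention = 1, avg_fte = 1)
  s0 <- initial_state(p)
  res <- step(s0, p, 2010)
  rn <- res$rows[res$rows$group == "RN", ]
  expect_equal(rn$demand, 100)
  expect_equal(rn$supply, 50)
  expect_equal(rn$surplus_deficit, -50)
  expect_equal(rn$cumulative_deficit, 50)
  expect_equal(res$state$cumulative_deficit[res$state$group == "RN"], 50)
})

test_that("an empty horizon yields a run with empty tables", {
  run <- project(load_baseline(), horizon = integer(0))
  expect_s3_class(run, "careflow_run")
  expect_equal(nrow(run$rows), 0)
  expect_equal(nrow(glance(run)), 0)
})

test_that("a constant shortfall accumulates linearly over the horizon", {
  years <- 2010:2014
  streams <- tidyr::expand_grid(group = occupation_groups(), year = years)
  dem <- dplyr::mutate(streams, demand = 100)
  sup <- dplyr::mutate(streams, supply = 60)
  run <- project(toy_params(years = years), demand_stream = dem,
                 supply_stream = sup, horizon = years)
  expect_true(all(run$rows$surplus_deficit == -40))
  for (g in occupation_groups()) {
    expect_equal(cumsum(rep(40, length(years))),
                 cumsum(-run$rows$surplus_deficit[run$rows$group == g]))
  }
})

test_that("the projection matches an independently unrolled recursion", {
  p <- toy_params(rn_sep = 0.08, growth_rate = 0.03, shock = 0.0663,
                  graduates = 40, retention = 0.75, avg_fte = 0.8,
                  target_vac = 0.04, years = 2010:2012, gamma = 0.1,
                  exposed = 0.5)
  # shock only in the middle year
  p$shock$rate <- c(0, 0.0663, 0)
  run <- project(p)
  oracle <- oracle_project(p, 2010:2012)
  got <- run$rows[order(run$rows$year, run$rows$group),
                  c("group", "year", "demand", "supply", "surplus_deficit",
                    "filled_fte", "budgeted_fte", "cumulative_deficit")]
  want <- oracle[order(oracle$year, oracle$group), ]
  expect_equal(as.data.frame(got), want, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("yearly accounting identity holds to 1e-6 on the baseline", {
  run <- project(load_baseline())
  s0 <- initial_state(load_baseline())
  a <- setNames(load_baseline()$groups$avg_fte, load_baseline()$groups$group)
  for (g in occupation_groups()) {
    rows <- run$rows[run$rows$group == g, ]
    filled_prev <- s0$filled_fte[s0$group == g]
    for (i in seq_len(nrow(rows))) {
      expected <- filled_prev +
        (rows$hires[i] - rows$separations[i]) * a[[g]] - rows$shock_fte[i]
      expect_equal(rows$filled_fte[i], max(0, expected), tolerance = 1e-6)
      filled_prev <- rows$filled_fte[i]
    }
  }
})

test_that("ample supply means zero carryover and vacancy at target", {
  p <- toy_params(rn_sep = 0.05, growth_rate = 0.02, shock = 0,
                  graduates = 10000, retention = 1, avg_fte = 0.8,
                  target_vac = 0.04, years = 2010:2015)
  run <- project(p)
  expect_true(all(run$rows$surplus_deficit >= 0))
  expect_true(all(run$rows$cumulative_deficit == 0))
  pipeline <- run$rows$group %in% c("RN", "LPN")
  expect_equal(run$rows$fte_vacancy_rate[pipeline],
               rep(0.04, sum(pipeline)), tolerance = 1e-9)
})

test_that("identical inputs give identical projections", {
  r1 <- project(load_baseline(), careflow_scenarios()$retirement_impact)
  r2 <- project(load_baseline(), careflow_scenarios()$retirement_impact)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(glance(r1), glance(r2))
})

test_that("cumulative deficit is monotone in the policy levers", {
  base <- load_baseline()
  rn_cum <- function(params, scenario = NULL) {
    run <- project(params, scenario)
    -run$rows$surplus_deficit[run$rows$group == "RN" &
                                run$rows$year == 2020]
  }
  ov <- function(param, value) {
    scenario_spec("sweep", list(list(group = "RN", param = param,
                                     value = value)))
  }
  # separation rate up -> deficit up
  phis <- c(0.02, 0.0450, 0.07, 0.09)
  expect_true(all(diff(sapply(phis, function(v)
    rn_cum(base, ov("separation_rate", v)))) >= 0))
  # growth up -> deficit up
  deltas <- c(0, 0.0256, 0.04)
  expect_true(all(diff(sapply(deltas, function(v)
    rn_cum(apply_scenario(base, scenario_spec("g", list(
      list(group = "ALL", param = "growth_rate", value = v))))))) >= 0))
  # graduates up -> deficit down (weakly, each year)
  lo <- project(base)
  hi <- project(base, ov("graduates_per_year", 2500))
  expect_true(all(
    hi$rows$surplus_deficit[hi$rows$group == "RN"] >=
      lo$rows$surplus_deficit[lo$rows$group == "RN"] - 1e-9))
  # retention up -> deficit down
  thetas <- c(0.5, 0.7, 0.9, 1)
  expect_true(all(diff(sapply(thetas, function(v)
    rn_cum(base, ov("retention_rate", v)))) <= 0))
})

test_that("raising average FTE to 1 cannot raise headcount demand", {
  base <- load_baseline()
  full <- scenario_spec("full time", list(
    list(group = "ALL", param = "avg_fte", value = 1)))
  lo <- project(base)
  hi <- project(base, full)
  expect_true(all(hi$rows$demand <= lo$rows$demand + 1e-9))
})

test_that("run_scenarios preserves order and names the failing scenario", {
  base <- load_baseline()
  runs <- run_scenarios(base, careflow_scenarios()[1:2])
  expect_named(runs, c("baseline", "right_care_right_place"))
  expect_identical(tidy(runs$baseline), tidy(project(base)))
  # doubled separation never beats the baseline
  doubled <- run_scenarios(base, list(scenario_spec("double phi", list(
    list(group = "ALL", param = "separation_rate",
         value = 0.09)))))[[1]]
  expect_true(all(doubled$rows$cumulative_deficit >=
                    project(base)$rows$cumulative_deficit - 1e-9))
  expect_error(
    run_scenarios(base, list(scenario_spec("broken", list(
      list(group = "RN", param = "no_such", value = 1))))),
    regexp = "broken")
})

test_that("sensitivity sweep reports signed deltas; empty sweep is null", {
  sw0 <- sensitivity_sweep(load_baseline(), list())
  expect_true(all(sw0$summary$delta_cumulative_deficit == 0))
  expect_true(all(sw0$summary$delta_cumulative_surplus == 0))
  expect_true(all(sw0$yearly$delta == 0))
  sw <- sensitivity_sweep(load_baseline(), list(
    list(group = "RN", param = "separation_rate", value = 0.0343),
    list(group = "LPN", param = "separation_rate", value = 0.0416),
    list(group = "HCA", param = "separation_rate", value = 0.0593)))
  rn <- sw$yearly[sw$yearly$group == "RN", ]
  lpn <- sw$yearly[sw$yearly$group == "LPN", ]
  expect_true(all(rn$delta > 0))   # shortfall strictly smaller every year
  expect_true(all(lpn$delta > 0))  # surplus strictly larger every year
  expect_lt(sw$summary$delta_cumulative_deficit[sw$summary$group == "RN"], 0)
})
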