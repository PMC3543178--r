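#' Surplus or deficit
#'
#' Signed balance between supply and demand in persons; negative values
#' are shortfalls (rendered in parentheses in table output).
#'
#' @param demand,supply Persons (>= 0).
#' @return `supply - demand`.
#' @examples
#' deficit(3244, 1107) # -2137
#' @export
deficit <- function(demand, supply) {
  check_nonneg(demand, "demand")
  check_nonneg(supply, "supply")
  supply - demand
}

#' Share of the graduating class needed to meet demand
#'
#' Demand over the graduating class size, capped at the in-province
#' retention rate (a year cannot hire more of the class than history says
#' stays in the province). By convention the share is reported to the
#' whole percent.
#'
#' @param demand New staff demanded, persons.
#' @param graduates Graduating class, persons/year; 0 or missing gives
#'   `NA` (the share is undefined).
#' @param cap Retention cap, fraction in \[0, 1\].
#' @param exact Keep full precision instead of whole-percent rounding.
#' @return Fraction in \[0, `cap`\].
#' @examples
#' pct_graduates_hired(620, 802, 0.90) # 0.77
#' @export
pct_graduates_hired <- function(demand, graduates, cap, exact = FALSE) {
  check_nonneg(demand, "demand")
  if (is.na(graduates) || graduates == 0 || is.na(cap)) return(NA_real_)
  check_fraction(cap, "cap")
  check_nonneg(graduates, "graduates")
  p <- min(demand / graduates, cap)
  if (exact) p else round_half_up(p * 100) / 100
}

#' FTE vacancy rate
#'
#' Unfilled over budgeted FTE, clipped to \[0, 1\].
#'
#' @param unfilled_fte Unfilled FTE (>= 0).
#' @param budgeted_fte Funded FTE (> 0).
#' @return Fraction in \[0, 1\].
#' @examples
#' vacancy_rate(500, 10000) # 0.05
#' @export
vacancy_rate <- function(unfilled_fte, budgeted_fte) {
  check_nonneg(unfilled_fte, "unfilled_fte")
  if (any(budgeted_fte <= 0)) {
    abort("`budgeted_fte` must be positive.",
          class = "careflow_validation_error")
  }
  pmin(1, pmax(0, unfilled_fte / budgeted_fte))
}

#' Initial workforce state
#'
#' The projection starts from the funded establishment at its target
#' vacancy rate: filled FTE is budgeted FTE times (1 - target vacancy),
#' headcount is filled FTE over average FTE, and no deficit has been
#' carried in.
#'
#' @param params A `careflow_params` object.
#' @return Tibble, one row per group: `group`, `filled_fte`, `headcount`,
#'   `budgeted_fte`, `cumulative_deficit`.
#' @export
initial_state <- function(params) {
  validate_params(params)
  g <- params$groups
  filled <- g$budgeted_fte * (1 - g$target_vacancy_rate)
  tibble(group = g$group, filled_fte = filled,
         headcount = filled / g$avg_fte, budgeted_fte = g$budgeted_fte,
         cumulative_deficit = 0)
}

# one projection year for one group; state_row is a one-row tibble as in
# initial_state(). Fixed demand/supply (calibration mode) may be NA.
step_group <- function(state_row, params, group, year,
                       fixed_demand = NA_real_, fixed_supply = NA_real_) {
  row <- params_for_year(params, group, year)
  g_rate <- schedule_rate(params$growth, year, "growth")
  s_rate <- schedule_rate(params$shock, year, "shock")
  tv <- params$timevary
  tv_s <- tv[tv$group == group & tv$year == year & tv$parameter == "shock_rate", ]
  if (nrow(tv_s)) s_rate <- tv_s$value[nrow(tv_s)]
  a <- row$avg_fte

  dem <- demand_step(state_row, row, g_rate, s_rate)
  calibrated_demand <- !is.na(fixed_demand)
  demand <- if (calibrated_demand) fixed_demand else dem$total

  sup <- annual_supply(params, group, year)
  supply <- if (!is.na(fixed_supply)) {
    fixed_supply
  } else if (sup$mirror_demand) {
    demand
  } else {
    sup$new_graduate_hires
  }

  surplus_deficit <- deficit(demand, supply)
  hires <- max(0, min(supply, demand))
  shock_fte <- shock_loss(state_row$filled_fte, s_rate,
                          row$shock_exposed_fraction)
  filled_next <- max(0, state_row$filled_fte +
                       (hires - dem$replacement) * a - shock_fte)
  budgeted_next <- state_row$budgeted_fte * (1 + g_rate)
  carry_next <- max(0, demand - supply)

  list(
    state = tibble(group = group, filled_fte = filled_next,
                   headcount = filled_next / a,
                   budgeted_fte = budgeted_next,
                   cumulative_deficit = carry_next),
    row = tibble(
      group = group, year = as.integer(year),
      demand = demand, supply = supply, surplus_deficit = surplus_deficit,
      fte_vacancy_rate = vacancy_rate(max(0, budgeted_next - filled_next),
                                      budgeted_next),
      pct_graduates_hired = pct_graduates_hired(
        demand, row$graduates_per_year, row$retention_rate %||% NA_real_,
        exact = TRUE),
      demand_replacement = if (calibrated_demand) NA_real_ else dem$replacement,
      demand_growth = if (calibrated_demand) NA_real_ else dem$growth,
      demand_casual = if (calibrated_demand) NA_real_ else dem$casual_addon,
      demand_shock = if (calibrated_demand) NA_real_ else dem$shock,
      demand_vacancy_gap = if (calibrated_demand) NA_real_ else dem$vacancy_gap,
      demand_carryover = max(0, state_row$cumulative_deficit),
      hires = hires, separations = dem$replacement, shock_fte = shock_fte,
      filled_fte = filled_next, budgeted_fte = budgeted_next,
      headcount = filled_next / a, cumulative_deficit = carry_next,
      supply_capped = sup$capped, calibrated = calibrated_demand
    )
  )
}

#' Advance the projection by one year
#'
#' Applies the yearly recursion to every group: demand is assembled with
#' [demand_step()], supply with [annual_supply()] (mirror-demand groups
#' copy demand), the surplus/deficit is recorded, any shortfall becomes
#' next year's carryover, filled FTE is updated by hires minus
#' separations minus shock (an exact accounting identity), and budgeted
#' FTE grows with the year's growth rate.
#'
#' @param state Tibble as returned by [initial_state()] (one row per
#'   group).
#' @param params A `careflow_params` object.
#' @param year Projection year (must be inside the schedules).
#' @param demand_stream,supply_stream Optional calibration tibbles
#'   (`group`, `year`, `demand` / `supply`) fixing the streams for this
#'   year; see [project()].
#' @return List with `state` (next year's state tibble) and `rows` (this
#'   year's projection rows, unrounded).
#' @export
step <- function(state, params, year, demand_stream = NULL,
                 supply_stream = NULL) {
  validate_params(params)
  out <- purrr::map(state$group, function(g) {
    fd <- stream_value(demand_stream, g, year, "demand")
    fs <- stream_value(supply_stream, g, year, "supply")
    step_group(state[state$group == g, ], params, g, year, fd, fs)
  })
  list(state = purrr::list_rbind(purrr::map(out, "state")),
       rows = purrr::list_rbind(purrr::map(out, "row")))
}

stream_value <- function(stream, group, year, col) {
  if (is.null(stream)) return(NA_real_)
  hit <- stream[stream$group == group & stream$year == year, ]
  if (!nrow(hit)) return(NA_real_)
  hit[[col]][1]
}

#' Run a multi-year workforce projection
#'
#' Folds the yearly recursion over the horizon and returns a
#' `careflow_run`: per-group, per-year demand, supply, surplus/deficit,
#' vacancy rate, share of graduates hired, and the full demand-component
#' breakdown. The model is deterministic: identical inputs give identical
#' output.
#'
#' Calibration mode: `demand_stream` / `supply_stream` fix the demand
#' and/or supply columns to externally given person counts (for example a
#' published projection table), while the engine still computes deficits,
#' carryover, vacancy and percentage columns — so the downstream
#' arithmetic can be audited independently of the demand reconstruction.
#'
#' @param params A `careflow_params` object.
#' @param scenario Optional [scenario_spec()] applied before projecting.
#' @param horizon Integer vector of years (default: every year of the
#'   growth schedule). May be empty, giving a run with empty tables.
#' @param demand_stream,supply_stream Optional tibbles `group`, `year`,
#'   `demand` / `supply` (persons) fixing those streams where present.
#' @return A `careflow_run` object; see [tidy.careflow_run()],
#'   [glance.careflow_run()], [render_table()], [autoplot.careflow_run()].
#' @examples
#' run <- project(load_baseline())
#' glance(run)
#' @export
project <- function(params, scenario = NULL, horizon = NULL,
                    demand_stream = NULL, supply_stream = NULL) {
  params <- apply_scenario(params, scenario)
  if (is.null(horizon)) horizon <- params$growth$year
  horizon <- as.integer(horizon)
  if (length(horizon) && is.unsorted(horizon)) {
    abort("`horizon` must be an increasing sequence of years.",
          class = "careflow_validation_error")
  }
  state <- initial_state(params)
  rows <- vector("list", length(horizon))
  for (i in seq_along(horizon)) {
    res <- step(state, params, horizon[i], demand_stream, supply_stream)
    state <- res$state
    rows[[i]] <- res$rows
  }
  rows <- if (length(rows)) purrr::list_rbind(rows) else
    step(state, params, params$growth$year[1])$rows[0, ]
  structure(
    list(scenario = if (is.null(scenario)) "baseline" else scenario$name,
         horizon = horizon, rows = rows, params = params,
         final_state = state),
    class = "careflow_run")
}

#' @export
print.careflow_run <- function(x, ...) {
  cat(sprintf("<careflow_run> scenario '%s', %s\n", x$scenario,
              if (length(x$horizon))
                sprintf("%d--%d", min(x$horizon), max(x$horizon))
              else "empty horizon"))
  print(glance(x))
  invisible(x)
}

# packaged scenarios -------------------------------------------------------

#' The six packaged policy scenarios
#'
#' The discussion-paper scenario set: (1) baseline status quo; (2) "right
#' care, right place" — aged-care services shifted toward the continuing
#' care workforce; (3) "full time work for full time pay" — higher
#' average FTE per employee; (4) retirement impact — an ageing workforce
#' raises separation rates; (5) "right care, right place, right skill"
#' via LPN expansion; (6) the same via HCA expansion. Skill-mix scenarios
#' reallocate budgeted FTE between groups at a constant total (skill mix
#' is defined from budgeted FTE); the published set states the direction
#' of each lever but not its size, so the shift magnitudes here are
#' illustrative defaults meant to be edited with [scenario_spec()].
#'
#' @return Named list of six [scenario_spec()] objects.
#' @export
careflow_scenarios <- function() {
  # budgeted-FTE reallocations keep the Table-2 total of 20753 FTE
  list(
    baseline = scenario_spec(
      "baseline", list(), "Continuation of the status quo."),
    right_care_right_place = scenario_spec(
      "right_care_right_place",
      list(list(group = "RN", param = "budgeted_fte", value = 14238),
           list(group = "HCA", param = "budgeted_fte", value = 3454)),
      "Aged-care redesign: two points of skill mix move from RN to HCA."),
    full_time_work = scenario_spec(
      "full_time_work",
      list(list(group = "RN", param = "avg_fte", value = 0.80),
           list(group = "LPN", param = "avg_fte", value = 0.80),
           list(group = "HCA", param = "avg_fte", value = 0.50)),
      "Full-time work for full-time pay: higher average FTE worked."),
    retirement_impact = scenario_spec(
      "retirement_impact",
      list(list(group = "RN", param = "separation_rate", value = 0.0563),
           list(group = "LPN", param = "separation_rate", value = 0.0724),
           list(group = "HCA", param = "separation_rate", value = 0.0958)),
      "Ageing workforce: separation rates up by a quarter."),
    lpn_expansion = scenario_spec(
      "lpn_expansion",
      list(list(group = "RN", param = "budgeted_fte", value = 13615),
           list(group = "LPN", param = "budgeted_fte", value = 4098)),
      "Right skill (i): five points of skill mix move from RN to LPN."),
    hca_expansion = scenario_spec(
      "hca_expansion",
      list(list(group = "RN", param = "budgeted_fte", value = 13615),
           list(group = "HCA", param = "budgeted_fte", value = 4077)),
      "Right skill (ii): five points of skill mix move from RN to HCA.")
  )
}

#' Project a list of scenarios
#'
#' Runs [project()] once per scenario, in order. Any invalid scenario
#' aborts with the scenario's name in the message.
#'
#' @param params A `careflow_params` object.
#' @param specs List of [scenario_spec()] objects (default: the six
#'   packaged scenarios from [careflow_scenarios()]).
#' @param horizon Passed to [project()].
#' @return Named list of `careflow_run` objects.
#' @export
run_scenarios <- function(params, specs = careflow_scenarios(),
                          horizon = NULL) {
  validate_params(params)
  runs <- purrr::map(specs, function(sp) {
    tryCatch(project(params, sp, horizon = horizon),
             error = function(e) {
               abort(sprintf("scenario '%s' failed: %s", sp$name,
                             conditionMessage(e)),
                     class = "careflow_config_error")
             })
  })
  names(runs) <- purrr::map_chr(specs, "name")
  runs
}

#' One-at-a-time sensitivity sweep
#'
#' Runs the baseline and an adjusted projection with the given parameter
#' overrides applied, and reports the per-group change in cumulative
#' deficit, cumulative surplus and end-year vacancy rate. Year-by-year
#' deltas are kept alongside for plotting or deeper checks.
#'
#' @param params A `careflow_params` object.
#' @param overrides List of `list(group =, param =, value =)` entries
#'   (empty list gives all-zero deltas).
#' @param scenario Optional scenario applied to both arms (sensitivity
#'   around a non-baseline scenario).
#' @param horizon Passed to [project()].
#' @return A `careflow_sensitivity` object: `summary` tibble (`group`,
#'   baseline/adjusted/delta for `cumulative_deficit`,
#'   `cumulative_surplus`, `end_vacancy_rate`), `yearly` tibble of
#'   per-year surplus/deficit deltas, and the two runs.
#' @examples
#' sw <- sensitivity_sweep(load_baseline(),
#'   list(list(group = "RN", param = "separation_rate", value = 0.0343)))
#' sw$summary
#' @export
sensitivity_sweep <- function(params, overrides, scenario = NULL,
                              horizon = NULL) {
  base_params <- apply_scenario(params, scenario)
  base_run <- project(base_params, horizon = horizon)
  adj_run <- project(base_params,
                     scenario_spec("sensitivity", overrides),
                     horizon = horizon)
  gb <- glance(base_run)
  ga <- glance(adj_run)
  summary <- left_join(gb, ga, by = "group",
                       suffix = c("_baseline", "_adjusted")) %>%
    mutate(
      delta_cumulative_deficit = .data$cumulative_deficit_adjusted -
        .data$cumulative_deficit_baseline,
      delta_cumulative_surplus = .data$cumulative_surplus_adjusted -
        .data$cumulative_surplus_baseline,
      delta_end_vacancy_rate = .data$end_vacancy_rate_adjusted -
        .data$end_vacancy_rate_baseline) %>%
    select("group", dplyr::starts_with("cumulative_deficit"),
           dplyr::starts_with("cumulative_surplus"),
           dplyr::starts_with("end_vacancy_rate"),
           dplyr::starts_with("delta_"))
  yearly <- left_join(
    select(base_run$rows, "group", "year",
           surplus_deficit_baseline = "surplus_deficit"),
    select(adj_run$rows, "group", "year",
           surplus_deficit_adjusted = "surplus_deficit"),
    by = c("group", "year")) %>%
    mutate(delta = .data$surplus_deficit_adjusted -
             .data$surplus_deficit_baseline)
  structure(list(summary = summary, yearly = yearly,
                 baseline = base_run, adjusted = adj_run),
            class = "careflow_sensitivity")
}

#' @export
print.careflow_sensitivity <- function(x, ...) {
  cat("<careflow_sensitivity>\n")
  print(x$summary, width = Inf)
  invisible(x)
}
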