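#' The three care-workforce occupation groups
#'
#' The care workforce is modelled as Registered Nurses (RN), Licensed
#' Practical Nurses (LPN) and Health Care Aides (HCA). Registered
#' Psychiatric Nurses are too few to model separately and are counted
#' inside the RN pool.
#'
#' @return Character vector `c("RN", "LPN", "HCA")`.
#' @export
occupation_groups <- function() c("RN", "LPN", "HCA")

# Numeric group parameters and the admissible range of each. Used both to
# validate fixtures and to validate scenario overrides.
group_param_ranges <- function() {
  list(
    budgeted_fte           = c(0, Inf),
    avg_fte                = c(1e-12, 1),
    separation_rate        = c(0, 1),
    retention_rate         = c(0, 1),
    graduates_per_year     = c(0, Inf),
    target_vacancy_rate    = c(0, 1),
    casual_requirement     = c(0, 1),
    casual_active_fraction = c(0, 1),
    shock_exposed_fraction = c(0, 1),
    supply_override        = c(0, Inf)
  )
}

schedule_params <- function() c("growth_rate", "shock_rate")

#' Construct a parameter set
#'
#' Bundles the per-group parameter table with the year schedules into a
#' `careflow_params` object, the input to [project()] and friends.
#'
#' @param groups Tibble with one row per occupation group and columns
#'   `group`, `budgeted_fte` (funded positions, FTE), `avg_fte` (mean FTE
#'   held per employee, in (0, 1]), `separation_rate` (fraction of staff
#'   ending employment per year), `retention_rate` (fraction of provincial
#'   graduates hireable in-province; NA for groups without a pipeline),
#'   `graduates_per_year` (persons), `target_vacancy_rate` (normative
#'   fraction of funded positions unfilled), `casual_requirement`
#'   (additional casual need per unit of growth demand),
#'   `casual_active_fraction` (share of the casual pool actually working
#'   shifts), `shock_exposed_fraction` (share of the group's FTE exposed to
#'   economic-recovery withdrawal), `supply_rule` ("pipeline" or
#'   "mirror_demand") and `supply_override` (persons/year replacing the
#'   pipeline formula, NA to use the formula).
#' @param growth Tibble `year`, `rate`: all-sector growth of demand for the
#'   care workforce (fraction per year), one row per projection year.
#' @param shock Tibble `year`, `rate`: economic-recovery FTE withdrawal
#'   rate applied to exposed FTE in that year.
#' @param timevary Optional tibble `group`, `parameter`, `year`, `value`
#'   holding per-year parameter overrides (empty by default).
#' @return A `careflow_params` object.
#' @seealso [load_baseline()] for the packaged baseline,
#'   [apply_scenario()] for overrides.
#' @export
careflow_params <- function(groups, growth, shock,
                            timevary = empty_timevary()) {
  x <- structure(
    list(groups = as_tibble(groups), growth = as_tibble(growth),
         shock = as_tibble(shock), timevary = as_tibble(timevary)),
    class = "careflow_params"
  )
  validate_params(x)
}

empty_timevary <- function() {
  tibble(group = character(), parameter = character(),
         year = integer(), value = double())
}

#' Validate a parameter set
#'
#' Checks every structural invariant: exactly the three occupation groups,
#' all rates inside their admissible ranges, a growth rate for every
#' scheduled year, shock rates in \[0, 1\], and well-formed time-varying
#' overrides. Called by every constructor; exported so configurations read
#' from disk can be re-checked.
#'
#' @param params A `careflow_params` object.
#' @return `params`, invisibly usable, after passing all checks.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "careflow_params")) {
    abort("`params` must be a `careflow_params` object.",
          class = "careflow_validation_error")
  }
  g <- params$groups
  if (!setequal(g$group, occupation_groups()) ||
      nrow(g) != length(occupation_groups())) {
    abort("`groups` must contain exactly one row for each of RN, LPN, HCA.",
          class = "careflow_validation_error")
  }
  ranges <- group_param_ranges()
  for (p in setdiff(names(ranges), "supply_override")) {
    allow_na <- p %in% c("retention_rate", "graduates_per_year")
    check_fraction(g[[p]], p, ranges[[p]][1], ranges[[p]][2],
                   allow_na = allow_na)
  }
  check_nonneg(g$supply_override, "supply_override", allow_na = TRUE)
  if (!all(g$supply_rule %in% c("pipeline", "mirror_demand"))) {
    abort("`supply_rule` must be 'pipeline' or 'mirror_demand'.",
          class = "careflow_validation_error")
  }
  pipeline <- g$supply_rule == "pipeline" & is.na(g$supply_override)
  if (any(pipeline & (is.na(g$retention_rate) | is.na(g$graduates_per_year)))) {
    abort(paste("pipeline-fed groups need `graduates_per_year` and",
                "`retention_rate` (or a `supply_override`)."),
          class = "careflow_config_error")
  }
  check_fraction(params$growth$rate, "growth rate", -1, 1)
  if (anyNA(params$growth$year) || anyDuplicated(params$growth$year)) {
    abort("growth schedule needs one distinct row per year.",
          class = "careflow_validation_error")
  }
  check_fraction(params$shock$rate, "shock rate", 0, 1)
  tv <- params$timevary
  if (nrow(tv)) {
    known <- c(names(ranges), schedule_params())
    if (!all(tv$parameter %in% known)) {
      abort(sprintf("unknown time-varying parameter(s): %s",
                    paste(setdiff(tv$parameter, known), collapse = ", ")),
            class = "careflow_config_error")
    }
    for (i in seq_len(nrow(tv))) {
      validate_override_value(tv$parameter[i], tv$value[i])
    }
  }
  params
}

validate_override_value <- function(param, value) {
  ranges <- group_param_ranges()
  if (param %in% names(ranges)) {
    r <- ranges[[param]]
    check_fraction(value, param, r[1], r[2])
  } else if (param == "growth_rate") {
    check_fraction(value, param, -1, 1)
  } else if (param == "shock_rate") {
    check_fraction(value, param, 0, 1)
  } else {
    abort(sprintf("unknown parameter `%s`.", param),
          class = "careflow_config_error")
  }
  invisible(value)
}

#' @export
print.careflow_params <- function(x, ...) {
  cat("<careflow_params>\n")
  cat("Groups:\n")
  print(x$groups, width = Inf)
  cat(sprintf("Growth schedule: %d--%d (rates %.2f%%--%.2f%%)\n",
              min(x$growth$year), max(x$growth$year),
              100 * min(x$growth$rate), 100 * max(x$growth$rate)))
  sh <- x$shock[x$shock$rate > 0, ]
  if (nrow(sh)) {
    cat("Shock years:", paste(sprintf("%d (%.2f%%)", sh$year, 100 * sh$rate),
                              collapse = ", "), "\n")
  } else cat("Shock years: none\n")
  if (nrow(x$timevary)) {
    cat(sprintf("Time-varying overrides: %d\n", nrow(x$timevary)))
  }
  invisible(x)
}

#' Packaged baseline parameter set
#'
#' The status-quo baseline of the Alberta care-workforce planning exercise,
#' December 2009 stocks projected 2010--2020: budgeted FTE and skill mix
#' (RN 14653, LPN 3060, HCA 3039), separation rates estimated from 2009
#' payroll (RN 4.50%, LPN 5.79%, HCA 7.66%), normative vacancy targets
#' (RN 3%, LPN/HCA 5%), graduate classes of 1582 RNs and 802 LPNs retained
#' at 70% and 90% respectively, the all-sector age-weighted growth
#' schedule, and a one-off economic-recovery withdrawal of 6.63% of
#' exposed FTE. HCA supply mirrors demand (`supply_rule =
#' "mirror_demand"`) because HCA supply is not consistently measurable.
#'
#' Average FTE per employee is not part of the published parameter list for
#' RNs and LPNs; the fixture carries estimates from the 2009 Alberta
#' full-time/part-time mix (part-time counted as half an FTE, casuals
#' excluded), and the published casual-inclusive continuing-care proxy
#' 7567/17820 = 0.424 for HCAs.
#'
#' @param shock_onset Year the economic-recovery withdrawal is applied
#'   (default 2011, the first projection year after the 2010 base year).
#'   `NA` disables the shock.
#' @param lpn_supply_override Optional LPN supply in persons/year replacing
#'   the pipeline formula (802 graduates x 90% retention = 722). The
#'   published baseline table uses a constant 799/year; pass 799 to
#'   reproduce that convention.
#' @param years Projection years (default 2010:2020, the span of the
#'   packaged growth schedule).
#' @return A `careflow_params` object.
#' @examples
#' base <- load_baseline()
#' base$groups
#' @export
load_baseline <- function(shock_onset = 2011, lpn_supply_override = NULL,
                          years = 2010:2020) {
  groups <- tibble(
    group                  = c("RN", "LPN", "HCA"),
    budgeted_fte           = c(14653, 3060, 3039),
    avg_fte                = c(0.68, 0.70, 0.424),
    separation_rate        = c(0.0450, 0.0579, 0.0766),
    retention_rate         = c(0.70, 0.90, NA),
    graduates_per_year     = c(1582, 802, NA),
    target_vacancy_rate    = c(0.03, 0.05, 0.05),
    casual_requirement     = c(0, 0, 0),
    casual_active_fraction = c(0.526, 0.526, 0.526),
    shock_exposed_fraction = c(1, 1, 1),
    supply_rule            = c("pipeline", "pipeline", "mirror_demand"),
    supply_override        = c(NA_real_,
                               if (is.null(lpn_supply_override)) NA_real_
                               else lpn_supply_override,
                               NA_real_)
  )
  growth <- default_growth_schedule()
  if (!identical(as.integer(years), growth$year)) {
    growth <- growth[growth$year %in% years, ]
    missing <- setdiff(years, growth$year)
    if (length(missing)) {
      abort(sprintf("no growth rate on record for year(s) %s.",
                    paste(missing, collapse = ", ")),
            class = "careflow_config_error")
    }
  }
  shock <- tibble(
    year = as.integer(years),
    rate = ifelse(!is.na(shock_onset) & years == shock_onset, 0.0663, 0)
  )
  careflow_params(groups, growth, shock)
}

#' All-sector growth schedule, 2010--2020
#'
#' The projected yearly increase in demand for the care workforce: an
#' age-weighted aggregate over the six service sectors (acute care,
#' community/rural, seniors health, public health, primary care, mental
#' health), consumed directly as the all-sector rate.
#'
#' @return Tibble with columns `year` and `rate`.
#' @export
default_growth_schedule <- function() {
  tibble(
    year = 2010:2020,
    rate = c(0.0256, 0.0245, 0.0240, 0.0231, 0.0224, 0.0223,
             0.0224, 0.0225, 0.0227, 0.0223, 0.0225)
  )
}

# scenarios ----------------------------------------------------------------

#' Define a policy scenario
#'
#' A scenario is a named set of parameter overrides applied on top of a
#' baseline parameter set. Each override names an occupation group (or
#' `"ALL"`), a parameter, and either a single value or a named per-year
#' vector (names are years) for time-varying policies. Schedule parameters
#' `growth_rate` and `shock_rate` may also be overridden (group `"ALL"`).
#'
#' @param name Scenario name.
#' @param overrides List of `list(group =, param =, value =)` entries.
#' @param description Free-text description.
#' @return A `careflow_scenario` object.
#' @examples
#' low_turnover <- scenario_spec(
#'   "low RN turnover",
#'   overrides = list(list(group = "RN", param = "separation_rate",
#'                         value = 0.0343)))
#' @export
scenario_spec <- function(name, overrides = list(), description = "") {
  stopifnot(is.character(name), length(name) == 1)
  for (ov in overrides) {
    if (!is.list(ov) || !all(c("group", "param", "value") %in% names(ov))) {
      abort("each override needs `group`, `param` and `value`.",
            class = "careflow_config_error")
    }
  }
  structure(list(name = name, overrides = overrides,
                 description = description),
            class = "careflow_scenario")
}

#' @export
print.careflow_scenario <- function(x, ...) {
  cat(sprintf("<careflow_scenario> %s (%d override%s)\n", x$name,
              length(x$overrides), if (length(x$overrides) == 1) "" else "s"))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  for (ov in x$overrides) {
    v <- ov$value
    vtxt <- if (length(v) > 1 || !is.null(names(v))) {
      paste(sprintf("%s=%g", names(v), v), collapse = " ")
    } else format(v)
    cat(sprintf("  %s.%s <- %s\n", ov$group, ov$param, vtxt))
  }
  invisible(x)
}

#' Apply a scenario to a parameter set
#'
#' Pure function: returns a new parameter set with the scenario's
#' overrides applied; the input is never modified and non-overridden
#' values are carried through unchanged. Unknown parameter paths raise a
#' configuration error; out-of-range values raise a validation error.
#'
#' @param params A `careflow_params` object (e.g. [load_baseline()]).
#' @param scenario A [scenario_spec()]. `NULL` or an empty scenario
#'   returns `params` unchanged.
#' @return A new, validated `careflow_params` object.
#' @export
apply_scenario <- function(params, scenario = NULL) {
  validate_params(params)
  if (is.null(scenario)) return(params)
  if (!inherits(scenario, "careflow_scenario")) {
    abort("`scenario` must be a `careflow_scenario` object.",
          class = "careflow_config_error")
  }
  out <- params
  for (ov in scenario$overrides) {
    out <- apply_one_override(out, ov$group, ov$param, ov$value,
                              scenario$name)
  }
  validate_params(out)
}

apply_one_override <- function(params, group, param, value, where) {
  groups_hit <- if (identical(group, "ALL")) occupation_groups() else group
  if (!all(groups_hit %in% occupation_groups())) {
    abort(sprintf("scenario '%s': unknown group `%s`.", where, group),
          class = "careflow_config_error")
  }
  known <- c(names(group_param_ranges()), schedule_params())
  if (!param %in% known) {
    abort(sprintf("scenario '%s': unknown parameter `%s`.", where, param),
          class = "careflow_config_error")
  }
  per_year <- length(value) > 1 || !is.null(names(value))
  if (per_year && is.null(names(value))) {
    abort(sprintf("scenario '%s': per-year values for `%s` must be named by year.",
                  where, param), class = "careflow_config_error")
  }
  for (v in value) validate_override_value(param, v)
  if (param %in% schedule_params()) {
    slot <- if (param == "growth_rate") "growth" else "shock"
    sched <- params[[slot]]
    if (per_year) {
      yrs <- as.integer(names(value))
      unknown <- setdiff(yrs, sched$year)
      if (length(unknown)) {
        abort(sprintf("scenario '%s': year(s) %s outside the schedule.",
                      where, paste(unknown, collapse = ", ")),
              class = "careflow_config_error")
      }
      sched$rate[match(yrs, sched$year)] <- unname(value)
    } else {
      sched$rate <- unname(value)
    }
    params[[slot]] <- sched
    return(params)
  }
  if (per_year) {
    add <- tibble(group = rep(groups_hit, each = length(value)),
                  parameter = param,
                  year = rep(as.integer(names(value)), length(groups_hit)),
                  value = rep(unname(as.double(value)), length(groups_hit)))
    params$timevary <- bind_rows(params$timevary, add)
  } else {
    idx <- params$groups$group %in% groups_hit
    params$groups[[param]][idx] <- unname(value)
  }
  params
}

# resolve the parameter row in force for one group in one year, folding in
# time-varying overrides
params_for_year <- function(params, group, year) {
  row <- params$groups[params$groups$group == group, ]
  tv <- params$timevary
  tv <- tv[tv$group == group & tv$year == year, ]
  if (nrow(tv)) {
    for (i in seq_len(nrow(tv))) row[[tv$parameter[i]]] <- tv$value[i]
  }
  row
}

schedule_rate <- function(sched, year, what) {
  i <- match(year, sched$year)
  if (is.na(i)) {
    abort(sprintf("year %d is outside the %s schedule (%d--%d).",
                  year, what, min(sched$year), max(sched$year)),
          class = "careflow_config_error")
  }
  sched$rate[i]
}

# config file I/O ----------------------------------------------------------

#' Write / read a parameter set as JSON
#'
#' The JSON layout mirrors the object: `groups` (records), `growth`,
#' `shock` and `timevary`. Full numeric precision is preserved, so a
#' written file reads back into an identical parameter set.
#'
#' @param params A `careflow_params` object.
#' @param path File path.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns a validated `careflow_params`.
#' @export
write_params_json <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(
    list(groups = params$groups, growth = params$growth,
         shock = params$shock, timevary = params$timevary),
    path, digits = NA, na = "null", auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tv <- if (is.null(raw$timevary) || length(raw$timevary) == 0) {
    empty_timevary()
  } else as_tibble(raw$timevary)
  if (nrow(tv)) tv$year <- as.integer(tv$year)
  groups <- as_tibble(raw$groups)
  groups$supply_override <- as.double(groups$supply_override)
  growth <- as_tibble(raw$growth); growth$year <- as.integer(growth$year)
  shock <- as_tibble(raw$shock); shock$year <- as.integer(shock$year)
  careflow_params(groups, growth, shock, tv)
}

#' Export / import the group parameter table as CSV
#'
#' Long format with columns `group`, `parameter`, `value`, `units`,
#' `source`, one row per group-level parameter — the interchange format
#' for reviewing or editing parameters in a spreadsheet. Schedules are not
#' part of this table; use the JSON config for a complete round trip.
#'
#' @param params A `careflow_params` object.
#' @param path File path.
#' @param base Parameter set supplying schedules and supply rules when
#'   importing (default [load_baseline()]).
#' @return `write_params_csv()` returns `path` invisibly;
#'   `read_params_csv()` a validated `careflow_params`.
#' @export
write_params_csv <- function(params, path) {
  validate_params(params)
  units <- c(budgeted_fte = "FTE", avg_fte = "FTE/person",
             separation_rate = "fraction/year", retention_rate = "fraction",
             graduates_per_year = "persons/year",
             target_vacancy_rate = "fraction", casual_requirement = "fraction",
             casual_active_fraction = "fraction",
             shock_exposed_fraction = "fraction",
             supply_override = "persons/year")
  long <- params$groups %>%
    select(-"supply_rule") %>%
    tidyr::pivot_longer(-"group", names_to = "parameter",
                        values_to = "value") %>%
    mutate(units = unname(units[.data$parameter]), source = "model fixture")
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path, base = load_baseline()) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("group", "parameter", "value")
  if (!all(needed %in% names(long))) {
    abort("parameter CSV needs columns group, parameter, value.",
          class = "careflow_config_error")
  }
  wide <- tidyr::pivot_wider(long[needed], names_from = "parameter",
                             values_from = "value")
  groups <- base$groups
  for (p in intersect(names(wide), names(group_param_ranges()))) {
    groups[[p]][match(wide$group, groups$group)] <- wide[[p]]
  }
  careflow_params(groups, base$growth, base$shock, base$timevary)
}
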