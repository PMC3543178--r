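#' Graduates retained in the province
#'
#' Universities and colleges in the province are net exporters of new
#' graduates, so the graduating class is reduced by the historical
#' fraction retained in-province before it enters supply.
#'
#' @param graduates Graduating class size, persons/year (>= 0).
#' @param retention_rate Fraction of graduates hireable in-province.
#' @return Whole persons/year, rounded half-up.
#' @examples
#' retained_graduates(1582, 0.70) # 1107
#' retained_graduates(802, 0.90)  # 722
#' @export
retained_graduates <- function(graduates, retention_rate) {
  check_nonneg(graduates, "graduates")
  check_fraction(retention_rate, "retention_rate")
  round_half_up(graduates * retention_rate)
}

#' Annual separations
#'
#' Employees ending employment during the year: headcount times the
#' separation (turnover, including retirement) rate.
#'
#' @param headcount Persons employed (>= 0).
#' @param separation_rate Fraction leaving per year, in \[0, 1\].
#' @return Whole persons/year, rounded half-up.
#' @examples
#' separations(1000, 0.0766) # 77
#' @export
separations <- function(headcount, separation_rate) {
  check_nonneg(headcount, "headcount")
  check_fraction(separation_rate, "separation_rate")
  round_half_up(headcount * separation_rate)
}

#' FTE withdrawn by an economic shock
#'
#' In a resource-sector recovery a fraction of the nursing workforce in
#' exposed areas reduces hours or leaves; the loss is a rate applied to
#' the exposed share of filled FTE. Stays in FTE (not rounded): the
#' projection converts to persons with the group's average FTE.
#'
#' @param filled_fte Filled FTE (>= 0).
#' @param shock_rate Withdrawal rate, fraction of FTE.
#' @param exposed_fraction Share of the group's FTE in exposed areas.
#' @return FTE lost (numeric).
#' @examples
#' shock_loss(10000, 0.0663, 1.0) # 663
#' @export
shock_loss <- function(filled_fte, shock_rate, exposed_fraction = 1) {
  check_nonneg(filled_fte, "filled_fte")
  check_fraction(shock_rate, "shock_rate")
  check_fraction(exposed_fraction, "exposed_fraction")
  filled_fte * shock_rate * exposed_fraction
}

#' Average FTE per employee
#'
#' Total assigned FTE divided by the count of employees holding an FTE.
#' Converts between FTE stocks and person counts; also used for the
#' casual-inclusive proxy (total sector FTE over total headcount including
#' casuals).
#'
#' @param total_fte Total assigned FTE (>= 0).
#' @param headcount Employees holding an FTE (> 0).
#' @return Fraction (FTE per person).
#' @examples
#' average_fte(7567, 17820) # 0.4246...
#' @export
average_fte <- function(total_fte, headcount) {
  check_nonneg(total_fte, "total_fte")
  if (any(headcount == 0)) {
    abort("`headcount` is zero: average FTE is undefined for an empty workforce.",
          class = "careflow_validation_error")
  }
  check_nonneg(headcount, "headcount")
  total_fte / headcount
}

#' Casual staff actually working shifts
#'
#' Payroll systems keep casual employees on the books whether or not they
#' work; the active-casual proxy scales the payroll pool down to the share
#' observed to be working shifts in a month.
#'
#' @param casual_on_payroll Casual employees on the payroll (>= 0).
#' @param active_fraction Fraction actively working (default 0.526, the
#'   worked-hours estimate from January 2010 payroll records).
#' @return Whole persons, rounded half-up.
#' @examples
#' active_casual(1000, 0.526) # 526
#' @export
active_casual <- function(casual_on_payroll, active_fraction = 0.526) {
  check_nonneg(casual_on_payroll, "casual_on_payroll")
  check_fraction(active_fraction, "active_fraction")
  round_half_up(casual_on_payroll * active_fraction)
}

#' Annual supply of new staff for one group
#'
#' Pipeline-fed groups (RN, LPN) supply a constant annual stream of
#' retained graduates, optionally replaced by an explicit
#' `supply_override` (or a per-year override for intake-policy
#' scenarios). Groups flagged `mirror_demand` (HCA, whose supply is not
#' consistently measurable) return a sentinel telling the projection to
#' set supply equal to demand.
#'
#' @param params A `careflow_params` object.
#' @param group One of `"RN"`, `"LPN"`, `"HCA"`.
#' @param year Projection year (resolves any per-year overrides).
#' @return Tibble with one row: `group`, `year`, `new_graduate_hires`
#'   (persons; `NA` for mirror-demand groups), `mirror_demand` (logical)
#'   and `capped` (`TRUE` when the retention cap binds, i.e. hires equal
#'   the full retained-graduate stream rather than an override below it).
#' @examples
#' annual_supply(load_baseline(), "RN", 2012)
#' @export
annual_supply <- function(params, group, year) {
  validate_params(params)
  row <- params_for_year(params, group, year)
  if (row$supply_rule == "mirror_demand") {
    return(tibble(group = group, year = as.integer(year),
                  new_graduate_hires = NA_real_, mirror_demand = TRUE,
                  capped = FALSE))
  }
  if (!is.na(row$supply_override)) {
    hires <- round_half_up(row$supply_override)
    cap <- if (is.na(row$graduates_per_year)) Inf else
      retained_graduates(row$graduates_per_year, row$retention_rate)
    return(tibble(group = group, year = as.integer(year),
                  new_graduate_hires = hires, mirror_demand = FALSE,
                  capped = hires >= cap))
  }
  if (is.na(row$graduates_per_year) || is.na(row$retention_rate)) {
    abort(sprintf(
      "group %s has no graduate pipeline and no supply rule; set `graduates_per_year`/`retention_rate`, a `supply_override`, or `supply_rule = 'mirror_demand'`.",
      group), class = "careflow_config_error")
  }
  tibble(group = group, year = as.integer(year),
         new_graduate_hires = retained_graduates(row$graduates_per_year,
                                                 row$retention_rate),
         mirror_demand = FALSE, capped = TRUE)
}
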