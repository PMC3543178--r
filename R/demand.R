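#' All-sector growth rate from sector rates and weights
#'
#' Sector-specific growth estimates (acute care, community/rural, seniors
#' health, public health, primary care, mental health) are combined into a
#' single age-weighted all-sector rate as the weighted mean.
#'
#' @param sector_rates Named numeric vector: growth rate per sector.
#' @param sector_weights Named numeric vector over the same sectors,
#'   non-negative and summing to 1 (tolerance 1e-9).
#' @return The aggregate growth rate (fraction).
#' @examples
#' aggregate_growth_rate(c(acute = 0.02, seniors = 0.04),
#'                       c(acute = 0.5, seniors = 0.5))
#' @export
aggregate_growth_rate <- function(sector_rates, sector_weights) {
  if (!setequal(names(sector_rates), names(sector_weights)) ||
      is.null(names(sector_rates))) {
    abort("`sector_rates` and `sector_weights` must share the same sector names.",
          class = "careflow_validation_error")
  }
  check_nonneg(sector_weights, "sector_weights")
  if (abs(sum(sector_weights) - 1) > 1e-9) {
    abort("`sector_weights` must sum to 1.",
          class = "careflow_validation_error")
  }
  w <- sector_weights[names(sector_rates)]
  sum(w * sector_rates)
}

#' Skill-mix shares from budgeted FTE
#'
#' The proportional split of the care workforce across groups, from funded
#' (budgeted) FTE: 14653/3060/3039 FTE gives the 70.6%/14.7%/14.7%
#' RN/LPN/HCA status-quo mix.
#'
#' @param budgeted_fte Numeric vector of budgeted FTE, optionally named by
#'   group; at least one entry must be positive.
#' @return Shares summing to 1, same names as the input.
#' @examples
#' skill_mix_shares(c(RN = 14653, LPN = 3060, HCA = 3039))
#' @export
skill_mix_shares <- function(budgeted_fte) {
  check_nonneg(budgeted_fte, "budgeted_fte")
  total <- sum(budgeted_fte)
  if (total <= 0) {
    abort("all budgeted FTE are zero: skill mix is undefined.",
          class = "careflow_validation_error")
  }
  budgeted_fte / total
}

#' Allocate total demand across groups by skill mix
#'
#' Splits a total FTE (or person) demand across groups in proportion to
#' the given shares, rounding to whole units with a largest-remainder
#' correction so the rounded allocation conserves the rounded total
#' exactly.
#'
#' @param total Total demand (>= 0).
#' @param shares Skill-mix shares summing to 1 (tolerance 1e-9).
#' @return Named numeric vector of whole-unit allocations summing to
#'   `round_half_up(total)`.
#' @examples
#' allocate_demand(100, c(1, 1, 1) / 3) # 34 33 33
#' @export
allocate_demand <- function(total, shares) {
  check_nonneg(total, "total")
  check_nonneg(shares, "shares")
  if (abs(sum(shares) - 1) > 1e-9) {
    abort("`shares` must sum to 1.", class = "careflow_validation_error")
  }
  exact <- total * shares
  base <- floor(exact)
  target <- round_half_up(total)
  short <- as.integer(target - sum(base))
  if (short > 0) {
    # hand out the leftover units to the largest fractional remainders;
    # ties go to the earlier group for determinism
    order_by_rem <- order(exact - base, decreasing = TRUE)
    base[order_by_rem[seq_len(short)]] <- base[order_by_rem[seq_len(short)]] + 1
  }
  base
}

#' One year's demand for new staff, by component
#'
#' Assembles the annual demand for one occupation group from its current
#' state:
#' \itemize{
#'   \item `replacement`: separations, the headcount leaving this year;
#'   \item `growth`: extra staff for service growth, the filled FTE scaled
#'     by the growth rate and converted to persons via average FTE;
#'   \item `casual_addon`: additional casual requirement, a configurable
#'     fraction of the growth component (0 in the baseline);
#'   \item `shock`: persons needed to replace FTE withdrawn by an
#'     economic-recovery shock;
#'   \item `vacancy_gap`: persons needed to pull the vacancy rate back
#'     down to the target, net of demand already claimed by `carryover`
#'     (so unfilled positions are not double-counted);
#'   \item `carryover`: last year's unmet deficit, carried forward
#'     undiminished.
#' }
#' Components are returned unrounded; the projection rounds person counts
#' at reporting time so repeated rounding cannot drift the accounting.
#'
#' @param state One-row tibble (see [initial_state()]) with `filled_fte`,
#'   `headcount`, `budgeted_fte`, `cumulative_deficit`.
#' @param params_row One row of the group parameter table (see
#'   [careflow_params()]).
#' @param growth_rate Growth rate for the year (fraction).
#' @param shock_rate Shock withdrawal rate for the year (fraction of FTE).
#' @return One-row tibble: the six components plus `total` (their sum, in
#'   persons).
#' @examples
#' st <- tibble::tibble(filled_fte = 10000, headcount = 12500,
#'                      budgeted_fte = 10000 / 0.97,
#'                      cumulative_deficit = 100)
#' pr <- load_baseline()$groups[1, ]
#' pr$avg_fte <- 0.8; pr$separation_rate <- 0.05
#' demand_step(st, pr, growth_rate = 0.02, shock_rate = 0)
#' @export
demand_step <- function(state, params_row, growth_rate, shock_rate) {
  a <- params_row$avg_fte
  if (is.na(a) || a <= 0) {
    abort("`avg_fte` must be positive to convert FTE into persons.",
          class = "careflow_config_error")
  }
  check_fraction(growth_rate, "growth_rate", -1, 1)
  check_fraction(shock_rate, "shock_rate")
  E <- state$filled_fte
  replacement <- state$headcount * params_row$separation_rate
  growth <- E * growth_rate / a
  casual_addon <- params_row$casual_requirement * growth
  shock <- shock_loss(E, shock_rate, params_row$shock_exposed_fraction) / a
  unfilled <- max(0, state$budgeted_fte - E)
  gap_fte <- unfilled - params_row$target_vacancy_rate * state$budgeted_fte -
    state$cumulative_deficit * a
  vacancy_gap <- max(0, gap_fte) / a
  carryover <- max(0, state$cumulative_deficit)
  tibble(
    replacement = replacement, growth = growth,
    casual_addon = casual_addon, shock = shock,
    vacancy_gap = vacancy_gap, carryover = carryover,
    total = replacement + growth + casual_addon + shock + vacancy_gap +
      carryover
  )
}
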