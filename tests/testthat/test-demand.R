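test_that("all-sector growth rate is the weighted mean of sector rates", {
  expect_equal(aggregate_growth_rate(c(acute = 0.02, seniors = 0.04),
                                     c(acute = 0.5, seniors = 0.5)), 0.03)
  expect_equal(aggregate_growth_rate(c(acute = 0.017), c(acute = 1)), 0.017)
  six <- setNames(rep(0.0256, 6),
                  c("acute", "community", "seniors", "public", "primary",
                    "mental"))
  w <- setNames(c(0.4, 0.2, 0.15, 0.1, 0.1, 0.05), names(six))
  expect_equal(aggregate_growth_rate(six, w), 0.0256)
  expect_error(aggregate_growth_rate(c(a = 0.1), c(b = 1)),
               class = "careflow_validation_error")
  expect_error(aggregate_growth_rate(c(a = 0.1, b = 0.2), c(a = 0.5, b = 0.6)),
               class = "careflow_validation_error")
})

test_that("aggregate growth rate lies between the sector extremes", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    rates <- setNames(runif(n, 0, 0.1), paste0("s", seq_len(n)))
    w <- runif(n); w <- setNames(w / sum(w), names(rates))
    agg <- aggregate_growth_rate(rates, w)
    expect_gte(agg, min(rates) - 1e-12)
    expect_lte(agg, max(rates) + 1e-12)
  }
})

test_that("skill-mix shares reproduce the budgeted-FTE split", {
  shares <- skill_mix_shares(c(RN = 14653, LPN = 3060, HCA = 3039))
  expect_equal(round(shares[["RN"]], 3), 0.706)
  expect_equal(round(shares[["LPN"]], 3), 0.147)
  expect_equal(shares[["HCA"]], 3039 / (14653 + 3060 + 3039))
  expect_equal(sum(shares), 1)
  expect_equal(unname(skill_mix_shares(c(1, 0, 0))), c(1, 0, 0))
  expect_equal(unname(skill_mix_shares(c(10, 10, 10))), rep(1 / 3, 3))
  expect_error(skill_mix_shares(c(0, 0, 0)),
               class = "careflow_validation_error")
})

# brute-force largest-remainder oracle: over every integer allocation that
# conserves the rounded total, pick the one closest to the exact split
# (ties to earlier groups)
lr_oracle <- function(total, shares) {
  target <- floor(total + 0.5)
  exact <- total * shares
  base <- floor(exact)
  extra <- target - sum(base)
  combos <- utils::combn(length(shares), extra, simplify = FALSE)
  best <- NULL
  best_err <- Inf
  for (cb in combos) {
    alloc <- base
    alloc[cb] <- alloc[cb] + 1
    err <- sum((alloc - exact)^2)
    if (err < best_err - 1e-12) {
      best <- alloc
      best_err <- err
    }
  }
  best
}

test_that("allocate_demand matches the largest-remainder oracle", {
  expect_equal(unname(allocate_demand(1000, c(0.706, 0.147, 0.147))),
               c(706, 147, 147))
  expect_equal(unname(allocate_demand(123, c(1, 0, 0))), c(123, 0, 0))
  expect_equal(unname(allocate_demand(100, rep(1 / 3, 3))), c(34, 33, 33))
  expect_equal(unname(allocate_demand(100, rep(1 / 3, 3))),
               lr_oracle(100, rep(1 / 3, 3)))
  set.seed(7)
  for (i in 1:20) {
    shares <- runif(3); shares <- shares / sum(shares)
    total <- runif(1, 0, 5000)
    alloc <- unname(allocate_demand(total, shares))
    expect_equal(sum(alloc), round_half_up(total)) # conservation
    expect_equal(alloc, lr_oracle(total, shares))
  }
  expect_error(allocate_demand(-5, c(1, 0, 0)),
               class = "careflow_validation_error")
})

test_that("demand components follow the hand-unrolled arithmetic", {
  pr <- load_baseline()$groups[1, ]
  pr$avg_fte <- 0.8
  pr$separation_rate <- 0.05
  pr$casual_requirement <- 0
  st <- tibble::tibble(filled_fte = 10000, headcount = 12500,
                       budgeted_fte = 10000 / 0.97,
                       cumulative_deficit = 100)
  d <- demand_step(st, pr, growth_rate = 0.02, shock_rate = 0)
  expect_equal(d$replacement, 625)   # 12500 x 0.05
  expect_equal(d$growth, 250)        # 10000 x 0.02 / 0.8
  expect_equal(d$carryover, 100)
  expect_equal(d$vacancy_gap, 0)     # at target once carryover is netted out
  expect_equal(d$total, 975)
  expect_equal(d$total, d$replacement + d$growth + d$casual_addon +
                 d$shock + d$vacancy_gap + d$carryover)
})

test_that("demand is zero for an empty system and at steady state", {
  pr <- load_baseline()$groups[1, ]
  empty <- tibble::tibble(filled_fte = 0, headcount = 0, budgeted_fte = 0,
                          cumulative_deficit = 40)
  d <- demand_step(empty, pr, growth_rate = 0.02, shock_rate = 0.0663)
  expect_equal(d$total, d$carryover)
  expect_equal(d$carryover, 40)
  pr0 <- pr
  pr0$separation_rate <- 0
  steady <- tibble::tibble(filled_fte = 1000, headcount = 1000 / pr$avg_fte,
                           budgeted_fte = 1000 / (1 - pr$target_vacancy_rate),
                           cumulative_deficit = 0)
  expect_equal(demand_step(steady, pr0, 0, 0)$total, 0)
})

test_that("demand is monotone in turnover, growth, shock and carryover", {
  pr <- load_baseline()$groups[1, ]
  st <- function(carry) {
    tibble::tibble(filled_fte = 10000, headcount = 10000 / pr$avg_fte,
                   budgeted_fte = 10000 / (1 - pr$target_vacancy_rate),
                   cumulative_deficit = carry)
  }
  total <- function(phi = 0.05, dpop = 0.02, eps = 0, carry = 0) {
    p <- pr; p$separation_rate <- phi
    demand_step(st(carry), p, dpop, eps)$total
  }
  grid <- seq(0, 0.2, by = 0.04)
  expect_true(all(diff(sapply(grid, function(v) total(phi = v))) >= 0))
  expect_true(all(diff(sapply(grid, function(v) total(dpop = v))) >= 0))
  expect_true(all(diff(sapply(grid, function(v) total(eps = v))) >= 0))
  expect_true(all(diff(sapply(0:5 * 100,
                              function(v) total(carry = v))) >= 0))
})

test_that("zero average FTE is rejected when converting to persons", {
  pr <- load_baseline()$groups[1, ]
  pr$avg_fte <- NA_real_
  st <- tibble::tibble(filled_fte = 10, headcount = 10, budgeted_fte = 10,
                       cumulative_deficit = 0)
  expect_error(demand_step(st, pr, 0.02, 0), class = "careflow_config_error")
})
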