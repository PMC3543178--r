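# Shared fixtures and a test-only, independently written recursion used as
# the oracle for projection equivalence. The oracle shares no code with the
# package's step()/project() path.

toy_params <- function(rn_sep = 0.1, growth_rate = 0, shock = 0,
                       graduates = 0, retention = 1, avg_fte = 1,
                       target_vac = 0, years = 2010:2012,
                       mirror_hca = TRUE, gamma = 0, exposed = 1) {
  groups <- tibble::tibble(
    group = c("RN", "LPN", "HCA"),
    budgeted_fte = c(1000, 500, 300),
    avg_fte = avg_fte,
    separation_rate = c(rn_sep, rn_sep, rn_sep),
    retention_rate = c(retention, retention, if (mirror_hca) NA else retention),
    graduates_per_year = c(graduates, graduates,
                           if (mirror_hca) NA else graduates),
    target_vacancy_rate = target_vac,
    casual_requirement = gamma,
    casual_active_fraction = 0.526,
    shock_exposed_fraction = exposed,
    supply_rule = c("pipeline", "pipeline",
                    if (mirror_hca) "mirror_demand" else "pipeline"),
    supply_override = NA_real_
  )
  growth <- tibble::tibble(year = years, rate = growth_rate)
  shock_tbl <- tibble::tibble(year = years, rate = shock)
  careflow_params(groups, growth, shock_tbl)
}

# independent plain-arithmetic recursion (test-only oracle)
oracle_project <- function(params, years) {
  rhu <- function(x) floor(x + 0.5)
  g <- params$groups
  out <- list()
  state <- list()
  for (i in seq_len(nrow(g))) {
    state[[g$group[i]]] <- list(
      E = g$budgeted_fte[i] * (1 - g$target_vacancy_rate[i]),
      B = g$budgeted_fte[i], carry = 0)
  }
  for (yr in years) {
    dpop <- params$growth$rate[params$growth$year == yr]
    eps <- params$shock$rate[params$shock$year == yr]
    for (i in seq_len(nrow(g))) {
      nm <- g$group[i]; s <- state[[nm]]
      a <- g$avg_fte[i]
      H <- s$E / a
      rep_ <- H * g$separation_rate[i]
      grow <- s$E * dpop / a
      shock_fte <- s$E * eps * g$shock_exposed_fraction[i]
      unfilled <- max(0, s$B - s$E)
      gap <- max(0, unfilled - g$target_vacancy_rate[i] * s$B -
                   s$carry * a) / a
      dem <- rep_ + grow + g$casual_requirement[i] * grow +
        shock_fte / a + gap + s$carry
      sup <- if (g$supply_rule[i] == "mirror_demand") dem else
        rhu(g$graduates_per_year[i] * g$retention_rate[i])
      hires <- max(0, min(sup, dem))
      E2 <- max(0, s$E + (hires - rep_) * a - shock_fte)
      B2 <- s$B * (1 + dpop)
      out[[length(out) + 1]] <- data.frame(
        group = nm, year = yr, demand = dem, supply = sup,
        surplus_deficit = sup - dem, filled_fte = E2, budgeted_fte = B2,
        cumulative_deficit = max(0, dem - sup))
      state[[nm]] <- list(E = E2, B = B2, carry = max(0, dem - sup))
    }
  }
  do.call(rbind, out)
}

# calibration-mode baseline run replaying the published table's streams
calibration_run <- function(params = load_baseline()) {
  ref <- reference_projection()
  project(params,
          demand_stream = ref[!is.na(ref$demand),
                              c("group", "year", "demand")],
          supply_stream = ref[!is.na(ref$supply),
                              c("group", "year", "supply")])
}

# the CSV presentation table, for comparing against a parsed round trip
render_csv_for_test <- function(run) render_table(run, "csv")
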