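#' Tidy a projection run
#'
#' Returns the run's rows as a tibble: one row per group per year, with
#' demand, supply, surplus/deficit, vacancy rate, percentage of graduates
#' hired, and the demand-component breakdown. Person counts are kept at
#' full precision by default; `rounded = TRUE` applies the reporting
#' convention (whole persons, whole percents, deficit recomputed from the
#' rounded columns so the identity supply - demand still holds).
#'
#' @param x A `careflow_run`.
#' @param rounded Round person counts and percentages for presentation.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy careflow_run
#' @export
tidy.careflow_run <- function(x, rounded = FALSE, ...) {
  rows <- x$rows
  if (!rounded) return(rows)
  rows %>%
    mutate(demand = round_half_up(.data$demand),
           supply = round_half_up(.data$supply),
           surplus_deficit = .data$supply - .data$demand,
           fte_vacancy_rate = round_half_up(100 * .data$fte_vacancy_rate) / 100,
           pct_graduates_hired =
             round_half_up(100 * .data$pct_graduates_hired) / 100)
}

#' Summarise a projection run per group
#'
#' One row per group: the end-year balance, cumulative deficit (the
#' shortfall carried out of the final year; deficits accumulate through
#' carryover, so this is the whole-horizon figure), cumulative surplus
#' (sum of the positive yearly surpluses), end-year vacancy rate, and the
#' number of years in deficit while hiring the full graduate stream
#' (`cap_bound_years` — years where more graduates would have helped).
#'
#' @param x A `careflow_run`.
#' @param ... Unused.
#' @return A tibble with one row per group.
#' @method glance careflow_run
#' @export
glance.careflow_run <- function(x, ...) {
  rows <- x$rows
  if (!nrow(rows)) {
    return(tibble(group = character(), end_year = integer(),
                  end_surplus_deficit = double(),
                  cumulative_deficit = double(),
                  cumulative_surplus = double(),
                  end_vacancy_rate = double(), cap_bound_years = integer()))
  }
  rows %>%
    group_by(.data$group) %>%
    summarise(
      end_year = max(.data$year),
      end_surplus_deficit = .data$surplus_deficit[which.max(.data$year)],
      cumulative_deficit = max(0, -.data$surplus_deficit[which.max(.data$year)]),
      cumulative_surplus = sum(pmax(.data$surplus_deficit, 0)),
      end_vacancy_rate = .data$fte_vacancy_rate[which.max(.data$year)],
      cap_bound_years = sum(.data$supply_capped & .data$surplus_deficit < 0),
      .groups = "drop") %>%
    arrange(match(.data$group, occupation_groups()))
}

#' Headline summary of a projection run
#'
#' Text summary in the style of the planning headlines ("a deficit which
#' grows to N over the horizon", "vacancy rate growing to X%"): cumulative
#' deficits or surpluses per group, end-year vacancy rates, and the years
#' in which the graduate-supply cap binds. Every number is recomputed from
#' the run's rows.
#'
#' @param run A `careflow_run`.
#' @return Character vector of summary lines.
#' @export
summarize_run <- function(run) {
  g <- glance(run)
  if (!nrow(g)) return("empty run: no years projected")
  lines <- sprintf("scenario '%s', %d-%d", run$scenario,
                   min(run$horizon), max(run$horizon))
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    lines <- c(lines, if (r$cumulative_deficit > 0) {
      sprintf("%s: cumulative deficit of %d by %d; vacancy rate %d%%%s",
              r$group, round_half_up(r$cumulative_deficit), r$end_year,
              round_half_up(100 * r$end_vacancy_rate),
              if (r$cap_bound_years > 0)
                sprintf(" (graduate supply cap binding in %d year%s)",
                        r$cap_bound_years,
                        if (r$cap_bound_years == 1) "" else "s")
              else "")
    } else {
      sprintf("%s: no shortfall projected; cumulative surplus of %d by %d",
              r$group, round_half_up(r$cumulative_surplus), r$end_year)
    })
  }
  lines
}

#' @export
summary.careflow_run <- function(object, ...) {
  lines <- summarize_run(object)
  cat(lines, sep = "\n")
  invisible(lines)
}

# presentation table -------------------------------------------------------

presentation_rows <- function(run) {
  tidy(run, rounded = TRUE) %>%
    mutate(fte_vacancy_pct = round_half_up(100 * .data$fte_vacancy_rate),
           pct_graduates_hired_pct =
             round_half_up(100 * .data$pct_graduates_hired))
}

paren <- function(x) {
  ifelse(x < 0, sprintf("(%d)", abs(x)), sprintf("%d", x))
}

#' Render a projection run as a table, CSV or JSON
#'
#' Text mode renders one block per group with the planning-table column
#' set — Year, Demand, Supply, Supply Surplus/Deficit, FTE Vacancy Rate,
#' % of Graduates Hired — with deficits in parentheses and whole-percent
#' rates; mirror-demand groups (HCA) render the demand column only. CSV
#' mode writes one RFC 4180 file with the rounded presentation columns
#' plus full-precision parallel columns. JSON mode serialises the rows
#' losslessly.
#'
#' @param run A `careflow_run`.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @param path Optional output path; written when given.
#' @return Text lines (character vector), the CSV tibble, or the JSON
#'   string, invisibly when `path` is given.
#' @export
render_table <- function(run, format = c("text", "csv", "json"),
                         path = NULL) {
  format <- match.arg(format)
  out <- switch(format,
                text = render_text(run),
                csv = render_csv(run),
                json = render_json(run))
  if (!is.null(path)) {
    if (format == "csv") {
      readr::write_csv(out, path, na = "")
    } else {
      writeLines(as.character(out), path)
    }
    return(invisible(out))
  }
  out
}

render_text <- function(run) {
  rows <- presentation_rows(run)
  mirror <- run$params$groups$group[run$params$groups$supply_rule ==
                                      "mirror_demand"]
  lines <- character()
  for (g in intersect(occupation_groups(), unique(run$params$groups$group))) {
    sub <- rows[rows$group == g, ]
    if (g %in% mirror) {
      header <- c("Year", sprintf("Total %s Demand", g))
      body <- if (nrow(sub)) sprintf("%-6d%s", sub$year,
                                     format(sub$demand, width = 8)) else
        character()
    } else {
      header <- c("Year", sprintf("%s Demand", g), sprintf("%s Supply", g),
                  "Supply Surplus/Deficit", "FTE Vacancy Rate",
                  "% of Graduates Hired")
      body <- if (nrow(sub)) {
        sprintf("%-6d%10s%10s%12s%8s%8s", sub$year,
                format(sub$demand), format(sub$supply),
                paren(sub$surplus_deficit),
                sprintf("%d%%", sub$fte_vacancy_pct),
                ifelse(is.na(sub$pct_graduates_hired_pct), "",
                       sprintf("%d%%", sub$pct_graduates_hired_pct)))
      } else character()
    }
    lines <- c(lines, paste(header, collapse = "  "), body, "")
  }
  lines
}

render_csv <- function(run) {
  presentation_rows(run) %>%
    select("group", "year", "demand", "supply", "surplus_deficit",
           "fte_vacancy_pct", "pct_graduates_hired_pct") %>%
    left_join(
      run$rows %>%
        select("group", "year", demand_exact = "demand",
               supply_exact = "supply",
               surplus_deficit_exact = "surplus_deficit",
               "fte_vacancy_rate", "pct_graduates_hired"),
      by = c("group", "year"))
}

render_json <- function(run) {
  jsonlite::toJSON(
    list(scenario = run$scenario, horizon = run$horizon, rows = run$rows),
    dataframe = "rows", digits = NA, na = "null", auto_unbox = TRUE)
}

#' Parse a projection table back from serialized form
#'
#' Inverse of [render_table()] for the CSV and JSON formats, used for
#' round-trip checks and for feeding saved runs back into reports.
#'
#' @param path File written by [render_table()].
#' @return CSV: the presentation tibble; JSON: a list with `scenario`,
#'   `horizon` and `rows`.
#' @export
read_projection_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(group = "c", year = "i",
                                          .default = "d"))
}

#' @rdname read_projection_csv
#' @export
read_projection_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$rows <- as_tibble(raw$rows)
  raw$horizon <- as.integer(raw$horizon)
  raw
}

#' Plot demand, supply and balance trajectories
#'
#' Mirrors the planning dashboard's three graphs: per-group demand and
#' supply lines over the horizon, with the yearly surplus/deficit as a
#' column underlay.
#'
#' @param object A `careflow_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot careflow_run
#' @export
autoplot.careflow_run <- function(object, ...) {
  rows <- tidy(object, rounded = TRUE)
  streams <- rows %>%
    select("group", "year", "demand", "supply") %>%
    tidyr::pivot_longer(c("demand", "supply"), names_to = "stream",
                        values_to = "persons")
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$surplus_deficit),
                      fill = "grey80") +
    ggplot2::geom_line(data = streams,
                       ggplot2::aes(y = .data$persons,
                                    colour = .data$stream)) +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "persons",
                  title = sprintf("Care-workforce projection: %s",
                                  object$scenario),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Reference baseline projection table
#'
#' The published baseline-scenario projection of the Alberta
#' care-workforce planning exercise, 2010--2020, as printed (whole
#' persons, whole percents): RN and LPN demand, supply, surplus/deficit
#' and percentage of graduates hired, RN FTE vacancy rate, and total HCA
#' demand. Shipped as a plain-text fixture; its demand and supply columns
#' are the canonical input for [project()]'s calibration mode, and its
#' arithmetic columns are the ground truth the engine's accounting is
#' checked against.
#'
#' @return Tibble: `year`, `group`, `demand`, `supply`,
#'   `surplus_deficit`, `fte_vacancy_rate`, `pct_graduates_hired`
#'   (fractions; `NA` where the published table has no such column).
#' @examples
#' ref <- reference_projection()
#' subset(ref, group == "RN" & year == 2012)
#' @export
reference_projection <- function() {
  path <- system.file("extdata", "reference_projection.csv",
                      package = "careflow", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(year = "i", group = "c",
                                          .default = "d"))
}
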