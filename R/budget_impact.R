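#' Per-member-per-month (PMPM) amount
#'
#' The standard payer budgeting unit: an annual plan-level amount divided by
#' member-months.
#'
#' @param annual_amount Annual plan-level amount (USD).
#' @param members Number of plan members (> 0).
#' @return USD per member per month (unrounded).
#' @examples
#' pmpm(14046.77 * 212200, 5e6)  # ~49.68
#' @export
pmpm <- function(annual_amount, members) {
  if (any(members <= 0)) abort("members must be > 0")
  annual_amount / (members * 12)
}

#' PMPM series: without, with, and impact views
#'
#' "Without" applies the unenrolled per-patient cost to the whole eligible
#' population in every year (hence identical yearly columns); "with" mixes
#' enrolled patients at the enrolled cost with the remainder at the
#' unenrolled cost; "impact" is their difference, which collapses to the
#' per-patient cost difference on enrolled patients.
#'
#' @param unenrolled,enrolled Cost breakdowns from [baseline_breakdown()] /
#'   [enrolled_breakdown()].
#' @param counts Population tibble from [enrolled_counts()] or
#'   [population_table()] (needs `year`, `enrolled`, `unenrolled`).
#' @param plan_size Number of plan members.
#' @return Long tibble with columns `view` (`without`/`with`/`impact`),
#'   `category` (the cost categories plus `"total"`), `year`, `pmpm`
#'   (unrounded USD per member-month).
#' @export
pmpm_table <- function(unenrolled, enrolled, counts, plan_size) {
  eligible <- counts$enrolled + counts$unenrolled
  cats <- unenrolled$category
  per_year <- purrr::map(seq_len(nrow(counts)), function(i) {
    without <- pmpm(unenrolled$cost * eligible[i], plan_size)
    with_ <- pmpm(unenrolled$cost * counts$unenrolled[i] +
                    enrolled$cost * counts$enrolled[i], plan_size)
    tibble(
      view = rep(c("without", "with", "impact"), each = length(cats) + 1),
      category = rep(c(cats, "total"), times = 3),
      year = counts$year[i],
      pmpm = c(without, sum(without), with_, sum(with_),
               with_ - without, sum(with_) - sum(without))
    )
  })
  dplyr::bind_rows(per_year)
}

#' Across-year average PMPM
#'
#' Unweighted arithmetic mean of the yearly PMPM values, per view and
#' category (the convention of multi-year budget-impact tables).
#'
#' @param pmpm_tbl Output of [pmpm_table()].
#' @return Tibble with columns `view`, `category`, `average`.
#' @export
pmpm_average <- function(pmpm_tbl) {
  dplyr::summarise(pmpm_tbl, average = mean(.data$pmpm),
                   .by = c("view", "category"))
}

#' Wide PMPM layout (years as columns, plus average)
#'
#' @inheritParams pmpm_average
#' @return Tibble with `view`, `category`, `year_1` .. `year_H`, `average`.
#' @export
pmpm_wide <- function(pmpm_tbl) {
  wide <- tidyr::pivot_wider(pmpm_tbl, names_from = "year",
                             values_from = "pmpm", names_prefix = "year_")
  dplyr::left_join(wide, pmpm_average(pmpm_tbl), by = c("view", "category"))
}

#' Plan-level expenditures for enrolled patients and horizon net savings
#'
#' Expenditure is the per-patient enrolled cost times the enrolled count,
#' per year and category, exactly.  Horizon net savings sum, over years, the
#' per-patient cost difference on enrolled patients.
#'
#' @inheritParams pmpm_table
#' @return Tibble with `year`, `category`, `expenditure` (USD), carrying the
#'   scalar attribute `horizon_net_savings` (USD saved over the horizon;
#'   positive means the intervention saves money).
#' @export
aggregate_expenditures <- function(unenrolled, enrolled, counts) {
  tbl <- tidyr::crossing(year = counts$year, category = enrolled$category) |>
    dplyr::left_join(dplyr::select(enrolled, "category", "cost"), by = "category") |>
    dplyr::left_join(dplyr::select(counts, "year", "enrolled"), by = "year") |>
    dplyr::mutate(expenditure = .data$cost * .data$enrolled) |>
    dplyr::select("year", "category", "expenditure")
  savings <- sum((breakdown_total(unenrolled) - breakdown_total(enrolled)) *
                   counts$enrolled)
  attr(tbl, "horizon_net_savings") <- savings
  tbl
}

#' Run the full budget-impact analysis for one payer
#'
#' Orchestrates the pipeline: eligible population and uptake, per-patient
#' breakdowns for both arms, PMPM tables for the three views, plan-level
#' expenditures and horizon net savings.
#'
#' @param inputs A [payer_inputs()] object.
#' @param readmission_policy Passed to the cost engine.
#' @return An object of class `bia_result` with elements `inputs`,
#'   `population`, `unenrolled`, `enrolled`, `pmpm`, `expenditures`,
#'   `per_patient_saving` (USD per enrolled patient-year).  Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' res <- run_bia(bia_config("commercial_replication"))
#' glance(res)
#' @export
run_bia <- function(inputs, readmission_policy = "subset") {
  pop <- population_table(inputs)
  unen <- baseline_breakdown(inputs, readmission_policy)
  enr <- enrolled_breakdown(inputs, readmission_policy = readmission_policy)
  structure(
    list(
      inputs = inputs,
      population = pop,
      unenrolled = unen,
      enrolled = enr,
      pmpm = pmpm_table(unen, enr, pop, inputs$plan_size),
      expenditures = aggregate_expenditures(unen, enr, pop),
      per_patient_saving = breakdown_total(unen) - breakdown_total(enr)
    ),
    class = "bia_result"
  )
}

#' @export
print.bia_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<bia_result: %s payer>\n", x$inputs$label))
  cat(sprintf("  eligible patients        %s\n",
              format(round_half_up(g$eligible), big.mark = ",")))
  cat(sprintf("  per-patient saving       $%s / year\n",
              render_currency(g$per_patient_saving, "dollars")))
  cat(sprintf("  average PMPM impact      %s\n",
              render_currency(g$avg_pmpm_impact, "pmpm")))
  cat(sprintf("  horizon net savings      $%sM over %d years\n",
              render_currency(g$horizon_net_savings, "millions"),
              length(x$inputs$uptake)))
  invisible(x)
}

#' @rdname run_bia
#' @param x A `bia_result`.
#' @param ... Unused.
#' @method tidy bia_result
#' @export
tidy.bia_result <- function(x, ...) x$pmpm

#' @rdname run_bia
#' @method glance bia_result
#' @export
glance.bia_result <- function(x, ...) {
  avg <- pmpm_average(x$pmpm)
  tibble(
    payer = x$inputs$label,
    eligible = eligible_patients(x$inputs),
    unenrolled_total = breakdown_total(x$unenrolled),
    enrolled_total = breakdown_total(x$enrolled),
    per_patient_saving = x$per_patient_saving,
    avg_pmpm_impact = avg$average[avg$view == "impact" & avg$category == "total"],
    horizon_net_savings = attr(x$expenditures, "horizon_net_savings")
  )
}

#' @rdname run_bia
#' @param object A `bia_result`.
#' @method autoplot bia_result
#' @export
autoplot.bia_result <- function(object, ...) {
  dat <- dplyr::filter(object$pmpm, .data$view == "impact",
                       .data$category != "total")
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$year), y = .data$pmpm,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "Year", y = "PMPM budget impact (USD)", fill = "Category",
      title = sprintf("PMPM budget impact, %s payer", object$inputs$label)
    ) +
    ggplot2::theme_minimal()
}
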