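#' Scenario specification
#'
#' Describes an alternative-effect scenario: an adherence (PDC) shift with
#' its linked hospitalization/ED reductions, and whether the extra
#' controller medication cost from improved adherence is charged to the
#' enrolled arm.
#'
#' @param label Scenario label.
#' @param pdc_delta Additive PDC increase (fraction of days, in \[0, 1\]).
#' @param hosp_reduction,ed_reduction,saba_reduction Optional overrides of
#'   the base-case reduction fractions; `NULL` keeps the configured value.
#' @param include_controller_costs Charge the adherence-linked controller
#'   cost increase to the enrolled arm?
#' @return A `scenario_spec` object (list).
#' @seealso [bia_scenarios()] for the four shipped adherence scenarios.
#' @export
scenario_spec <- function(label, pdc_delta = 0, hosp_reduction = NULL,
                          ed_reduction = NULL, saba_reduction = NULL,
                          include_controller_costs = FALSE) {
  stopifnot(pdc_delta >= 0, pdc_delta <= 1)
  for (r in compact_null(list(hosp_reduction, ed_reduction, saba_reduction))) {
    if (r < 0 || r > 1) abort("reduction fractions must lie in [0, 1]")
  }
  structure(
    list(label = label, pdc_delta = pdc_delta,
         hosp_reduction = hosp_reduction, ed_reduction = ed_reduction,
         saba_reduction = saba_reduction,
         include_controller_costs = include_controller_costs),
    class = "scenario_spec"
  )
}

#' The four shipped adherence-linked scenarios
#'
#' Scenarios 1A/1B assume a 0.10 PDC increase with linked reductions of
#' 5.20% (hospitalizations) and 1.15% (ED visits); 2A/2B triple all three
#' (0.30 PDC, 15.60%, 3.45%), treating the adherence-to-HCRU linkage as
#' exactly linear.  "A" variants charge the adherence-driven controller
#' cost; "B" variants exclude it.
#'
#' @return Named list of [scenario_spec()] objects (`1A`, `1B`, `2A`, `2B`).
#' @export
bia_scenarios <- function() {
  list(
    `1A` = scenario_spec("1A", pdc_delta = 0.10, hosp_reduction = 0.0520,
                         ed_reduction = 0.0115, include_controller_costs = TRUE),
    `1B` = scenario_spec("1B", pdc_delta = 0.10, hosp_reduction = 0.0520,
                         ed_reduction = 0.0115, include_controller_costs = FALSE),
    `2A` = scenario_spec("2A", pdc_delta = 0.30, hosp_reduction = 0.1560,
                         ed_reduction = 0.0345, include_controller_costs = TRUE),
    `2B` = scenario_spec("2B", pdc_delta = 0.30, hosp_reduction = 0.1560,
                         ed_reduction = 0.0345, include_controller_costs = FALSE)
  )
}

#' Controller cost increase from a PDC shift
#'
#' GOLD-weighted increase in annual controller cost when every group's PDC
#' rises by `pdc_delta` (clipped at 1): linear in the shift wherever no
#' group clips.
#'
#' @inheritParams annual_medical_costs
#' @param pdc_delta Additive PDC increase.
#' @return USD per patient-year (unrounded).
#' @examples
#' pdc_cost_delta(bia_config("commercial_replication"), 0.10)  # ~536.4
#' @export
pdc_cost_delta <- function(inputs, pdc_delta) {
  annual_controller_cost(inputs, pdc_delta) - annual_controller_cost(inputs, 0)
}

#' Run a scenario analysis
#'
#' Rebuilds the enrolled arm under the scenario's reductions, adds the
#' adherence-linked controller cost when requested, and aggregates to PMPM.
#' The reconciliation line is a base-case bookkeeping artifact and is
#' excluded from scenario arms.
#'
#' @inheritParams run_bia
#' @param scenario A [scenario_spec()].
#' @return A `bia_scenario` object: `scenario`, `unenrolled`, `enrolled`,
#'   `pmpm` (long, all three views), `average` (per view and category),
#'   `expenditures`.
#' @examples
#' sc <- run_scenario(bia_config("commercial_replication"), bia_scenarios()$`1A`)
#' dplyr::filter(sc$average, view == "impact", category == "controller")
#' @export
run_scenario <- function(inputs, scenario) {
  pop <- population_table(inputs)
  unen <- baseline_breakdown(inputs)
  enr <- enrolled_breakdown(inputs, scenario = scenario,
                            include_reconciliation = FALSE)
  pm <- pmpm_table(unen, enr, pop, inputs$plan_size)
  structure(
    list(scenario = scenario, unenrolled = unen, enrolled = enr,
         pmpm = pm, average = pmpm_average(pm),
         expenditures = aggregate_expenditures(unen, enr, pop)),
    class = "bia_scenario"
  )
}

#' @export
print.bia_scenario <- function(x, ...) {
  avg <- dplyr::filter(x$average, .data$view == "impact")
  cat(sprintf("<bia_scenario: %s>\n", x$scenario$label))
  for (i in seq_len(nrow(avg))) {
    cat(sprintf("  %-18s %s PMPM (3-yr average)\n", avg$category[i],
                render_currency(avg$average[i], "pmpm")))
  }
  invisible(x)
}

scale_parameter <- function(inputs, parameter, change) {
  f <- 1 + change
  if (parameter == "medical_unit_costs") {
    inputs$unit_costs[["hospitalization"]] <- inputs$unit_costs[["hospitalization"]] * f
    inputs$unit_costs[["ed_visit"]] <- inputs$unit_costs[["ed_visit"]] * f
    if (!is.null(inputs$baseline_overrides)) {
      inputs$baseline_overrides <- inputs$baseline_overrides * f
    }
  } else if (parameter == "hcru_reductions") {
    inputs$effects$hosp_reduction <- min(inputs$effects$hosp_reduction * f, 1)
    inputs$effects$ed_reduction <- min(inputs$effects$ed_reduction * f, 1)
  } else if (parameter == "saba_reduction") {
    inputs$effects$saba_reduction <- min(inputs$effects$saba_reduction * f, 1)
  } else {
    abort(sprintf("unknown sensitivity parameter: %s", parameter))
  }
  inputs
}

#' One-way sensitivity sweep
#'
#' Recomputes the per-patient annual saving (unenrolled minus enrolled
#' total, including any configured reconciliation line) with one parameter
#' scaled by (1 + change).  `medical_unit_costs` scales the hospitalization
#' and ED unit costs (and their baseline overrides); `hcru_reductions`
#' scales both effect fractions; either moves the saving identically
#' because both enter it bilinearly.  `saba_reduction` scales the SABA
#' effect.
#'
#' @inheritParams run_bia
#' @param parameter One of `"medical_unit_costs"`, `"hcru_reductions"`,
#'   `"saba_reduction"`.
#' @param relative_changes Relative changes to apply (e.g. `c(-0.25, -0.1,
#'   0.1, 0.25)`); 0 reproduces the base-case saving.
#' @return Tibble of class `bia_sensitivity`: `parameter`, `change`,
#'   `saving` (USD per enrolled patient-year, unrounded).
#' @export
one_way_sensitivity <- function(inputs, parameter,
                                relative_changes = c(-0.25, -0.10, 0, 0.10, 0.25)) {
  parameter <- match.arg(parameter,
                         c("medical_unit_costs", "hcru_reductions", "saba_reduction"))
  savings <- vapply(relative_changes, function(ch) {
    mod <- scale_parameter(inputs, parameter, ch)
    breakdown_total(baseline_breakdown(mod)) -
      breakdown_total(enrolled_breakdown(mod))
  }, numeric(1))
  structure(
    tibble(parameter = parameter, change = as.numeric(relative_changes),
           saving = savings),
    class = c("bia_sensitivity", class(tibble()))
  )
}

#' @rdname one_way_sensitivity
#' @param object A `bia_sensitivity` tibble.
#' @param ... Unused.
#' @method autoplot bia_sensitivity
#' @export
autoplot.bia_sensitivity <- function(object, ...) {
  base <- object$saving[object$change == 0]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$change, y = .data$saving)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    {if (length(base)) ggplot2::geom_hline(yintercept = base, linetype = 2)} +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%+.0f%%", 100 * x)) +
    ggplot2::labs(x = "Relative change in parameter",
                  y = "Per-patient annual saving (USD)",
                  title = unique(object$parameter)) +
    ggplot2::theme_minimal()
}

bisect <- function(f, lo, hi, tol = 1e-12, max_iter = 200) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) abort("bisection bracket does not change sign")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else hi <- mid
  }
  (lo + hi) / 2
}

#' Break-even hospitalization reduction
#'
#' Solves for the hospitalization-reduction fraction at which the enrolled
#' and unenrolled per-patient annual totals are equal.  The model is linear
#' in the reduction, so the solution has a closed form
#' (fixed intervention costs minus ED and SABA savings, divided by the
#' baseline hospitalization cost); an independent bisection on the full
#' per-patient cost difference cross-checks it.
#'
#' @inheritParams run_bia
#' @param include_reconciliation Count the configured reconciliation line
#'   among the enrolled arm's fixed costs (default `FALSE`).
#' @return A `bia_breakeven` object: `r_star` (closed form), `r_bisect`,
#'   `residual` (per-patient cost difference at `r_star`), `in_range`
#'   (whether `r_star` lies in \[0, 1\]).
#' @examples
#' break_even_hosp_reduction(bia_config("commercial_replication"))
#' @export
break_even_hosp_reduction <- function(inputs, include_reconciliation = FALSE) {
  unen <- baseline_breakdown(inputs)
  base_hosp <- unen$cost[unen$category == "hospitalizations"]
  if (base_hosp <= 0) abort("baseline hospitalization cost must be > 0")

  diff_at <- function(r) {
    # raw spec, bypassing the [0,1] guard: the probe may step outside the
    # admissible range when the solution itself lies there
    probe <- structure(list(label = "breakeven", pdc_delta = 0,
                            hosp_reduction = r, ed_reduction = NULL,
                            saba_reduction = NULL,
                            include_controller_costs = FALSE),
                       class = "scenario_spec")
    enr <- enrolled_breakdown(inputs, scenario = probe,
                              include_reconciliation = include_reconciliation)
    breakdown_total(enr) - breakdown_total(unen)
  }

  ed_saving <- unen$cost[unen$category == "ed_visits"] * inputs$effects$ed_reduction
  saba_saving <- unen$cost[unen$category == "saba"] * inputs$effects$saba_reduction
  fixed <- inputs$effects$subscription_cost +
    (if (isTRUE(inputs$effects$bill_rtm_for_all_enrolled)) annual_rtm_cost(inputs) else 0) +
    (if (include_reconciliation) inputs$settings$reconciliation_line else 0)
  r_star <- (fixed - ed_saving - saba_saving) / base_hosp

  in_range <- r_star >= 0 && r_star <= 1
  r_bisect <- if (in_range) bisect(diff_at, 0, 1) else {
    bisect(diff_at, min(r_star, 0) - 1, max(r_star, 1) + 1)
  }
  structure(
    list(r_star = r_star, r_bisect = r_bisect,
         residual = diff_at(r_star), in_range = in_range),
    class = "bia_breakeven"
  )
}

#' @export
print.bia_breakeven <- function(x, ...) {
  cat(sprintf("<bia_breakeven> hospitalization reduction %.5f%%%s\n",
              100 * x$r_star, if (x$in_range) "" else " (outside [0, 1])"))
  cat(sprintf("  residual cost difference %.2e; bisection agrees to %.1e\n",
              x$residual, abs(x$r_star - x$r_bisect)))
  invisible(x)
}

#' Budget-neutral PDC increase
#'
#' Solves for the adherence (PDC) increase, in percentage points, at which
#' the intervention's fixed costs are exactly offset, given a linear
#' adherence-to-HCRU linkage (reduction fractions per 0.10 of PDC).
#' Optionally charges the adherence-driven controller cost.
#'
#' @inheritParams run_bia
#' @param hosp_link,ed_link Reduction fractions per `per_pdc` of PDC
#'   increase (defaults: 5.20% and 1.15% per 0.10).
#' @param per_pdc PDC increment the linkage is quoted per (default 0.10).
#' @param include_controller_costs Charge the adherence-linked controller
#'   cost increase to the enrolled arm?
#' @return PDC increase in percentage points (100 x fraction of days).
#' @export
budget_neutral_pdc <- function(inputs, hosp_link = 0.052, ed_link = 0.0115,
                               per_pdc = 0.10, include_controller_costs = FALSE) {
  if (hosp_link <= 0 || ed_link <= 0) {
    abort("linkage reductions must be > 0 for a budget-neutral solve")
  }
  unen <- baseline_breakdown(inputs)
  base_hosp <- unen$cost[unen$category == "hospitalizations"]
  base_ed <- unen$cost[unen$category == "ed_visits"]
  saba_saving <- unen$cost[unen$category == "saba"] * inputs$effects$saba_reduction
  fixed <- inputs$effects$subscription_cost +
    (if (isTRUE(inputs$effects$bill_rtm_for_all_enrolled)) annual_rtm_cost(inputs) else 0) -
    saba_saving

  slope <- (base_hosp * hosp_link + base_ed * ed_link) / per_pdc
  if (include_controller_costs) {
    # marginal controller cost per unit of PDC (linear away from clipping)
    slope <- slope - pdc_cost_delta(inputs, 1e-6) / 1e-6
  }
  if (slope <= 0) abort("savings do not increase with PDC under this linkage")
  100 * fixed / slope
}
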