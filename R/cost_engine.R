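#' GOLD-share-weighted mean
#'
#' The model's aggregation rule: any per-group quantity (an event rate, a
#' cost) is averaged over GOLD 2017 ABCD groups with the group shares as
#' weights.
#'
#' @param values Numeric, one value per GOLD group (A--D order, or named).
#' @param gold_shares Named fractions over A--D summing to 1.
#' @return Scalar weighted mean.
#' @examples
#' shares <- c(A = 0.534, B = 0.267, C = 0.082, D = 0.117)
#' gold_weighted_mean(c(0.36, 0.46, 0.56, 0.56), shares)  # 0.4265
#' @export
gold_weighted_mean <- function(values, gold_shares) {
  shares <- unlist(gold_shares)[gold_groups]
  values <- unlist(values)
  if (!is.null(names(values))) values <- values[gold_groups]
  if (length(values) != 4) abort("need one value per GOLD group")
  sum(shares * values)
}

# effective per-event unit costs; replication overrides are translated into
# implied unit costs (override / weighted rate) so that per-group breakdowns
# stay well defined and their weighted mean reproduces the override exactly
effective_unit_costs <- function(inputs, readmission_policy) {
  hosp_rate <- inputs$hcru$hospitalizations
  if (readmission_policy == "separately_costed") {
    hosp_rate <- hosp_rate + inputs$hcru$readmissions
  }
  uc <- c(
    office = inputs$unit_costs[["office_outpatient_visit"]],
    ed = inputs$unit_costs[["ed_visit"]],
    hosp = inputs$unit_costs[["hospitalization"]]
  )
  ov <- inputs$baseline_overrides
  if (!is.null(ov)) {
    if ("hospitalizations" %in% names(ov)) {
      w <- gold_weighted_mean(hosp_rate, inputs$gold_shares)
      if (w <= 0) abort("cannot override hospitalization cost: weighted rate is 0")
      uc[["hosp"]] <- ov[["hospitalizations"]] / w
    }
    if ("ed_visits" %in% names(ov)) {
      w <- gold_weighted_mean(inputs$hcru$ed_visits, inputs$gold_shares)
      if (w <= 0) abort("cannot override ED cost: weighted rate is 0")
      uc[["ed"]] <- ov[["ed_visits"]] / w
    }
  }
  list(unit = uc, hosp_rate = hosp_rate)
}

# USD per rescue-inhaler puff; the replication override is converted to an
# implied per-puff price against the expected annual puffs
saba_per_puff <- function(inputs) {
  weeks <- inputs$settings$days_per_year / 7
  w_puffs <- gold_weighted_mean(inputs$saba$weekly_puffs, inputs$gold_shares)
  ov <- inputs$saba$annual_cost_override
  if (!is.null(ov)) {
    if (w_puffs * weeks <= 0) return(list(per_puff = 0, flat = ov))
    return(list(per_puff = ov / (w_puffs * weeks), flat = NULL))
  }
  if (nrow(inputs$saba$wac_prices) == 0) {
    abort("no WAC prices and no SABA annual cost override supplied")
  }
  list(per_puff = mean(inputs$saba$wac_prices$price) /
         inputs$saba$actuations_per_canister, flat = NULL)
}

#' Annual per-patient medical costs (GOLD-weighted)
#'
#' Weighted event rates times unit costs for the three medical categories.
#' Under the default `"subset"` readmission policy, readmissions are already
#' contained in the hospitalization rate and add nothing; under
#' `"separately_costed"` the weighted readmission rate is costed at the
#' hospitalization unit cost in addition.
#'
#' @param inputs A [payer_inputs()] object.
#' @param readmission_policy `"subset"` (default) or `"separately_costed"`.
#' @return Named numeric: `outpatient_office`, `ed_visits`,
#'   `hospitalizations` (USD per patient-year, unrounded).
#' @export
annual_medical_costs <- function(inputs,
                                 readmission_policy = c("subset", "separately_costed")) {
  readmission_policy <- match.arg(readmission_policy)
  eu <- effective_unit_costs(inputs, readmission_policy)
  c(
    outpatient_office = gold_weighted_mean(inputs$hcru$outpatient_visits,
                                           inputs$gold_shares) * eu$unit[["office"]],
    ed_visits = gold_weighted_mean(inputs$hcru$ed_visits, inputs$gold_shares) *
      eu$unit[["ed"]],
    hospitalizations = gold_weighted_mean(eu$hosp_rate, inputs$gold_shares) *
      eu$unit[["hosp"]]
  )
}

#' Annual per-patient rescue inhaler (SABA) cost
#'
#' Baseline SABA use proxies symptom burden.  Cost per puff is the simple
#' mean of the listed wholesale acquisition prices divided by actuations per
#' canister; annual puffs are the GOLD-weighted weekly puffs times weeks per
#' year.  A configured `annual_cost_override` short-circuits the derivation.
#'
#' @inheritParams annual_medical_costs
#' @return USD per patient-year (unrounded).
#' @export
annual_saba_cost <- function(inputs) {
  pp <- saba_per_puff(inputs)
  if (!is.null(pp$flat)) return(pp$flat)
  weeks <- inputs$settings$days_per_year / 7
  gold_weighted_mean(inputs$saba$weekly_puffs, inputs$gold_shares) * weeks * pp$per_puff
}

#' Annual per-patient controller medication cost
#'
#' Per group: the mix-weighted daily controller cost times the proportion of
#' days covered (PDC, optionally shifted by `pdc_delta` and clipped at 1)
#' times days per year; then GOLD-weighted.
#'
#' @inheritParams annual_medical_costs
#' @param pdc_delta Additive shift applied to every group's PDC (adherence
#'   scenarios); the shifted PDC is clipped to \[0, 1\].
#' @return USD per patient-year (unrounded).
#' @export
annual_controller_cost <- function(inputs, pdc_delta = 0) {
  ctrl <- inputs$controller
  daily <- vapply(gold_groups,
                  function(g) sum(ctrl$mix[[g]] * ctrl$daily_costs), numeric(1))
  pdc <- pmin(pmax(ctrl$pdc + pdc_delta, 0), 1)
  gold_weighted_mean(daily * pdc * inputs$settings$days_per_year,
                     inputs$gold_shares)
}

#' Annual per-patient remote therapeutic monitoring (RTM) cost
#'
#' Sum over the fee schedule of yearly billing frequency times fee.
#'
#' @inheritParams annual_medical_costs
#' @return USD per patient-year (unrounded).
#' @examples
#' annual_rtm_cost(bia_config("commercial_replication"))  # 654.78
#' @export
annual_rtm_cost <- function(inputs) {
  if (nrow(inputs$rtm) == 0) return(0)
  sum(inputs$rtm$annual_frequency * inputs$rtm$fee)
}

# per-GOLD-group category cost matrix (categories x groups); the GOLD-share
# weighted combination of its columns is the per-patient breakdown
category_matrix <- function(inputs, arm, scenario = NULL,
                            readmission_policy = "subset",
                            include_reconciliation = TRUE) {
  enrolled <- arm == "enrolled"
  eff <- inputs$effects
  red_h <- if (enrolled) (scenario$hosp_reduction %||% eff$hosp_reduction) else 0
  red_e <- if (enrolled) (scenario$ed_reduction %||% eff$ed_reduction) else 0
  red_s <- if (enrolled) (scenario$saba_reduction %||% eff$saba_reduction) else 0
  delta <- if (enrolled && isTRUE(scenario$include_controller_costs)) {
    scenario$pdc_delta %||% 0
  } else 0

  eu <- effective_unit_costs(inputs, readmission_policy)
  pp <- saba_per_puff(inputs)
  weeks <- inputs$settings$days_per_year / 7
  ctrl <- inputs$controller
  daily <- vapply(gold_groups,
                  function(g) sum(ctrl$mix[[g]] * ctrl$daily_costs), numeric(1))
  pdc <- pmin(pmax(ctrl$pdc + delta, 0), 1)

  saba_g <- if (!is.null(pp$flat)) rep(pp$flat, 4) else {
    inputs$saba$weekly_puffs * weeks * pp$per_puff
  }

  m <- rbind(
    subscription = rep(if (enrolled) eff$subscription_cost else 0, 4),
    hospitalizations = eu$hosp_rate * eu$unit[["hosp"]] * (1 - red_h),
    ed_visits = inputs$hcru$ed_visits * eu$unit[["ed"]] * (1 - red_e),
    outpatient_office = inputs$hcru$outpatient_visits * eu$unit[["office"]],
    rtm = rep(if (enrolled && isTRUE(eff$bill_rtm_for_all_enrolled)) {
      annual_rtm_cost(inputs)
    } else 0, 4),
    saba = saba_g * (1 - red_s),
    controller = daily * pdc * inputs$settings$days_per_year,
    reconciliation = rep(if (enrolled && include_reconciliation) {
      inputs$settings$reconciliation_line
    } else 0, 4)
  )
  colnames(m) <- gold_groups
  m
}

breakdown_from_matrix <- function(m, inputs, arm) {
  shares <- inputs$gold_shares
  tibble(arm = arm, category = rownames(m),
         cost = as.numeric(m %*% shares))
}

#' Per-patient annual cost breakdown, unenrolled (baseline) arm
#'
#' GOLD-weighted annual cost per patient by category for patients not on
#' the monitoring platform.  Subscription, RTM and reconciliation are
#' structurally zero on this arm.
#'
#' @inheritParams annual_medical_costs
#' @param by_gold If `TRUE`, return the per-GOLD-group breakdown (long
#'   tibble with `gold_group`) instead of the GOLD-weighted one.
#' @return Tibble with columns `arm`, `category`, `cost` (USD per
#'   patient-year, unrounded), categories in fixed order; or the per-group
#'   long form when `by_gold = TRUE`.
#' @examples
#' b <- baseline_breakdown(bia_config("commercial_replication"))
#' sum(b$cost)  # ~14047, renders as the published 14,048 give or take $1
#' @export
baseline_breakdown <- function(inputs,
                               readmission_policy = c("subset", "separately_costed"),
                               by_gold = FALSE) {
  readmission_policy <- match.arg(readmission_policy)
  m <- category_matrix(inputs, "unenrolled", readmission_policy = readmission_policy)
  if (by_gold) return(matrix_to_long(m, "unenrolled"))
  breakdown_from_matrix(m, inputs, "unenrolled")
}

#' Per-patient annual cost breakdown, enrolled (intervention) arm
#'
#' Applies the intervention effects to the baseline: hospitalization, ED and
#' SABA costs are scaled by one minus their reduction fractions; outpatient
#' and controller costs are unchanged; subscription, RTM fees and (if
#' configured) the reconciliation line are added.  A [scenario_spec()] may
#' override the reductions and add adherence-linked controller cost.
#'
#' @inheritParams baseline_breakdown
#' @param scenario Optional [scenario_spec()]; `NULL` for the base case.
#' @param include_reconciliation Include the configured reconciliation line
#'   (default `TRUE`; scenario and break-even analyses exclude it).
#' @return Tibble with columns `arm`, `category`, `cost`.
#' @export
enrolled_breakdown <- function(inputs, scenario = NULL,
                               readmission_policy = c("subset", "separately_costed"),
                               include_reconciliation = TRUE,
                               by_gold = FALSE) {
  readmission_policy <- match.arg(readmission_policy)
  m <- category_matrix(inputs, "enrolled", scenario = scenario,
                       readmission_policy = readmission_policy,
                       include_reconciliation = include_reconciliation)
  if (by_gold) return(matrix_to_long(m, "enrolled"))
  breakdown_from_matrix(m, inputs, "enrolled")
}

matrix_to_long <- function(m, arm) {
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(m), arm = arm, category = rownames(m)),
    dplyr::all_of(gold_groups), names_to = "gold_group", values_to = "cost"
  )
}

#' Total of a cost breakdown
#'
#' @param breakdown Tibble from [baseline_breakdown()] or
#'   [enrolled_breakdown()].
#' @return Sum of category costs (USD per patient-year, unrounded).
#' @export
breakdown_total <- function(breakdown) sum(breakdown$cost)
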