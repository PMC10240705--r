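# fixtures built in code: shipped configs loaded once, plus a tiny toy
# input set whose arithmetic can be followed by hand

commercial_rep <- bia_config("commercial_replication")
commercial_der <- bia_config("commercial_derived")
medicare_rep <- bia_config("medicare_replication")
medicare_der <- bia_config("medicare_derived")

# uniform toy inputs: every GOLD group identical, single controller
# category, flat prices -- expected costs are one-line products
toy_inputs <- function(...) {
  overrides <- list(...)
  base <- list(
    label = "commercial",
    plan_size = 120000,
    age_shares = c(under_40 = 0.5, age_40_64 = 0.3, age_65_plus = 0.2),
    prevalence = c(age_40_64 = 0.1, age_65_plus = 0.2),
    gold_shares = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25),
    hcru = list(
      outpatient_visits = rep(2, 4), ed_visits = rep(0.5, 4),
      hospitalizations = rep(0.4, 4), readmissions = rep(0.1, 4)
    ),
    unit_costs = c(office_outpatient_visit = 100, ed_visit = 1000,
                   hospitalization = 10000),
    saba = list(weekly_puffs = rep(7, 4),
                wac_prices = tibble::tibble(label = "generic", price = 50),
                actuations_per_canister = 200,
                annual_cost_override = NULL),
    controller = list(
      daily_costs = c(LAMA = 10, LABA = 0, LABA_ICS = 0, LABA_LAMA = 0,
                      LABA_LAMA_ICS = 0),
      mix = rep(list(c(LAMA = 1, LABA = 0, LABA_ICS = 0, LABA_LAMA = 0,
                       LABA_LAMA_ICS = 0)), 4) |> setNames(c("A", "B", "C", "D")),
      pdc = rep(0.5, 4)
    ),
    rtm = tibble::tibble(code = "98976", annual_frequency = 12, fee = 10),
    effects = list(hosp_reduction = 0.5, ed_reduction = 0.2,
                   saba_reduction = 0.1, subscription_cost = 100,
                   bill_rtm_for_all_enrolled = TRUE),
    uptake = c(0.1, 0.2),
    settings = list(days_per_year = 365, reconciliation_line = 0),
    baseline_overrides = NULL
  )
  base[names(overrides)] <- overrides
  do.call(payer_inputs, base)
}

# inputs where every rate, price and fee is zero
zero_inputs <- function() {
  toy_inputs(
    hcru = list(outpatient_visits = rep(0, 4), ed_visits = rep(0, 4),
                hospitalizations = rep(0, 4), readmissions = rep(0, 4)),
    unit_costs = c(office_outpatient_visit = 0, ed_visit = 0, hospitalization = 0),
    saba = list(weekly_puffs = rep(0, 4),
                wac_prices = tibble::tibble(label = "generic", price = 0),
                actuations_per_canister = 200, annual_cost_override = NULL),
    controller = list(
      daily_costs = c(LAMA = 0, LABA = 0, LABA_ICS = 0, LABA_LAMA = 0,
                      LABA_LAMA_ICS = 0),
      mix = rep(list(c(LAMA = 1, LABA = 0, LABA_ICS = 0, LABA_LAMA = 0,
                       LABA_LAMA_ICS = 0)), 4) |> setNames(c("A", "B", "C", "D")),
      pdc = rep(0, 4)
    ),
    rtm = tibble::tibble(code = character(), annual_frequency = numeric(),
                         fee = numeric()),
    effects = list(hosp_reduction = 0, ed_reduction = 0, saba_reduction = 0,
                   subscription_cost = 0, bill_rtm_for_all_enrolled = TRUE)
  )
}

breakdown_cost <- function(breakdown, cat) {
  breakdown$cost[breakdown$category == cat]
}

pmpm_value <- function(tbl, which_view, cat, yr) {
  tbl$pmpm[tbl$view == which_view & tbl$category == cat & tbl$year == yr]
}

avg_value <- function(avg_tbl, which_view, cat) {
  avg_tbl$average[avg_tbl$view == which_view & avg_tbl$category == cat]
}
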