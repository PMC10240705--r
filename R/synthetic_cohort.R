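#' Simulate a patient-level cohort
#'
#' Patient-level stochastic counterpart of the deterministic cohort model,
#' built so that every category's expected per-patient cost equals the
#' deterministic engine's value: GOLD group is categorical on the group
#' shares; outpatient, ED, hospitalization (and readmission) counts are
#' Poisson at the group's annual rate, with the enrolled arm's affected
#' rates scaled by one minus the corresponding reduction; annual rescue
#' puffs are Poisson at the group's weekly rate times weeks per year;
#' controller category is categorical on the group mix; days covered are
#' drawn in whole quarter-days, Binomial(4 x days-per-year, PDC)/4, so the
#' expectation is exactly PDC x days-per-year.  Costs use the same
#' (effective) unit prices as the deterministic engine.  All draws come
#' from one seeded generator in a fixed order (GOLD, outpatient, ED,
#' hospitalizations, readmissions, puffs, controller category, days
#' covered), so identical `(inputs, n, seed, arm)` give identical output.
#'
#' @param inputs A [payer_inputs()] object.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @param arm `"unenrolled"` or `"enrolled"`.
#' @return Tibble with one row per patient: `gold_group`, event counts,
#'   `saba_puffs`, `controller_category`, `days_covered`, and per-category
#'   cost columns (`cost_subscription`, ..., `cost_total`).
#' @export
simulate_patients <- function(inputs, n, seed = 1L,
                              arm = c("unenrolled", "enrolled")) {
  arm <- match.arg(arm)
  if (n < 1) abort("n must be ≥ 1")
  enrolled <- arm == "enrolled"
  eff <- inputs$effects
  red_h <- if (enrolled) eff$hosp_reduction else 0
  red_e <- if (enrolled) eff$ed_reduction else 0
  red_s <- if (enrolled) eff$saba_reduction else 0

  eu <- effective_unit_costs(inputs, "subset")
  pp <- saba_per_puff(inputs)
  days <- inputs$settings$days_per_year
  weeks <- days / 7
  ctrl <- inputs$controller

  withr::with_seed(seed, {
    g <- sample(gold_groups, n, replace = TRUE, prob = inputs$gold_shares)
    gi <- match(g, gold_groups)
    outp <- rpois(n, inputs$hcru$outpatient_visits[gi])
    ed <- rpois(n, inputs$hcru$ed_visits[gi] * (1 - red_e))
    hosp <- rpois(n, inputs$hcru$hospitalizations[gi] * (1 - red_h))
    readmit_p <- ifelse(inputs$hcru$hospitalizations[gi] > 0,
                        inputs$hcru$readmissions[gi] /
                          inputs$hcru$hospitalizations[gi], 0)
    readmit <- rbinom(n, hosp, readmit_p)
    puffs <- rpois(n, inputs$saba$weekly_puffs[gi] * weeks * (1 - red_s))
    # controller categories drawn group-block-wise (A then B, C, D)
    cat_idx <- integer(n)
    for (i in seq_along(gold_groups)) {
      idx <- which(gi == i)
      if (length(idx)) {
        cat_idx[idx] <- sample.int(length(controller_categories), length(idx),
                                   replace = TRUE,
                                   prob = ctrl$mix[[gold_groups[i]]])
      }
    }
    days_cov <- rbinom(n, round(4 * days), ctrl$pdc[gi]) / 4
  })

  subscription <- rep(if (enrolled) eff$subscription_cost else 0, n)
  rtm <- rep(if (enrolled && isTRUE(eff$bill_rtm_for_all_enrolled)) {
    annual_rtm_cost(inputs)
  } else 0, n)
  reconciliation <- rep(if (enrolled) inputs$settings$reconciliation_line else 0, n)
  saba_cost <- if (!is.null(pp$flat)) rep(pp$flat * (1 - red_s), n) else {
    puffs * pp$per_puff
  }

  tibble(
    arm = arm,
    gold_group = g,
    outpatient_visits = outp,
    ed_visits = ed,
    hospitalizations = hosp,
    readmissions = readmit,
    saba_puffs = puffs,
    controller_category = controller_categories[cat_idx],
    days_covered = days_cov,
    cost_subscription = subscription,
    cost_hospitalizations = hosp * eu$unit[["hosp"]],
    cost_ed_visits = ed * eu$unit[["ed"]],
    cost_outpatient_office = outp * eu$unit[["office"]],
    cost_rtm = rtm,
    cost_saba = saba_cost,
    cost_controller = ctrl$daily_costs[cat_idx] * days_cov,
    cost_reconciliation = reconciliation
  ) |>
    dplyr::mutate(cost_total = rowSums(dplyr::pick(dplyr::starts_with("cost_"))))
}

#' Monte-Carlo summary of per-patient annual costs
#'
#' Simulates `n` patients with [simulate_patients()] and summarizes the
#' mean per-patient annual cost and its standard error by category.  By the
#' law of large numbers the means converge to the deterministic engine's
#' per-patient breakdown; this is the package's validation oracle for the
#' cohort arithmetic.
#'
#' @inheritParams simulate_patients
#' @return Tibble of class `bia_sim_summary`: `category` (the cost
#'   categories plus `"total"`), `mean`, `se`, `n`, `seed`, `arm`.
#' @examples
#' sim <- simulate_cohort(bia_config("commercial_replication"), 2000, seed = 7)
#' det <- baseline_breakdown(bia_config("commercial_replication"))
#' merge(sim, det, by = "category")[, c("category", "mean", "se", "cost")]
#' @export
simulate_cohort <- function(inputs, n, seed = 1L,
                            arm = c("unenrolled", "enrolled")) {
  arm <- match.arg(arm)
  pts <- simulate_patients(inputs, n, seed, arm)
  long <- tidyr::pivot_longer(
    dplyr::select(pts, dplyr::starts_with("cost_")),
    dplyr::everything(), names_to = "category", values_to = "cost",
    names_prefix = "cost_"
  )
  out <- dplyr::summarise(
    long,
    mean = mean(.data$cost),
    se = stats::sd(.data$cost) / sqrt(dplyr::n()),
    .by = "category"
  ) |>
    dplyr::mutate(n = n, seed = as.integer(seed), arm = arm) |>
    dplyr::arrange(match(.data$category, c(cost_categories, "total")))
  structure(out, class = c("bia_sim_summary", class(tibble())))
}

#' Draw a random, valid payer input set
#'
#' Property-testing generator: every distribution is renormalized to sum to
#' one, rates and costs are nonnegative and bounded by ten times the shipped
#' configuration's values, and the result always passes
#' [validate_payer_inputs()].  Identical seeds give identical parameter
#' sets.
#'
#' @param seed Integer seed.
#' @return A validated [payer_inputs()] object.
#' @export
random_inputs <- function(seed = 1L) {
  withr::with_seed(seed, {
    norm <- function(k) { v <- runif(k) + 1e-6; v / sum(v) }
    ages <- norm(3)
    gold <- norm(4)
    hosp <- runif(4, 0, 5.6)
    mix <- lapply(seq_len(4), function(i) setNames(as.list(norm(5)), controller_categories))
    names(mix) <- gold_groups
    payer_inputs(
      label = sample(c("commercial", "medicare"), 1),
      plan_size = round(runif(1, 1e5, 1e7)),
      age_shares = setNames(as.list(ages), c("under_40", "age_40_64", "age_65_plus")),
      prevalence = list(age_40_64 = runif(1, 0, 0.76), age_65_plus = runif(1, 0, 1)),
      gold_shares = setNames(as.list(gold), gold_groups),
      hcru = list(
        outpatient_visits = runif(4, 0, 26.4),
        ed_visits = runif(4, 0, 2.2),
        hospitalizations = hosp,
        readmissions = runif(4) * hosp
      ),
      unit_costs = c(office_outpatient_visit = runif(1, 0, 1260),
                     ed_visit = runif(1, 0, 30650),
                     hospitalization = runif(1, 0, 258390)),
      saba = list(
        weekly_puffs = setNames(as.list(runif(4, 0, 127.8)), gold_groups),
        wac_prices = tibble(label = paste0("product_", 1:3),
                            price = runif(3, 0, 4264.5)),
        actuations_per_canister = sample(50:400, 1),
        annual_cost_override = NULL
      ),
      controller = list(
        daily_costs = setNames(as.list(runif(5, 0, 191.1)), controller_categories),
        mix = mix,
        pdc = setNames(as.list(runif(4)), gold_groups)
      ),
      rtm = tibble(code = c("98975", "98976", "98980"),
                   annual_frequency = sample(0:12, 3, replace = TRUE),
                   fee = runif(3, 0, 600)),
      effects = list(hosp_reduction = runif(1), ed_reduction = runif(1),
                     saba_reduction = runif(1),
                     subscription_cost = runif(1, 0, 2000),
                     bill_rtm_for_all_enrolled = TRUE),
      uptake = runif(3),
      settings = list(days_per_year = sample(c(365, 365.25), 1),
                      reconciliation_line = 0)
    )
  })
}
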