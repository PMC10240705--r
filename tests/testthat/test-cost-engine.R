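test_that("GOLD-weighted means reproduce hand-computed weighted sums", {
  sh <- commercial_der$gold_shares
  expect_equal(gold_weighted_mean(c(0.36, 0.46, 0.56, 0.56), sh), 0.4265)
  expect_equal(gold_weighted_mean(c(0.11, 0.19, 0.22, 0.22), sh), 0.15325)
  expect_equal(gold_weighted_mean(c(5.81, 8.82, 5.81, 12.78), sh), 7.42916)
  # identical values are invariant under weighting
  expect_equal(gold_weighted_mean(rep(3.7, 4), sh), 3.7)
})

test_that("medical category costs are weighted rate times unit cost", {
  med <- annual_medical_costs(commercial_der)
  expect_equal(med[["outpatient_office"]], 2.64 * 126)        # 332.64
  expect_equal(med[["hospitalizations"]], 0.4265 * 25839)     # 11020.33
  expect_equal(med[["ed_visits"]], 0.15325 * 3065)
  # readmissions are a subset by default; costing them separately adds
  # weighted readmission rate x hospitalization unit cost
  sep <- annual_medical_costs(commercial_der, "separately_costed")
  readmit_w <- gold_weighted_mean(c(0.04, 0.07, 0.08, 0.08),
                                  commercial_der$gold_shares)
  expect_equal(sep[["hospitalizations"]] - med[["hospitalizations"]],
               readmit_w * 25839)
  expect_error(annual_medical_costs(commercial_der, "bogus"))
  # zero unit costs zero out every category
  expect_equal(unname(annual_medical_costs(zero_inputs())), rep(0, 3))
})

test_that("SABA cost: override short-circuits, otherwise WAC mean per puff", {
  expect_equal(annual_saba_cost(commercial_rep), 292)
  # derived: mean WAC / actuations x weighted weekly puffs x weeks
  expect_equal(annual_saba_cost(commercial_der),
               169.049 / 200 * 7.42916 * 365.25 / 7)
  no_puffs <- toy_inputs(saba = list(weekly_puffs = rep(0, 4),
                                     wac_prices = tibble::tibble(label = "g", price = 50),
                                     actuations_per_canister = 200,
                                     annual_cost_override = NULL))
  expect_equal(annual_saba_cost(no_puffs), 0)
})

test_that("controller cost weights the mix-average daily cost by PDC and days", {
  # group A daily mix cost from the printed mix and prices
  ctrl <- commercial_der$controller
  expect_equal(sum(ctrl$mix$A * ctrl$daily_costs), 14.856)
  expect_equal(annual_controller_cost(commercial_der), 3042.128263,
               tolerance = 1e-9)
  # PDC of zero means no controller cost
  pdc0 <- commercial_der
  pdc0$controller$pdc[] <- 0
  expect_equal(annual_controller_cost(pdc0), 0)
  # shifted PDC clips at 1
  expect_equal(annual_controller_cost(pdc0, pdc_delta = 2),
               annual_controller_cost(pdc0, pdc_delta = 1))
})

test_that("RTM annual cost sums frequency times fee over the schedule", {
  expect_equal(annual_rtm_cost(commercial_rep), 1 * 19.38 + 6 * 55.72 + 6 * 50.18)
  expect_equal(annual_rtm_cost(toy_inputs()), 120)
  expect_equal(annual_rtm_cost(zero_inputs()), 0)
})

test_that("replication baselines reproduce the published per-patient columns", {
  unen <- baseline_breakdown(commercial_rep)
  expect_equal(round_half_up(unen$cost[match(
    c("hospitalizations", "ed_visits", "outpatient_office", "saba", "controller"),
    unen$category)]), c(9918, 462, 333, 292, 3042))
  expect_equal(breakdown_total(unen), 14046.768263, tolerance = 1e-9)
  # structural zeros on the unenrolled arm
  expect_equal(breakdown_cost(unen, "subscription"), 0)
  expect_equal(breakdown_cost(unen, "rtm"), 0)
  expect_equal(breakdown_cost(unen, "reconciliation"), 0)

  unen_m <- baseline_breakdown(medicare_rep)
  expect_equal(breakdown_total(unen_m), 8989.743648, tolerance = 1e-9)
  # Medicare outpatient uses the unrounded derived office cost: 233, not 232
  expect_equal(round_half_up(breakdown_cost(unen_m, "outpatient_office")), 233)
})

test_that("enrolled arm applies reductions and adds fixed intervention costs", {
  enr <- enrolled_breakdown(commercial_rep)
  expect_equal(breakdown_cost(enr, "hospitalizations"), 9918 * 0.70)
  expect_equal(breakdown_cost(enr, "ed_visits"), 462 * 0.45)
  expect_equal(breakdown_cost(enr, "saba"), 292 * 0.406)
  expect_equal(breakdown_cost(enr, "subscription"), 200)
  expect_equal(breakdown_cost(enr, "rtm"), 654.78)
  expect_equal(breakdown_cost(enr, "reconciliation"), 73)
  # outpatient and controller are untouched by the intervention
  unen <- baseline_breakdown(commercial_rep)
  expect_equal(breakdown_cost(enr, "outpatient_office"),
               breakdown_cost(unen, "outpatient_office"))
  expect_equal(breakdown_cost(enr, "controller"),
               breakdown_cost(unen, "controller"))
  expect_equal(breakdown_total(unen) - breakdown_total(enr), 2475.168,
               tolerance = 1e-9)
})

test_that("zero effects, fees and reconciliation make enrollment a no-op", {
  z <- toy_inputs(effects = list(hosp_reduction = 0, ed_reduction = 0,
                                 saba_reduction = 0, subscription_cost = 0,
                                 bill_rtm_for_all_enrolled = TRUE),
                  rtm = tibble::tibble(code = character(),
                                       annual_frequency = numeric(),
                                       fee = numeric()))
  unen <- baseline_breakdown(z)
  enr <- enrolled_breakdown(z)
  expect_equal(enr$cost, unen$cost, tolerance = 1e-12)
})

test_that("category costs are homogeneous of degree one in unit prices", {
  for (seed in 1:5) {
    ri <- random_inputs(seed)
    ri2 <- ri
    ri2$unit_costs <- ri$unit_costs * 2
    ri2$saba$wac_prices$price <- ri$saba$wac_prices$price * 2
    ri2$controller$daily_costs <- ri$controller$daily_costs * 2
    ri2$rtm$fee <- ri$rtm$fee * 2
    ri2$effects$subscription_cost <- ri$effects$subscription_cost * 2
    for (f in list(baseline_breakdown, enrolled_breakdown)) {
      expect_equal(f(ri2)$cost, 2 * f(ri)$cost, tolerance = 1e-9)
    }
  }
})

test_that("enrolled hospitalization cost is non-increasing in the reduction", {
  ri <- random_inputs(11)
  costs <- vapply(seq(0, 1, by = 0.2), function(r) {
    ri$effects$hosp_reduction <- r
    breakdown_cost(enrolled_breakdown(ri), "hospitalizations")
  }, numeric(1))
  expect_true(all(diff(costs) <= 1e-12))
})

test_that("weighting groups then costing equals costing groups then weighting", {
  for (inputs in list(commercial_der, medicare_der, commercial_rep,
                      random_inputs(3))) {
    for (f in list(baseline_breakdown, enrolled_breakdown)) {
      agg <- f(inputs)
      per_group <- f(inputs, by_gold = TRUE)
      rebuilt <- vapply(agg$category, function(cat) {
        g <- per_group[per_group$category == cat, ]
        gold_weighted_mean(setNames(g$cost, g$gold_group), inputs$gold_shares)
      }, numeric(1))
      expect_equal(unname(rebuilt), agg$cost, tolerance = 1e-9)
    }
  }
})
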