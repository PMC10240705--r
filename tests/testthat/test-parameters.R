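test_that("shipped configurations load with the published parameter values", {
  expect_equal(commercial_der$plan_size, 5e6)
  expect_equal(unname(commercial_der$age_shares), c(0.53, 0.35, 0.12))
  expect_equal(unname(commercial_der$gold_shares), c(0.534, 0.267, 0.082, 0.117))
  expect_equal(unname(commercial_der$prevalence), c(0.076, 0.132))
  expect_equal(unname(medicare_der$age_shares), c(0.03, 0.12, 0.85))
  expect_equal(nrow(commercial_der$saba$wac_prices), 10)
  expect_equal(mean(commercial_der$saba$wac_prices$price), 169.049)

  # replication configs carry the published per-patient baselines
  expect_equal(unname(commercial_rep$baseline_overrides),  c(9918, 462))
  expect_equal(unname(medicare_rep$baseline_overrides), c(5248, 175))
  expect_equal(commercial_rep$saba$annual_cost_override, 292)
  expect_equal(commercial_rep$settings$reconciliation_line, 73)
  expect_equal(medicare_rep$settings$reconciliation_line, 74)
})

test_that("Medicare unit costs derive from commercial via payment ratios", {
  med <- derive_medicare_unit_costs(
    c(office_outpatient_visit = 126, ed_visit = 3065, hospitalization = 25839),
    c(hospital_outpatient_ed = 2.64, physician_office = 1.43, inpatient = 1.89)
  )
  # unrounded internally; published values appear after rounding to dollars
  expect_equal(unname(round_half_up(med)), c(88, 1161, 13671))
  expect_equal(med[["hospitalization"]], 25839 / 1.89, tolerance = 1e-12)

  # identity ratios leave costs unchanged
  ones <- c(hospital_outpatient_ed = 1, physician_office = 1, inpatient = 1)
  expect_equal(
    derive_medicare_unit_costs(c(office_outpatient_visit = 10, ed_visit = 20,
                                 hospitalization = 30), ones),
    c(office_outpatient_visit = 10, ed_visit = 20, hospitalization = 30)
  )
  expect_error(
    derive_medicare_unit_costs(
      c(office_outpatient_visit = 10, ed_visit = 20, hospitalization = 30),
      c(hospital_outpatient_ed = 0, physician_office = 1, inpatient = 1)
    ),
    "positive"
  )
  # the shipped medicare configs hold the unrounded derived costs
  expect_equal(medicare_rep$unit_costs[["office_outpatient_visit"]], 126 / 1.43)
})

test_that("validation reports every violated invariant, not just the first", {
  bad <- function() {
    toy_inputs(age_shares = c(under_40 = 0.5, age_40_64 = 0.3, age_65_plus = 0.1),
               gold_shares = c(A = 0.5, B = 0.25, C = 0.25, D = 0.1))
  }
  expect_error(bad(), "age shares sum 0.9", class = "copdbia_validation_error")
  expect_error(bad(), "GOLD shares sum 1.1")

  expect_error(
    toy_inputs(hcru = list(outpatient_visits = rep(2, 4), ed_visits = rep(0.5, 4),
                           hospitalizations = rep(0.1, 4), readmissions = rep(0.2, 4))),
    "readmission rate exceeds"
  )
  expect_error(toy_inputs(controller = list(
    daily_costs = c(LAMA = 10, LABA = 0, LABA_ICS = 0, LABA_LAMA = 0,
                    LABA_LAMA_ICS = 0),
    mix = setNames(rep(list(c(LAMA = 0.5, LABA = 0, LABA_ICS = 0,
                              LABA_LAMA = 0, LABA_LAMA_ICS = 0)), 4),
                   c("A", "B", "C", "D")),
    pdc = rep(1.5, 4)
  )), "controller mix for group A")
  expect_error(toy_inputs(settings = list(days_per_year = 360)), "days_per_year")
})

test_that("unknown configuration keys are rejected by name", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  doc <- yaml::read_yaml(bia_config_path("commercial_derived"))
  doc$prevalnce <- doc$prevalence  # misspelling must not pass silently
  yaml::write_yaml(doc, tmp)
  expect_error(read_payer_inputs(tmp), "prevalnce",
               class = "copdbia_format_error")

  doc2 <- yaml::read_yaml(bia_config_path("commercial_derived"))
  doc2$effects$typo_key <- 1
  yaml::write_yaml(doc2, tmp)
  expect_error(read_payer_inputs(tmp), "effects.*typo_key")
})

test_that("write-then-read round-trips valid inputs, YAML and JSON alike", {
  for (cfg in list(commercial_rep, medicare_rep, toy_inputs())) {
    for (ext in c(".yaml", ".json")) {
      tmp <- withr::local_tempfile(fileext = ext)
      write_payer_inputs(cfg, tmp)
      back <- read_payer_inputs(tmp)
      expect_equal(back, cfg, tolerance = 1e-12)
    }
  }
})
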