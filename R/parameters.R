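#' Payer input set for the budget-impact model
#'
#' Bundles everything the model needs for one payer perspective: plan
#' demographics, COPD prevalence by age band, the GOLD 2017 ABCD group
#' distribution, annual healthcare resource use (HCRU) rates and unit costs,
#' rescue (SABA) and controller inhaler parameters, the remote therapeutic
#' monitoring (RTM) fee schedule, intervention effect sizes, the market
#' uptake schedule, and model settings.
#'
#' Two configurations per payer ship with the package (see [bia_config()]):
#' `"derived"` computes every baseline from the primary parameter table,
#' while `"replication"` overrides the baseline per-patient hospitalization,
#' emergency department (ED) and SABA costs with the published per-patient
#' values (their upstream derivation uses supplementary data that are not
#' part of the primary table) and carries an explicit reconciliation line on
#' the enrolled arm.
#'
#' @param label Payer perspective, `"commercial"` or `"medicare"`.
#' @param plan_size Number of plan members (> 0).
#' @param age_shares Named numeric, fractions for `under_40`, `age_40_64`,
#'   `age_65_plus`; must sum to 1.
#' @param prevalence Named numeric, COPD prevalence for `age_40_64` and
#'   `age_65_plus` (the under-40 band is structurally excluded).
#' @param gold_shares Named numeric over groups A--D; must sum to 1.
#' @param hcru List of four named numeric vectors over A--D:
#'   `outpatient_visits`, `ed_visits`, `hospitalizations`, `readmissions`
#'   (annual events per patient; readmissions are a subset of
#'   hospitalizations and may not exceed them).
#' @param unit_costs Named numeric per event (2020 USD):
#'   `office_outpatient_visit`, `ed_visit`, `hospitalization`.
#' @param payment_ratios Optional named numeric of commercial-to-Medicare
#'   payment ratios (`hospital_outpatient_ed`, `physician_office`,
#'   `inpatient`); when supplied, `unit_costs` is interpreted as the
#'   commercial set and Medicare unit costs are derived, unrounded, by
#'   [derive_medicare_unit_costs()].
#' @param saba List: `weekly_puffs` (named over A--D), `wac_prices` (data
#'   frame with `label`, `price` per canister), `actuations_per_canister`,
#'   and optional `annual_cost_override` (USD per patient-year).
#' @param controller List: `daily_costs` (named over the five controller
#'   categories), `mix` (list over A--D of named fractions summing to 1),
#'   `pdc` (proportion of days covered, named over A--D).
#' @param rtm Data frame with `code`, `annual_frequency`, `fee`.
#' @param effects List: `hosp_reduction`, `ed_reduction`, `saba_reduction`
#'   (fractions), `subscription_cost` (USD per patient-year),
#'   `bill_rtm_for_all_enrolled` (logical).
#' @param uptake Numeric vector of per-year market-penetration fractions.
#' @param settings List: `days_per_year` (365 or 365.25) and
#'   `reconciliation_line` (USD added to the enrolled arm; default 0).
#' @param baseline_overrides Optional named numeric overriding baseline
#'   per-patient annual costs for `hospitalizations` and/or `ed_visits`.
#'
#' @return A validated object of class `payer_inputs`.
#' @seealso [read_payer_inputs()], [bia_config()], [validate_payer_inputs()]
#' @export
payer_inputs <- function(label, plan_size, age_shares, prevalence,
                         gold_shares, hcru, unit_costs,
                         payment_ratios = NULL, saba, controller, rtm,
                         effects, uptake, settings = list(),
                         baseline_overrides = NULL) {
  settings <- modifyList(list(days_per_year = 365.25, reconciliation_line = 0),
                         settings)
  resolved <- unit_costs
  if (!is.null(payment_ratios)) {
    resolved <- derive_medicare_unit_costs(unit_costs, payment_ratios)
  }
  x <- structure(
    list(
      label = label,
      plan_size = plan_size,
      age_shares = as_named(age_shares, c("under_40", "age_40_64", "age_65_plus")),
      prevalence = as_named(prevalence, c("age_40_64", "age_65_plus")),
      gold_shares = as_named(gold_shares, gold_groups),
      hcru = lapply(hcru, as_named, nm = gold_groups),
      unit_costs = resolved,
      commercial_unit_costs = if (is.null(payment_ratios)) NULL else unlist(unit_costs),
      payment_ratios = if (is.null(payment_ratios)) NULL else unlist(payment_ratios),
      saba = list(
        weekly_puffs = as_named(saba$weekly_puffs, gold_groups),
        wac_prices = as_tibble(saba$wac_prices),
        actuations_per_canister = saba$actuations_per_canister,
        annual_cost_override = saba$annual_cost_override
      ),
      controller = list(
        daily_costs = as_named(controller$daily_costs, controller_categories),
        mix = lapply(controller$mix, as_named, nm = controller_categories)[gold_groups],
        pdc = as_named(controller$pdc, gold_groups)
      ),
      rtm = as_tibble(rtm),
      effects = effects,
      uptake = as.numeric(unlist(uptake)),
      settings = settings,
      baseline_overrides = if (is.null(baseline_overrides)) NULL else unlist(baseline_overrides)
    ),
    class = "payer_inputs"
  )
  validate_payer_inputs(x)
}

#' Derive Medicare unit costs from commercial costs and payment ratios
#'
#' Medicare pays less per event than commercial insurers; the model converts
#' commercial unit costs using published commercial-to-Medicare payment
#' ratios.  ED and hospital-outpatient events use the hospital-outpatient/ED
#' ratio, office visits the physician-office ratio, hospitalizations the
#' inpatient ratio.  Results are left unrounded; rounding to whole dollars
#' happens only at the reporting layer.
#'
#' @param commercial Named numeric: `office_outpatient_visit`, `ed_visit`,
#'   `hospitalization` (USD per event).
#' @param ratios Named numeric: `hospital_outpatient_ed`,
#'   `physician_office`, `inpatient`; all must be positive.
#' @return Named numeric of Medicare unit costs (unrounded).
#' @examples
#' derive_medicare_unit_costs(
#'   c(office_outpatient_visit = 126, ed_visit = 3065, hospitalization = 25839),
#'   c(hospital_outpatient_ed = 2.64, physician_office = 1.43, inpatient = 1.89)
#' )
#' @export
derive_medicare_unit_costs <- function(commercial, ratios) {
  commercial <- unlist(commercial)
  ratios <- unlist(ratios)
  need <- c("hospital_outpatient_ed", "physician_office", "inpatient")
  if (!all(need %in% names(ratios))) {
    abort(paste0("payment ratios must be named ", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    abort("all payment ratios must be positive")
  }
  c(
    office_outpatient_visit = unname(commercial[["office_outpatient_visit"]] /
                                       ratios[["physician_office"]]),
    ed_visit = unname(commercial[["ed_visit"]] / ratios[["hospital_outpatient_ed"]]),
    hospitalization = unname(commercial[["hospitalization"]] / ratios[["inpatient"]])
  )
}

as_named <- function(v, nm) {
  v <- unlist(v)
  if (is.null(names(v))) names(v) <- nm else v <- v[nm]
  v
}

# ---- validation --------------------------------------------------------

check_distribution <- function(x, what, tol = 1e-6) {
  errs <- character()
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    errs <- c(errs, sprintf("%s must all lie in [0, 1]", what))
  }
  s <- sum(x)
  if (is.finite(s) && abs(s - 1) > tol) {
    errs <- c(errs, sprintf("%s sum %.6g ≠ 1", what, s))
  }
  errs
}

#' Validate a payer input set
#'
#' Checks every structural invariant of the input set (positive plan size,
#' distributions summing to one, nonnegative rates and costs, readmissions
#' bounded by hospitalizations, fractions in \[0, 1\], integer RTM
#' frequencies, permitted days-per-year values) and reports *all* failures
#' at once, not just the first.
#'
#' @param x A `payer_inputs` object (or bare list with the same fields).
#' @return `x`, invisibly classed, if valid; otherwise an error listing
#'   every violated invariant.
#' @export
validate_payer_inputs <- function(x) {
  errs <- character()
  add <- function(e) errs <<- c(errs, e)

  if (!x$label %in% c("commercial", "medicare")) {
    add('label must be "commercial" or "medicare"')
  }
  if (!is.numeric(x$plan_size) || x$plan_size <= 0) {
    add("plan_size must be > 0")
  }
  add(check_distribution(x$age_shares, "age shares"))
  if (any(x$prevalence < 0 | x$prevalence > 1)) {
    add("prevalence values must lie in [0, 1]")
  }
  add(check_distribution(x$gold_shares, "GOLD shares"))

  for (nm in c("outpatient_visits", "ed_visits", "hospitalizations", "readmissions")) {
    if (any(x$hcru[[nm]] < 0)) add(sprintf("HCRU rates for %s must be ≥ 0", nm))
  }
  over <- x$hcru$readmissions > x$hcru$hospitalizations
  if (any(over)) {
    add(sprintf("readmission rate exceeds hospitalization rate for group %s",
                paste(gold_groups[over], collapse = ", ")))
  }
  if (any(x$unit_costs < 0)) add("unit costs must be ≥ 0")

  if (any(x$saba$weekly_puffs < 0)) add("weekly SABA puffs must be ≥ 0")
  if (nrow(x$saba$wac_prices) > 0 && any(x$saba$wac_prices$price < 0)) {
    add("WAC prices must be ≥ 0")
  }
  if (x$saba$actuations_per_canister <= 0) {
    add("actuations_per_canister must be > 0")
  }
  ov <- x$saba$annual_cost_override
  if (!is.null(ov) && ov < 0) add("SABA annual cost override must be ≥ 0")

  if (any(x$controller$daily_costs < 0)) add("controller daily costs must be ≥ 0")
  for (g in gold_groups) {
    add(check_distribution(x$controller$mix[[g]],
                           sprintf("controller mix for group %s", g)))
  }
  if (any(x$controller$pdc < 0 | x$controller$pdc > 1)) {
    add("PDC values must lie in [0, 1]")
  }

  if (nrow(x$rtm) > 0) {
    if (any(x$rtm$annual_frequency < 0) ||
        any(x$rtm$annual_frequency != round(x$rtm$annual_frequency))) {
      add("RTM annual frequencies must be nonnegative integers")
    }
    if (any(x$rtm$fee < 0)) add("RTM fees must be ≥ 0")
  }

  for (nm in c("hosp_reduction", "ed_reduction", "saba_reduction")) {
    v <- x$effects[[nm]]
    if (is.null(v) || v < 0 || v > 1) {
      add(sprintf("effects$%s must lie in [0, 1]", nm))
    }
  }
  if (is.null(x$effects$subscription_cost) || x$effects$subscription_cost < 0) {
    add("subscription cost must be ≥ 0")
  }

  if (length(x$uptake) < 1) add("uptake schedule needs at least one year")
  if (any(x$uptake < 0 | x$uptake > 1)) add("uptake fractions must lie in [0, 1]")

  if (!x$settings$days_per_year %in% c(365, 365.25)) {
    add("days_per_year must be 365 or 365.25")
  }
  if (!is.null(x$baseline_overrides)) {
    bad <- setdiff(names(x$baseline_overrides), c("hospitalizations", "ed_visits"))
    if (length(bad)) {
      add(sprintf("unknown baseline override(s): %s", paste(bad, collapse = ", ")))
    }
    if (any(x$baseline_overrides < 0)) add("baseline overrides must be ≥ 0")
  }

  if (length(errs)) {
    abort(c("invalid payer inputs:", setNames(errs, rep("x", length(errs)))),
          class = "copdbia_validation_error")
  }
  invisible(x)
}

# ---- config file schema ------------------------------------------------

gold_leaf <- function() setNames(rep(list("LEAF"), 4), gold_groups)
ctrl_leaf <- function() setNames(rep(list("LEAF"), 5), controller_categories)

config_schema <- function() {
  list(
    label = "LEAF", plan_size = "LEAF",
    age_shares = list(under_40 = "LEAF", age_40_64 = "LEAF", age_65_plus = "LEAF"),
    prevalence = list(age_40_64 = "LEAF", age_65_plus = "LEAF"),
    gold_shares = gold_leaf(),
    hcru = list(outpatient_visits = gold_leaf(), ed_visits = gold_leaf(),
                hospitalizations = gold_leaf(), readmissions = gold_leaf()),
    unit_costs = list(office_outpatient_visit = "LEAF", ed_visit = "LEAF",
                      hospitalization = "LEAF",
                      commercial = list(office_outpatient_visit = "LEAF",
                                        ed_visit = "LEAF",
                                        hospitalization = "LEAF"),
                      payment_ratios = list(hospital_outpatient_ed = "LEAF",
                                            physician_office = "LEAF",
                                            inpatient = "LEAF")),
    saba = list(weekly_puffs = gold_leaf(),
                wac_prices = list(ENTRY = list(label = "LEAF", price = "LEAF")),
                actuations_per_canister = "LEAF",
                annual_cost_override = "LEAF"),
    controller = list(daily_costs = ctrl_leaf(),
                      mix = setNames(rep(list(ctrl_leaf()), 4), gold_groups),
                      pdc = gold_leaf()),
    rtm = list(ENTRY = list(code = "LEAF", annual_frequency = "LEAF", fee = "LEAF")),
    effects = list(hosp_reduction = "LEAF", ed_reduction = "LEAF",
                   saba_reduction = "LEAF", subscription_cost = "LEAF",
                   bill_rtm_for_all_enrolled = "LEAF"),
    uptake = "LEAF",
    settings = list(days_per_year = "LEAF", reconciliation_line = "LEAF"),
    baseline_overrides = list(hospitalizations = "LEAF", ed_visits = "LEAF")
  )
}

check_unknown_keys <- function(node, schema, path = "") {
  errs <- character()
  if (identical(schema, "LEAF") || !is.list(node)) return(errs)
  if (!is.null(schema$ENTRY)) {
    for (i in seq_along(node)) {
      errs <- c(errs, check_unknown_keys(node[[i]], schema$ENTRY,
                                         sprintf("%s[%d]", path, i)))
    }
    return(errs)
  }
  unknown <- setdiff(names(node), names(schema))
  if (length(unknown)) {
    errs <- c(errs, sprintf("unknown key(s) at %s: %s",
                            if (nzchar(path)) path else "top level",
                            paste(unknown, collapse = ", ")))
  }
  for (nm in intersect(names(node), names(schema))) {
    errs <- c(errs, check_unknown_keys(node[[nm]], schema[[nm]],
                                       paste0(path, if (nzchar(path)) "/" else "", nm)))
  }
  errs
}

#' Read a payer configuration file
#'
#' Parses a YAML or JSON configuration (keyed after the model's parameter
#' table), rejects unknown keys (a guard against silently misspelled
#' parameter names), and validates every invariant.  A Medicare
#' configuration may supply `unit_costs: commercial: ... payment_ratios:`
#' instead of direct unit costs; the Medicare costs are then derived
#' unrounded.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated [payer_inputs()] object.
#' @export
read_payer_inputs <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  doc <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) {
      abort(sprintf("could not parse config %s: %s", path, conditionMessage(e)),
            class = "copdbia_format_error")
    }
  )
  payer_inputs_from_list(doc, source = path)
}

payer_inputs_from_list <- function(doc, source = "config") {
  errs <- check_unknown_keys(doc, config_schema())
  required <- c("label", "plan_size", "age_shares", "prevalence", "gold_shares",
                "hcru", "unit_costs", "saba", "controller", "rtm", "effects",
                "uptake")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    errs <- c(errs, sprintf("missing required key(s): %s",
                            paste(missing, collapse = ", ")))
  }
  if (length(errs)) {
    abort(c(sprintf("invalid config %s:", source),
            setNames(errs, rep("x", length(errs)))),
          class = "copdbia_format_error")
  }

  uc <- doc$unit_costs
  ratios <- NULL
  if (!is.null(uc$payment_ratios)) {
    ratios <- uc$payment_ratios
    uc <- uc$commercial
  }
  wac <- doc$saba$wac_prices %||% list()
  wac_tbl <- tibble(
    label = vapply(wac, function(e) as.character(e$label), character(1)),
    price = vapply(wac, function(e) as.numeric(e$price), numeric(1))
  )
  rtm_tbl <- tibble(
    code = vapply(doc$rtm, function(e) as.character(e$code), character(1)),
    annual_frequency = vapply(doc$rtm, function(e) as.numeric(e$annual_frequency), numeric(1)),
    fee = vapply(doc$rtm, function(e) as.numeric(e$fee), numeric(1))
  )

  payer_inputs(
    label = doc$label,
    plan_size = doc$plan_size,
    age_shares = doc$age_shares,
    prevalence = doc$prevalence,
    gold_shares = doc$gold_shares,
    hcru = doc$hcru,
    unit_costs = unlist(uc),
    payment_ratios = ratios,
    saba = list(weekly_puffs = doc$saba$weekly_puffs,
                wac_prices = wac_tbl,
                actuations_per_canister = doc$saba$actuations_per_canister,
                annual_cost_override = doc$saba$annual_cost_override),
    controller = doc$controller,
    rtm = rtm_tbl,
    effects = doc$effects,
    uptake = doc$uptake,
    settings = doc$settings %||% list(),
    baseline_overrides = doc$baseline_overrides
  )
}

#' Serialize a payer input set back to a configuration file
#'
#' Writes the same schema [read_payer_inputs()] accepts; reading the result
#' back reproduces an equal object (round-trip identity).  Medicare inputs
#' built from commercial costs and payment ratios are written in that
#' derived form.
#'
#' @param x A `payer_inputs` object.
#' @param path Destination path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_payer_inputs <- function(x, path) {
  uc <- if (is.null(x$payment_ratios)) {
    as.list(x$unit_costs)
  } else {
    list(commercial = as.list(x$commercial_unit_costs),
         payment_ratios = as.list(x$payment_ratios))
  }
  doc <- compact_null(list(
    label = x$label,
    plan_size = x$plan_size,
    age_shares = as.list(x$age_shares),
    prevalence = as.list(x$prevalence),
    gold_shares = as.list(x$gold_shares),
    hcru = lapply(x$hcru, as.list),
    unit_costs = uc,
    saba = compact_null(list(
      weekly_puffs = as.list(x$saba$weekly_puffs),
      wac_prices = purrr::pmap(x$saba$wac_prices, function(label, price) {
        list(label = label, price = price)
      }),
      actuations_per_canister = x$saba$actuations_per_canister,
      annual_cost_override = x$saba$annual_cost_override
    )),
    controller = list(daily_costs = as.list(x$controller$daily_costs),
                      mix = lapply(x$controller$mix, as.list),
                      pdc = as.list(x$controller$pdc)),
    rtm = purrr::pmap(x$rtm, function(code, annual_frequency, fee) {
      list(code = code, annual_frequency = annual_frequency, fee = fee)
    }),
    effects = x$effects,
    uptake = as.list(x$uptake),
    settings = x$settings,
    baseline_overrides = if (is.null(x$baseline_overrides)) NULL else as.list(x$baseline_overrides)
  ))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(path)
}

#' Load a shipped payer configuration
#'
#' @param name One of `"commercial_derived"`, `"commercial_replication"`,
#'   `"medicare_derived"`, `"medicare_replication"`.
#' @return A validated [payer_inputs()] object.
#' @examples
#' cfg <- bia_config("commercial_replication")
#' cfg$plan_size
#' @export
bia_config <- function(name = c("commercial_replication", "commercial_derived",
                                "medicare_replication", "medicare_derived")) {
  name <- match.arg(name)
  read_payer_inputs(bia_config_path(name))
}

#' @rdname bia_config
#' @export
bia_config_path <- function(name) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "copdbia")
  if (!nzchar(path)) abort(sprintf("no shipped config named %s", name))
  path
}

#' @export
print.payer_inputs <- function(x, ...) {
  cat(sprintf("<payer_inputs: %s>\n", x$label))
  cat(sprintf("  plan size      %s members\n", format(x$plan_size, big.mark = ",")))
  cat(sprintf("  GOLD shares    %s\n",
              paste(sprintf("%s %.1f%%", gold_groups, 100 * x$gold_shares),
                    collapse = ", ")))
  cat(sprintf("  unit costs     office %.2f, ED %.2f, hosp %.2f\n",
              x$unit_costs[["office_outpatient_visit"]],
              x$unit_costs[["ed_visit"]], x$unit_costs[["hospitalization"]]))
  cat(sprintf("  uptake         %s\n",
              paste(sprintf("%.0f%%", 100 * x$uptake), collapse = " / ")))
  if (!is.null(x$baseline_overrides)) {
    cat(sprintf("  overrides      %s\n",
                paste(sprintf("%s = %s", names(x$baseline_overrides),
                              x$baseline_overrides), collapse = ", ")))
  }
  invisible(x)
}
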