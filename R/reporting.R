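#' Run the full analysis and write a report bundle
#'
#' Runs [run_bia()] and writes, under `out_dir`: the population table, the
#' per-patient breakdown by arm (and the rendered difference column), the
#' PMPM tables for the three views, the expenditure report, a JSON summary
#' with unrounded values, and a run manifest sufficient to reproduce the
#' bundle.  CSV cells follow the reporting rounding rules (whole dollars
#' for per-patient values, two decimals for PMPM); the JSON mirror keeps
#' full precision — consumers needing exact values read the JSON.
#'
#' @param inputs A [payer_inputs()] object, or a path to a config file.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer; recorded in the manifest and used for the
#'   optional validation simulation.
#' @param simulate_n If > 0, also run [simulate_cohort()] with `simulate_n`
#'   patients per arm and write the summaries.
#' @param quiet Suppress the console summary.
#' @return The [run_bia()] result, invisibly.
#' @export
run_full_analysis <- function(inputs, out_dir, seed = NULL, simulate_n = 0,
                              quiet = FALSE) {
  config_path <- NULL
  if (is.character(inputs)) {
    config_path <- inputs
    inputs <- read_payer_inputs(inputs)
  }
  validate_payer_inputs(inputs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output dir %s", out_dir))

  res <- run_bia(inputs)

  pop <- dplyr::mutate(res$population, dplyr::across(
    c("eligible", "enrolled", "unenrolled", dplyr::starts_with("gold_")),
    ~ round_half_up(.x)
  ))
  per_patient <- dplyr::bind_rows(res$unenrolled, res$enrolled) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "cost") |>
    dplyr::mutate(
      difference = .data$enrolled - .data$unenrolled,
      dplyr::across(c("unenrolled", "enrolled", "difference"),
                    ~ render_currency(.x, "dollars"))
    )
  pmpm_out <- dplyr::mutate(pmpm_wide(res$pmpm), dplyr::across(
    c(dplyr::starts_with("year_"), "average"),
    ~ render_currency(.x, "pmpm")
  ))
  expend <- dplyr::mutate(res$expenditures,
                          expenditure = render_currency(.data$expenditure, "dollars"))

  utils::write.csv(pop, file.path(out_dir, "population.csv"), row.names = FALSE)
  utils::write.csv(per_patient, file.path(out_dir, "per_patient_costs.csv"),
                   row.names = FALSE)
  utils::write.csv(pmpm_out, file.path(out_dir, "pmpm.csv"), row.names = FALSE)
  utils::write.csv(expend, file.path(out_dir, "expenditures.csv"),
                   row.names = FALSE)

  g <- glance(res)
  summary_json <- list(
    payer = inputs$label,
    eligible = g$eligible,
    per_patient = list(unenrolled_total = g$unenrolled_total,
                       enrolled_total = g$enrolled_total,
                       saving = g$per_patient_saving),
    avg_pmpm_impact = g$avg_pmpm_impact,
    horizon_net_savings = g$horizon_net_savings,
    pmpm = pmpm_wide(res$pmpm)
  )
  if (simulate_n > 0) {
    sims <- lapply(c("unenrolled", "enrolled"), function(arm) {
      simulate_cohort(inputs, simulate_n, seed = seed %||% 1L, arm = arm)
    })
    summary_json$simulation <- setNames(sims, c("unenrolled", "enrolled"))
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  write_manifest(out_dir, subcommand = "run", config_path = config_path,
                 options = list(simulate_n = simulate_n), seed = seed)

  if (!quiet) {
    cat(sprintf("payer: %s\n", inputs$label))
    cat(sprintf("eligible COPD patients: %s\n",
                format(round_half_up(g$eligible), big.mark = ",")))
    cat(sprintf("per-patient annual saving: $%s\n",
                render_currency(g$per_patient_saving, "dollars")))
    cat(sprintf("average PMPM impact: %s\n",
                render_currency(g$avg_pmpm_impact, "pmpm")))
  }
  invisible(res)
}

#' Write a run manifest
#'
#' Every output bundle carries a manifest (config path, subcommand,
#' options, seed, package version, timestamp) sufficient to reproduce it.
#'
#' @param out_dir Output directory.
#' @param subcommand Character label of the operation.
#' @param config_path Path of the config used, if read from file.
#' @param options Named list of options.
#' @param seed Integer seed or `NULL`.
#' @return Path to the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, subcommand, config_path = NULL,
                           options = list(), seed = NULL) {
  manifest <- list(
    subcommand = subcommand,
    config = config_path,
    options = options,
    seed = seed,
    package = "copdbia",
    version = as.character(utils::packageVersion("copdbia")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(compact_null(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
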