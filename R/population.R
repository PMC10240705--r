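#' Eligible COPD patients in a plan
#'
#' Eligibility requires age >= 40 and COPD: the plan's 40--64 and 65+ age
#' bands are multiplied by the band-specific COPD prevalence and summed;
#' the under-40 band contributes nothing by construction.  The count is kept
#' real-valued internally; rounding to whole patients happens only in
#' reports.
#'
#' @param inputs A [payer_inputs()] object.
#' @return Number of eligible patients (real-valued).
#' @examples
#' eligible_patients(bia_config("commercial_replication"))  # 212200
#' @export
eligible_patients <- function(inputs) {
  inputs$plan_size * (inputs$age_shares[["age_40_64"]] * inputs$prevalence[["age_40_64"]] +
                        inputs$age_shares[["age_65_plus"]] * inputs$prevalence[["age_65_plus"]])
}

#' Enrolled and unenrolled counts under the uptake schedule
#'
#' Uptake is the fraction of the eligible population enrolled for the whole
#' of each year (no mid-year entry); the eligible population is held
#' constant over the horizon (no incidence, mortality, or disenrollment).
#'
#' @param eligible Eligible patient count (>= 0).
#' @param uptake Numeric vector of per-year market-penetration fractions.
#' @return Tibble with columns `year`, `uptake`, `enrolled`, `unenrolled`.
#' @export
enrolled_counts <- function(eligible, uptake) {
  if (eligible < 0) abort("eligible count must be ≥ 0")
  tibble(
    year = seq_along(uptake),
    uptake = as.numeric(uptake),
    enrolled = eligible * as.numeric(uptake),
    unenrolled = eligible * (1 - as.numeric(uptake))
  )
}

#' Partition a patient count across GOLD 2017 ABCD groups
#'
#' @param count Patient count (>= 0).
#' @param gold_shares Named fractions over groups A--D summing to 1.
#' @return Tibble with columns `gold_group`, `share`, `patients`
#'   (real-valued; the partition conserves the total exactly).
#' @export
gold_partition <- function(count, gold_shares) {
  if (count < 0) abort("count must be ≥ 0")
  shares <- unlist(gold_shares)[gold_groups]
  tibble(gold_group = gold_groups, share = unname(shares),
         patients = count * unname(shares))
}

#' Population table for one payer
#'
#' One row per horizon year: eligible, enrolled, unenrolled counts and the
#' GOLD-group partition of the eligible population.
#'
#' @param inputs A [payer_inputs()] object.
#' @return Tibble with columns `year`, `eligible`, `uptake`, `enrolled`,
#'   `unenrolled`, and `gold_A` .. `gold_D`.
#' @examples
#' population_table(bia_config("commercial_replication"))
#' @export
population_table <- function(inputs) {
  elig <- eligible_patients(inputs)
  counts <- enrolled_counts(elig, inputs$uptake)
  gold <- gold_partition(elig, inputs$gold_shares)
  gold_wide <- setNames(as.list(gold$patients), paste0("gold_", gold$gold_group))
  dplyr::mutate(counts, eligible = elig, !!!gold_wide,
                .after = "year")
}
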