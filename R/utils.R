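#' Round half away from zero
#'
#' Commercial rounding (half-up on the magnitude), as used by payer budget
#' tables: 6942.6 renders as 6943, -1.605 at two decimals as -1.60.  Base
#' [round()] applies banker's rounding and is not what printed budget tables
#' use.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(6942.6, 232.5, -1.605), c(0, 0, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny nudge guards against 0.49999999 artefacts of binary floats
  out <- sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
  out[out == 0] <- 0  # normalize IEEE -0 so it never renders as "-0.00"
  out
}

#' Render a currency amount for reporting
#'
#' All model arithmetic is carried unrounded; rounding happens exactly once,
#' here, at render time.  Three layers match the conventions of payer budget
#' tables: whole dollars with thousands separators, per-member-per-month at
#' two decimals, and plan-level aggregates in millions at one decimal.
#'
#' @param value Finite numeric vector (2020 USD).
#' @param layer One of `"dollars"`, `"pmpm"`, `"millions"`.
#' @return Character vector.
#' @examples
#' render_currency(6942.6, "dollars")     # "6,943"
#' render_currency(-1.60487, "pmpm")      # "-1.60"
#' render_currency(13894432, "millions")  # "13.9"
#' @export
render_currency <- function(value, layer = c("dollars", "pmpm", "millions")) {
  layer <- match.arg(layer)
  if (any(!is.finite(value))) {
    abort("`value` must be finite to render as currency.")
  }
  switch(layer,
    dollars = formatC(round_half_up(value, 0), format = "d", big.mark = ",",
                      flag = ""),
    pmpm = sprintf("%.2f", round_half_up(value, 2)),
    millions = sprintf("%.1f", round_half_up(value / 1e6, 1))
  )
}

# numeric value after render-time rounding, used by tests and reports
rendered_dollars <- function(value) round_half_up(value, 0)

compact_null <- function(x) x[!vapply(x, is.null, logical(1))]
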