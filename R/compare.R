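#' Convert a cumulative percent change to an annualized rate
#'
#' Geometric-mean standardization used to compare monitoring schemes with
#' different running times:
#' `100 * ((1 + cumulative/100)^(1/span) - 1)`.
#'
#' @param cumulative_percent Cumulative percent change (> -100).
#' @param span_years Years spanned (>= 1).
#' @return Percent change per year. Vectorized.
#' @examples
#' cumulative_to_annual(-40, 25) # about -2.0
#' @export
cumulative_to_annual <- function(cumulative_percent, span_years) {
  if (any(cumulative_percent <= -100)) {
    abort("Cumulative change must be greater than -100%.")
  }
  if (any(span_years < 1)) abort("`span_years` must be >= 1.")
  100 * ((1 + cumulative_percent / 100)^(1 / span_years) - 1)
}

#' Convert an annualized rate to a cumulative percent change
#'
#' Exact inverse of [cumulative_to_annual()]:
#' `100 * ((1 + annual/100)^span - 1)`.
#'
#' @param annual_percent Percent change per year (> -100).
#' @param span_years Years spanned (>= 1).
#' @return Cumulative percent change. Vectorized.
#' @export
annual_to_cumulative <- function(annual_percent, span_years) {
  if (any(annual_percent <= -100)) {
    abort("Annual change must be greater than -100%.")
  }
  if (any(span_years < 1)) abort("`span_years` must be >= 1.")
  100 * ((1 + annual_percent / 100)^span_years - 1)
}

#' Published European scheme summaries for cross-scheme comparison
#'
#' Reference rows for three long-running European butterfly monitoring
#' programmes (the UK scheme split into its countryside and specialist
#' indicators, the Dutch scheme, and the Catalan scheme): study span,
#' site counts, reported cumulative and annualized total-abundance
#' trends, and tallies of positive/negative/stable species trends as
#' published by each programme.
#'
#' @return A tibble with one row per scheme indicator.
#' @export
european_schemes <- function() {
  tibble(
    region = c("United Kingdom (countryside)", "United Kingdom (specialist)",
               "Netherlands", "Catalonia"),
    span_years = c(41, 41, 25, 22),
    n_sites = c(3164, 3164, 600, 116),
    cumulative_percent = c(-28, -63, -40, -44),
    annual_percent = c(-0.8, -2.4, -2.0, -2.6),
    species_positive = c(11, 11, 11, 15),
    species_negative = c(22, 22, 23, 46),
    species_stable = c(24, 24, 13, 5)
  )
}

#' Assemble a cross-scheme comparison table
#'
#' Recomputes each scheme's annualized rate from its cumulative change and
#' span with the geometric-mean formula, and flags rows whose reported
#' annual rate disagrees with the recomputed one by more than
#' `tolerance` percentage points.
#'
#' @param schemes Tibble like [european_schemes()]: `region`,
#'   `span_years`, `cumulative_percent`, and optionally `annual_percent`
#'   and the species tallies.
#' @param tolerance Allowed |reported - recomputed| in percentage points
#'   (default 0.05).
#' @return The input with `annual_recomputed` and logical `inconsistent`
#'   columns added.
#' @export
build_comparison_table <- function(schemes, tolerance = 0.05) {
  if (nrow(schemes) < 1) abort("Need at least one scheme.")
  out <- schemes |>
    mutate(annual_recomputed = cumulative_to_annual(.data$cumulative_percent,
                                                    .data$span_years))
  if ("annual_percent" %in% names(out)) {
    out <- mutate(out, inconsistent = abs(.data$annual_percent -
                                            .data$annual_recomputed) > tolerance)
  } else {
    out <- mutate(out, annual_percent = .data$annual_recomputed,
                  inconsistent = FALSE)
  }
  out
}
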