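#' Read and write survey tables as CSV
#'
#' The on-disk format is the long survey table: one row per
#' site x year x week x species with columns `site_id`, `year`, `week`,
#' `survey_date`, `duration_min`, `species_id`, `count`, `surveyed`.
#'
#' @param surveys Long survey tibble.
#' @param path File path.
#' @return `write_survey_csv()` returns `surveys` invisibly;
#'   `read_survey_csv()` returns the tibble with types restored.
#' @export
write_survey_csv <- function(surveys, path) {
  readr::write_csv(surveys, path)
  invisible(surveys)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    year = readr::col_integer(),
    week = readr::col_integer(),
    survey_date = readr::col_date(),
    duration_min = readr::col_double(),
    species_id = readr::col_character(),
    count = readr::col_integer(),
    surveyed = readr::col_logical()
  ))
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields map directly onto [sim_config()] arguments; a
#' `species_specs` entry may give either `n_species` (plus optional
#' `annual_trend` and `seed`) to regenerate a community, or a path to a
#' CSV of explicit species rows (with `brood_peaks_gdd` as
#' semicolon-separated degree-day positions).
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sp_cfg <- raw$species_specs
  raw$species_specs <- NULL
  args <- raw
  if (!is.null(sp_cfg$csv)) {
    sp <- readr::read_csv(sp_cfg$csv, show_col_types = FALSE) |>
      mutate(brood_peaks_gdd = purrr::map(
        strsplit(as.character(.data$brood_peaks_gdd), ";"),
        as.numeric))
    args$species_specs <- sp
  } else if (!is.null(sp_cfg)) {
    args$species_specs <- do.call(sim_species_specs, sp_cfg)
  }
  do.call(sim_config, args)
}

#' Write the generator's ground truth as JSON
#'
#' Serializes the true species parameters and the realized site, year and
#' observation effects of a simulated dataset so downstream recovery
#' checks can be run without the generating R session.
#'
#' @param sim A `pollard_sim` from [simulate_monitoring()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "pollard_sim"))
  tr <- sim$truth
  obj <- list(
    species = tr$species |> mutate(
      brood_peaks_gdd = purrr::map_chr(.data$brood_peaks_gdd,
                                       ~ paste(round(.x, 2), collapse = ";"))),
    site_effects = tr$site_effects,
    year_effects = tr$year_effects,
    obs_effects = tr$obs_effects,
    year_mid = tr$year_mid
  )
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write a population-index table as CSV
#'
#' @param indices A `PopulationIndexTable`.
#' @param path File path.
#' @return `indices`, invisibly.
#' @export
write_index_csv <- function(indices, path) {
  readr::write_csv(indices, path)
  invisible(indices)
}

#' Write a species trend table as CSV
#'
#' One row per species mirroring the usual scheme report layout: sample
#' sizes, the year coefficient with SE and p-value, the classification,
#' and annual/cumulative percent rates.
#'
#' @param trend_table Tibble as produced by the per-species trend loop
#'   (see the vignette).
#' @param path File path.
#' @return `trend_table`, invisibly.
#' @export
write_trend_csv <- function(trend_table, path) {
  readr::write_csv(trend_table, path)
  invisible(trend_table)
}
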