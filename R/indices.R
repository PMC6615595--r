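#' Trapezoid population index over a weekly count series
#'
#' Integrates an ordered series of weekly counts (observed plus imputed)
#' with the trapezoid rule at unit week spacing:
#' `sum((c[i] + c[i+1]) / 2)` over consecutive weeks. The result has units
#' of butterfly-weeks.
#'
#' @param weekly_counts Numeric vector of length >= 2, nonnegative, no
#'   missing entries (imputation must already have been applied).
#' @return A single nonnegative number.
#' @examples
#' trapezoid_index(c(0, 2, 4, 2, 0)) # 8
#' @export
trapezoid_index <- function(weekly_counts) {
  if (length(weekly_counts) < 2) abort("Need at least 2 weekly counts.")
  if (anyNA(weekly_counts)) abort("Missing entries: impute before integrating.")
  if (any(weekly_counts < 0)) abort("Negative counts are not allowed.")
  n <- length(weekly_counts)
  sum((weekly_counts[-n] + weekly_counts[-1]) / 2)
}

#' Mean list-length of the surveys in one site-year
#'
#' List-length is the number of species recorded (count > 0) in a survey,
#' a synthetic proxy for effort and conditions. Only observed (non-imputed)
#' surveys contribute.
#'
#' @param surveys Long survey rows for one site-year: `week`, `species_id`,
#'   `count`, `surveyed`.
#' @return Mean species per survey over the surveyed weeks.
#' @export
mean_list_length <- function(surveys) {
  obs <- filter(surveys, .data$surveyed)
  if (nrow(obs) == 0) abort("No surveyed weeks: list-length undefined.")
  obs |>
    group_by(.data$week) |>
    summarise(n_species = sum(.data$count > 0, na.rm = TRUE), .groups = "drop") |>
    pull(.data$n_species) |>
    mean()
}

#' Projected total survey duration for one site-year
#'
#' The total duration the site-year would have accumulated had every week
#' of the season been surveyed at its mean observed duration; used as the
#' model offset so that trends are rates of butterflies per minute.
#'
#' @param surveys Survey rows for one site-year with `week`,
#'   `duration_min`, `surveyed`.
#' @param weeks_per_season Season length in weeks (default 30).
#' @return Projected duration in minutes.
#' @export
projected_duration <- function(surveys, weeks_per_season = 30) {
  obs <- distinct(filter(surveys, .data$surveyed), .data$week, .data$duration_min)
  if (nrow(obs) == 0) abort("No surveyed weeks: projected duration undefined.")
  if (anyNA(obs$duration_min)) abort("Missing durations on surveyed weeks.")
  weeks_per_season * mean(obs$duration_min)
}

#' Build the population-index table from completed weekly counts
#'
#' One row per site x year x species: the trapezoid index over the
#' completed weekly series, plus the sampling covariates (mean list-length
#' and projected duration, both computed from observed surveys only) and
#' the number of surveyed weeks.
#'
#' @param completed Completed count table (all modelled species):
#'   `site_id`, `year`, `week`, `species_id`, `count` (no NAs within used
#'   site-years), `surveyed`, `duration_min`.
#' @param surveys Optional raw survey table from which the sampling
#'   covariates are computed. Transect lists record every species seen,
#'   not only the species that end up with fitted phenology models, so
#'   list-length should be taken from the full record when it is
#'   available; the default falls back to the observed rows of
#'   `completed`.
#' @param weeks_per_season Season length in weeks.
#' @return A `PopulationIndexTable` tibble: `site_id`, `year`,
#'   `species_id`, `index`, `mean_list_length`,
#'   `projected_duration_min`, `n_surveys`.
#' @export
population_indices <- function(completed, surveys = NULL,
                               weeks_per_season = 30) {
  covar_src <- (surveys %||% completed) |> filter(.data$surveyed)
  covars <- covar_src |>
    group_by(.data$site_id, .data$year, .data$week) |>
    summarise(n_species = sum(.data$count > 0, na.rm = TRUE),
              duration_min = .data$duration_min[1], .groups = "drop_last") |>
    summarise(mean_list_length = mean(.data$n_species),
              projected_duration_min = weeks_per_season * mean(.data$duration_min),
              n_surveys = n(), .groups = "drop")
  completed |>
    group_by(.data$site_id, .data$year, .data$species_id) |>
    arrange(.data$week, .by_group = TRUE) |>
    summarise(index = trapezoid_index(.data$count), .groups = "drop") |>
    left_join(covars, by = c("site_id", "year"))
}

#' Apply the trend-analysis inclusion filters
#'
#' Site-years qualify when they have at least `min_surveys_per_year`
#' surveyed weeks; sites are retained when they contribute at least
#' `min_years_per_site` qualifying years. Species are flagged eligible for
#' species-level trend models when they were recorded (observed count > 0)
#' at `min_sites_species` or more retained sites and in
#' `min_years_species` or more years; all species remain in the table for
#' the total-abundance aggregation.
#'
#' @param indices A `PopulationIndexTable` from [population_indices()].
#' @param surveys The raw long survey table (used for observed presences).
#' @param min_years_per_site,min_surveys_per_year Site-level thresholds
#'   (defaults 3 years, 10 surveys).
#' @param min_sites_species,min_years_species Species-level thresholds
#'   (defaults 5 sites, 10 years).
#' @return A list with `indices` (the filtered table) and `species`
#'   (tibble: `species_id`, `n_sites_present`, `n_years_present`,
#'   `eligible`).
#' @export
apply_trend_filters <- function(indices, surveys,
                                min_years_per_site = 3,
                                min_surveys_per_year = 10,
                                min_sites_species = 5,
                                min_years_species = 10) {
  if (nrow(indices) == 0) {
    return(list(indices = indices,
                species = tibble(species_id = character(),
                                 n_sites_present = integer(),
                                 n_years_present = integer(),
                                 eligible = logical())))
  }
  qualifying <- indices |>
    distinct(.data$site_id, .data$year, .data$n_surveys) |>
    filter(.data$n_surveys >= min_surveys_per_year)
  keep_sites <- qualifying |>
    dplyr::count(.data$site_id) |>
    filter(.data$n >= min_years_per_site) |>
    pull(.data$site_id)
  kept <- indices |>
    inner_join(qualifying |> select("site_id", "year"),
               by = c("site_id", "year")) |>
    filter(.data$site_id %in% keep_sites)

  presence <- surveys |>
    filter(.data$surveyed, .data$count > 0,
           .data$site_id %in% keep_sites) |>
    inner_join(distinct(kept, .data$site_id, .data$year),
               by = c("site_id", "year"))
  species_map <- indices |>
    distinct(.data$species_id) |>
    left_join(
      presence |>
        group_by(.data$species_id) |>
        summarise(n_sites_present = dplyr::n_distinct(.data$site_id),
                  n_years_present = dplyr::n_distinct(.data$year),
                  .groups = "drop"),
      by = "species_id") |>
    mutate(
      n_sites_present = dplyr::coalesce(.data$n_sites_present, 0L),
      n_years_present = dplyr::coalesce(.data$n_years_present, 0L),
      eligible = .data$n_sites_present >= min_sites_species &
        .data$n_years_present >= min_years_species
    )
  list(indices = kept, species = species_map)
}

#' Aggregate population indices across species to total abundance
#'
#' Sums indices over species within each site-year; sampling covariates
#' are carried through unchanged (they are site-year properties). A
#' site-year whose species indices are all zero is retained with a zero
#' total.
#'
#' @param indices A (filtered) `PopulationIndexTable`.
#' @return One row per site x year with the summed `index`.
#' @export
total_abundance_indices <- function(indices) {
  chk <- indices |>
    distinct(.data$site_id, .data$year, .data$mean_list_length,
             .data$projected_duration_min, .data$n_surveys) |>
    dplyr::count(.data$site_id, .data$year)
  if (any(chk$n > 1)) {
    abort("Conflicting covariate values within a site-year: corrupt input.")
  }
  indices |>
    group_by(.data$site_id, .data$year) |>
    summarise(index = sum(.data$index),
              mean_list_length = .data$mean_list_length[1],
              projected_duration_min = .data$projected_duration_min[1],
              n_surveys = .data$n_surveys[1],
              .groups = "drop")
}

#' Index rows for one species' trend model
#'
#' Restricts the filtered index table to site-years at sites where the
#' species was ever recorded, so that structural absences (sites outside
#' the species' range) do not enter its trend model, while zero-index
#' site-years within occupied sites do.
#'
#' @param indices Filtered `PopulationIndexTable` (all species rows).
#' @param surveys Raw long survey table.
#' @param species One `species_id`.
#' @return The species' index rows at its occupied sites.
#' @export
species_index_rows <- function(indices, surveys, species) {
  occupied <- surveys |>
    filter(.data$species_id == species, .data$surveyed, .data$count > 0) |>
    distinct(.data$site_id)
  indices |>
    filter(.data$species_id == species) |>
    inner_join(occupied, by = "site_id")
}
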