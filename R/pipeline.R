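#' Join surveys to degree-days and site coordinates
#'
#' Attaches each survey week's accumulated degree-days (from the weekly
#' schedule derived from daily temperatures) and the site coordinates,
#' producing the table the phenology models train on.
#'
#' @param surveys Long survey tibble.
#' @param temperatures Daily temperature tibble.
#' @param sites Site tibble with `site_id`, `lat`, `lon`.
#' @param weeks_per_season,season_start_doy,base Passed to
#'   [degree_day_schedule()].
#' @return The survey rows with `gdd`, `gdd_lo`, `gdd_hi`, `lat`, `lon`.
#' @export
prepare_survey_gdd <- function(surveys, temperatures, sites,
                               weeks_per_season = 30, season_start_doy = 91,
                               base = 5) {
  sched <- degree_day_schedule(temperatures,
                               weeks_per_season = weeks_per_season,
                               season_start_doy = season_start_doy,
                               base = base)
  surveys |>
    left_join(sched |> select("site_id", "year", "week", "gdd", "gdd_lo",
                              "gdd_hi"),
              by = c("site_id", "year", "week")) |>
    left_join(sites |> select("site_id", "lat", "lon"), by = "site_id")
}

#' Fit flight-curve models for every species
#'
#' Restricts to phenology-eligible site-years, then fits one regional
#' flight-curve model per species. Species that refuse to fit (too few
#' nonzero counts, or no signal) are skipped with a warning.
#'
#' @param survey_gdd Output of [prepare_survey_gdd()].
#' @param min_surveys Phenology eligibility threshold per site-year.
#' @param ... Passed to [fit_flight_curve()].
#' @return A named list of `flight_curve` objects (skipped species are
#'   absent).
#' @export
fit_flight_curves <- function(survey_gdd, min_surveys = 5, ...) {
  eligible <- eligible_for_phenology(survey_gdd, min_surveys = min_surveys)
  species <- sort(unique(eligible$species_id))
  curves <- purrr::map(species, function(sp) {
    tryCatch(
      fit_flight_curve(filter(eligible, .data$species_id == sp), ...),
      error = function(e) {
        warn(paste0("Skipping flight curve for ", sp, ": ",
                    conditionMessage(e)))
        NULL
      })
  })
  names(curves) <- species
  purrr::compact(curves)
}

#' Complete the weekly count table for every modelled species
#'
#' Applies [impute_missing_counts()] species by species over the
#' phenology-eligible site-years, returning one completed long table.
#'
#' @param survey_gdd Output of [prepare_survey_gdd()].
#' @param curves Named list from [fit_flight_curves()].
#' @param min_surveys Phenology eligibility threshold per site-year.
#' @return Completed counts (species without a model are dropped).
#' @export
complete_counts <- function(survey_gdd, curves, min_surveys = 5) {
  eligible <- eligible_for_phenology(survey_gdd, min_surveys = min_surveys)
  purrr::imap(curves, function(curve, sp) {
    impute_missing_counts(filter(eligible, .data$species_id == sp), curve)
  }) |>
    purrr::list_rbind()
}

#' Run the full abundance-trend pipeline on a monitoring dataset
#'
#' Degree-day schedule, per-species flight curves, imputation of missed
#' weeks, trapezoid population indices with effort covariates, inclusion
#' filters, aggregation to total abundance, and the overdispersed Poisson
#' trend model for the total.
#'
#' @param sim A `pollard_sim`, or a list with `surveys`, `temperatures`,
#'   `sites`.
#' @param species Character vector of focal species to model. Defaults to
#'   the simulation's focal species; survey lists typically record many
#'   more species than are modelled, and the extra records still feed the
#'   list-length covariate.
#' @param weeks_per_season,season_start_doy Season layout.
#' @param min_surveys_phenology Site-year eligibility for phenology models.
#' @param engine Passed to [fit_flight_curve()].
#' @param ... Further arguments to [apply_trend_filters()].
#' @return A list of class `pollard_pipeline`: `curves`, `completed`,
#'   `indices` (all species, filtered), `species` eligibility map,
#'   `total_indices`, and `total_fit` (a `trend_fit`).
#' @export
run_abundance_pipeline <- function(sim, species = NULL,
                                   weeks_per_season = 30,
                                   season_start_doy = 91,
                                   min_surveys_phenology = 5,
                                   engine = "auto", ...) {
  species <- species %||%
    (if (!is.null(sim$truth$config$species_specs)) {
      sim$truth$config$species_specs$species_id
    } else {
      unique(sim$surveys$species_id)
    })
  survey_gdd <- prepare_survey_gdd(sim$surveys, sim$temperatures, sim$sites,
                                   weeks_per_season = weeks_per_season,
                                   season_start_doy = season_start_doy) |>
    filter(.data$species_id %in% species)
  curves <- fit_flight_curves(survey_gdd,
                              min_surveys = min_surveys_phenology,
                              engine = engine)
  completed <- complete_counts(survey_gdd, curves,
                               min_surveys = min_surveys_phenology)
  indices <- population_indices(completed, surveys = sim$surveys,
                                weeks_per_season = weeks_per_season)
  filtered <- apply_trend_filters(indices, sim$surveys, ...)
  total <- total_abundance_indices(filtered$indices)
  total_fit <- fit_trend_glmm(total)
  structure(list(
    curves = curves,
    completed = completed,
    indices = filtered$indices,
    species = filtered$species,
    total_indices = total,
    total_fit = total_fit
  ), class = "pollard_pipeline")
}

#' @export
print.pollard_pipeline <- function(x, ...) {
  cat(sprintf(
    "Abundance pipeline: %d flight curves, %d site-year indices, %d eligible species\n",
    length(x$curves), nrow(x$total_indices), sum(x$species$eligible)))
  print(x$total_fit)
  invisible(x)
}

#' Fit per-species trend models
#'
#' Loops the trend GLMM over the species flagged eligible by
#' [apply_trend_filters()], restricting each species to its occupied
#' sites, and assembles a scheme-report-style table.
#'
#' @param pipeline A `pollard_pipeline`, or a list with `indices` and
#'   `species` elements.
#' @param surveys Raw long survey table (for occupied-site restriction
#'   and total-counted tallies).
#' @param alpha Classification threshold.
#' @return A tibble with one row per fitted species: sample sizes, the
#'   year coefficient, SE, p-value, annual rate, and classification.
#'   Species whose model fails are reported with NA estimates.
#' @export
fit_species_trends <- function(pipeline, surveys, alpha = 0.05) {
  eligible <- pipeline$species |> filter(.data$eligible) |> pull(.data$species_id)
  purrr::map(eligible, function(sp) {
    rows <- species_index_rows(pipeline$indices, surveys, sp)
    totals <- surveys |>
      filter(.data$species_id == sp, .data$surveyed) |>
      summarise(total_counted = sum(.data$count, na.rm = TRUE))
    base <- tibble(
      species_id = sp,
      total_counted = totals$total_counted,
      n_sites = dplyr::n_distinct(rows$site_id),
      n_years = dplyr::n_distinct(rows$year),
      n_site_years = nrow(rows)
    )
    fit <- tryCatch(fit_trend_glmm(rows), error = function(e) NULL)
    if (is.null(fit)) {
      return(mutate(base, beta_year = NA_real_, std_error = NA_real_,
                    p_value = NA_real_, annual_rate_percent = NA_real_,
                    classification = factor(NA, levels = c("negative", "stable",
                                                           "positive"))))
    }
    yr <- summarize_trend(fit, alpha = alpha)
    mutate(base, beta_year = yr$beta_year, std_error = yr$std_error,
           p_value = yr$p_value,
           annual_rate_percent = yr$annual_rate_percent,
           classification = yr$classification)
  }) |>
    purrr::list_rbind() |>
    arrange(.data$beta_year)
}
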