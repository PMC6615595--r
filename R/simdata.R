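#' Synthetic species specifications for a monitoring simulation
#'
#' Draws a community of butterfly species with flight curves expressed as
#' Gaussian mixtures in accumulated growing degree-days (GDD, base 5 degC):
#' one mixture component per brood, so univoltine species get one peak,
#' bivoltine two, and multivoltine three. Baseline abundance, voltinism mix,
#' and life-history traits are drawn once so that every species carries the
#' covariates the trait-association models consume.
#'
#' @param n_species Number of species to generate.
#' @param annual_trend True log-scale abundance trend per year shared by all
#'   species (default `log(0.98)`, a 2% annual decline). May be a vector of
#'   length `n_species` for heterogeneous trends.
#' @param prop_voltinism Probabilities for univoltine, bivoltine and
#'   multivoltine species (in that order; normalised internally).
#' @param prop_migratory Probability that a species is migratory.
#' @param baseline_mean,baseline_sd Mean and SD of the species' baseline
#'   log abundance (log expected count at unit flight-curve mass and mean
#'   survey duration).
#' @param seed Integer seed; the same seed reproduces the same community.
#' @return A tibble with one row per species: identifiers, voltinism, brood
#'   peaks (`brood_peaks_gdd`, a list column of degree-day positions),
#'   brood SD, baseline log abundance, true annual trend, and trait columns
#'   (`range_position`, `overwinter_stage`, `host_category`, `host_breadth`,
#'   `wing_length_mm`, `wetland_dependent`, `disturbance_tolerant`,
#'   `migratory`).
#' @export
sim_species_specs <- function(n_species = 100,
                              annual_trend = log(0.98),
                              prop_voltinism = c(0.45, 0.35, 0.20),
                              prop_migratory = 0.15,
                              baseline_mean = 3,
                              baseline_sd = 1.2,
                              seed = 1L) {
  stopifnot(n_species >= 1, length(prop_voltinism) == 3, all(prop_voltinism >= 0))
  if (!length(annual_trend) %in% c(1L, n_species)) {
    abort("`annual_trend` must have length 1 or `n_species`.")
  }
  withr::with_seed(seed, {
    voltinism <- sample(c("univoltine", "bivoltine", "multivoltine"),
                        n_species, replace = TRUE,
                        prob = prop_voltinism / sum(prop_voltinism))
    n_broods <- c(univoltine = 1L, bivoltine = 2L, multivoltine = 3L)[voltinism]
    peaks <- purrr::map(n_broods, function(k) {
      if (k == 1L) {
        runif(1, 450, 1600)
      } else {
        first <- runif(1, 250, 700)
        first + cumsum(c(0, runif(k - 1, 450, 750)))
      }
    })
    tibble(
      species_id = sprintf("sp%03d", seq_len(n_species)),
      voltinism = voltinism,
      brood_peaks_gdd = peaks,
      brood_sd_gdd = runif(n_species, 80, 150),
      baseline_log_abundance = rnorm(n_species, baseline_mean, baseline_sd),
      annual_trend = rep_len(annual_trend, n_species),
      migratory = runif(n_species) < prop_migratory,
      range_position = sample(c("Southern", "core", "Northern"), n_species,
                              replace = TRUE, prob = c(0.2, 0.55, 0.25)),
      overwinter_stage = ifelse(
        migratory, "migrant",
        sample(c("egg", "larva", "pupa", "adult"), n_species,
               replace = TRUE, prob = c(0.15, 0.5, 0.25, 0.1))),
      host_category = sample(c("forb", "graminoid", "woody"), n_species,
                             replace = TRUE, prob = c(0.5, 0.2, 0.3)),
      host_breadth = sample(c("one family-or-genus", "multiple families"),
                            n_species, replace = TRUE, prob = c(0.6, 0.4)),
      wing_length_mm = rlnorm(n_species, log(25), 0.3),
      wetland_dependent = runif(n_species) < 0.15,
      disturbance_tolerant = runif(n_species) < 0.4
    )
  })
}

#' Synthetic monitoring sites on a latitudinal temperature gradient
#'
#' @param n_sites Number of transect sites.
#' @param lat_range,lon_range Ranges (degrees) over which site coordinates
#'   are drawn uniformly; defaults span Ohio.
#' @param seed Integer seed.
#' @return A tibble with `site_id`, `lat`, `lon`.
#' @export
sim_sites <- function(n_sites = 104,
                      lat_range = c(38.4, 41.7),
                      lon_range = c(-84.8, -80.5),
                      seed = 1L) {
  stopifnot(n_sites >= 1)
  withr::with_seed(seed, tibble(
    site_id = sprintf("site%03d", seq_len(n_sites)),
    lat = runif(n_sites, lat_range[1], lat_range[2]),
    lon = runif(n_sites, lon_range[1], lon_range[2])
  ))
}

#' Configuration for a synthetic Pollard-walk monitoring dataset
#'
#' Bundles and validates every knob of the generator. Defaults reproduce the
#' structure of a 21-season statewide scheme: 104 sites, 30-week
#' April-October seasons with weeks missed completely at random at rate 7/30
#' (so a median of about 23 of 30 weeks are surveyed), surveys averaging 85
#' minutes, and log-scale random-effect SDs of 0.417 (site), 0.121 (year)
#' and 0.278 (site-by-year observation).
#'
#' @param n_sites,n_years,weeks_per_season Design dimensions.
#' @param species_specs Species table from [sim_species_specs()].
#' @param sd_site,sd_year,sd_obs Log-scale SDs of the site, year, and
#'   site-by-year (observation-level) random intercepts.
#' @param missing_week_prob Probability that a scheduled week goes
#'   unsurveyed, independently of everything else.
#' @param duration_mean_minutes,duration_sd_minutes Mean and SD of the
#'   log-normal survey-duration distribution (truncated below at 10 min).
#' @param listlength_effect Log-scale slope of focal-species counts per
#'   species listed in the survey (default 0.104): surveys that record a
#'   longer species list are better surveys (conditions, observer), and
#'   every count rises accordingly. This is how effort/conditions
#'   confounding enters the generator, and it is what the trend model's
#'   list-length covariate adjusts for.
#' @param n_incidental_species Size of the background community pool.
#'   Real transect lists are dominated by species outside any focal
#'   modelling set; each background species is listed with its own
#'   per-survey probability, modulated by a latent survey-quality factor,
#'   giving the species list realistic exogenous variation.
#' @param incidental_p_range Range of the per-survey listing
#'   probabilities across the background pool.
#' @param quality_coupling Logit-scale effect of the latent survey
#'   quality on background listing probabilities.
#' @param temp_gradient_per_degree_lat Cooling (degC) per degree latitude
#'   northward in mean annual temperature.
#' @param first_year First calendar year of monitoring.
#' @param season_start_doy Day of year on which week 1 starts (April 1).
#' @param seed Integer master seed; all generator sub-streams derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 104,
                       n_years = 21,
                       weeks_per_season = 30,
                       species_specs = sim_species_specs(seed = seed),
                       sd_site = 0.417,
                       sd_year = 0.121,
                       sd_obs = 0.278,
                       missing_week_prob = 7 / 30,
                       duration_mean_minutes = 85,
                       duration_sd_minutes = 30,
                       listlength_effect = 0.104,
                       n_incidental_species = 60,
                       incidental_p_range = c(0.05, 0.35),
                       quality_coupling = 0.3,
                       temp_gradient_per_degree_lat = 1.5,
                       first_year = 1996,
                       season_start_doy = 91,
                       seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites), n_years = as.integer(n_years),
    weeks_per_season = as.integer(weeks_per_season),
    species_specs = species_specs,
    sd_site = sd_site, sd_year = sd_year, sd_obs = sd_obs,
    missing_week_prob = missing_week_prob,
    duration_mean_minutes = duration_mean_minutes,
    duration_sd_minutes = duration_sd_minutes,
    listlength_effect = listlength_effect,
    n_incidental_species = as.integer(n_incidental_species),
    incidental_p_range = incidental_p_range,
    quality_coupling = quality_coupling,
    temp_gradient_per_degree_lat = temp_gradient_per_degree_lat,
    first_year = as.integer(first_year),
    season_start_doy = as.integer(season_start_doy),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_sites < 1) abort("`n_sites` must be >= 1.")
    if (n_years < 2) abort("`n_years` must be >= 2.")
    if (weeks_per_season < 2) abort("`weeks_per_season` must be >= 2.")
    if (any(c(sd_site, sd_year, sd_obs, listlength_effect) < 0)) {
      abort("Random-effect SDs must be >= 0.")
    }
    if (missing_week_prob < 0 || missing_week_prob >= 1) {
      abort("`missing_week_prob` must be in [0, 1).")
    }
    if (duration_mean_minutes <= 0) abort("`duration_mean_minutes` must be positive.")
    if (n_incidental_species < 0) abort("`n_incidental_species` must be >= 0.")
  })
  validate_species_specs(cfg$species_specs)
  cfg
}

validate_species_specs <- function(sp) {
  need <- c("species_id", "voltinism", "brood_peaks_gdd", "brood_sd_gdd",
            "baseline_log_abundance", "annual_trend")
  missing_cols <- setdiff(need, names(sp))
  if (length(missing_cols)) {
    abort(paste0("species_specs lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(sp$species_id)) abort("Duplicated species_id in species_specs.")
  if (any(sp$brood_sd_gdd <= 0)) abort("brood_sd_gdd must be positive.")
  n_broods <- lengths(sp$brood_peaks_gdd)
  ok <- (sp$voltinism == "univoltine" & n_broods == 1) |
    (sp$voltinism == "bivoltine" & n_broods == 2) |
    (sp$voltinism == "multivoltine" & n_broods >= 3)
  if (!all(ok)) {
    abort(paste0("Brood count inconsistent with voltinism for: ",
                 paste(sp$species_id[!ok], collapse = ", ")))
  }
  invisible(sp)
}

#' Simulate daily site temperatures on a latitudinal gradient
#'
#' Daily mean temperature is a sinusoid of day-of-year (warmest in mid July)
#' plus a site offset that cools with latitude plus optional day-level
#' noise; `tmin`/`tmax` sit symmetrically a fixed diurnal range apart, so
#' `tmax >= tmin` always holds.
#'
#' @param sites Tibble with `site_id` and `lat` (finite latitudes required).
#' @param years Number of calendar years to simulate (>= 1).
#' @param first_year First calendar year.
#' @param mean_annual Mean annual temperature (degC) at `lat_ref`.
#' @param amplitude Seasonal half-amplitude (degC).
#' @param diurnal_range Fixed `tmax - tmin` (degC).
#' @param noise_sd SD of day-level noise added to the daily mean (degC).
#' @param gradient_per_degree_lat Cooling per degree latitude (degC).
#' @param lat_ref Reference latitude for `mean_annual`.
#' @param seed Integer seed.
#' @return A tibble with `site_id`, `date`, `year`, `doy`, `tmin`, `tmax`.
#' @export
simulate_temperatures <- function(sites, years,
                                  first_year = 1996,
                                  mean_annual = 11,
                                  amplitude = 12,
                                  diurnal_range = 10,
                                  noise_sd = 2.5,
                                  gradient_per_degree_lat = 1.5,
                                  lat_ref = 40,
                                  seed = 1L) {
  if (!all(is.finite(sites$lat))) abort("Non-finite latitude in `sites`.")
  stopifnot(years >= 1)
  days <- tidyr::expand_grid(
    year = first_year + seq_len(years) - 1L,
    doy = 1:365
  )
  grid <- tidyr::expand_grid(sites[c("site_id", "lat")], days)
  withr::with_seed(seed, {
    noise <- if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
    grid |>
      mutate(
        tmid = mean_annual - gradient_per_degree_lat * (.data$lat - lat_ref) +
          amplitude * cospi(2 * (.data$doy - 200) / 365) + noise,
        tmin = .data$tmid - diurnal_range / 2,
        tmax = .data$tmid + diurnal_range / 2,
        date = as.Date(.data$doy - 1, origin = paste0(.data$year, "-01-01"))
      ) |>
      select("site_id", "date", "year", "doy", "tmin", "tmax")
  })
}

#' Simulate a Pollard-walk monitoring dataset with known ground truth
#'
#' Generates site temperatures, converts them to accumulated degree-days,
#' and draws weekly transect counts for every focal species. The expected
#' count for a surveyed week is
#' `exp(baseline + trend * (year - midyear) + site + year + obs effects +
#' listlength_effect * (list deviation)) *
#' (flight-curve mass in the week's degree-day window) *
#' (duration / mean duration)`, with counts Poisson conditional on the
#' log-normal site-by-year observation effect (an overdispersed Poisson).
#' Weeks are dropped completely at random at `missing_week_prob`.
#'
#' Alongside the focal species, each survey also lists a draw from a
#' background community of incidental species (singleton records) whose
#' per-survey richness varies with a latent survey-quality factor. These
#' records give the survey's species list the exogenous variation that
#' list-length covariates are meant to capture; the list deviation above
#' is the background richness minus its expectation, so longer-list
#' surveys also yield higher focal counts.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `pollard_sim` with elements `surveys` (long
#'   tibble: site_id, year, week, survey_date, duration_min, species_id,
#'   count, surveyed; background records carry `inc` species ids),
#'   `temperatures`, `sites`, and `truth` (true species parameters and
#'   realised site/year/observation effects).
#' @export
simulate_monitoring <- function(config) {
  config <- validate_sim_config(config)
  seeds <- withr::with_seed(config$seed, sample.int(.Machine$integer.max, 6))
  sites <- sim_sites(config$n_sites, seed = seeds[1])
  temps <- simulate_temperatures(
    sites, config$n_years, first_year = config$first_year,
    gradient_per_degree_lat = config$temp_gradient_per_degree_lat,
    seed = seeds[2]
  )
  sched <- degree_day_schedule(temps,
                               weeks_per_season = config$weeks_per_season,
                               season_start_doy = config$season_start_doy)

  years <- config$first_year + seq_len(config$n_years) - 1L
  year_mid <- mean(years)
  sp <- config$species_specs

  effects <- withr::with_seed(seeds[3], {
    site_eff <- tibble(site_id = sites$site_id,
                       site_effect = rnorm(nrow(sites), 0, config$sd_site))
    year_eff <- tibble(year = years,
                       year_effect = rnorm(length(years), 0, config$sd_year))
    obs_eff <- tidyr::expand_grid(site_id = sites$site_id, year = years) |>
      mutate(obs_effect = rnorm(n(), 0, config$sd_obs))
    list(site = site_eff, year = year_eff, obs = obs_eff)
  })

  # survey-level design: missingness, duration, latent quality, and the
  # incidental species listed from the background community
  incidental <- NULL
  design <- withr::with_seed(seeds[4], {
    m <- config$duration_mean_minutes
    s <- config$duration_sd_minutes
    sdlog <- if (s > 0) sqrt(log(1 + (s / m)^2)) else 0
    meanlog <- log(m) - sdlog^2 / 2
    d <- sched |>
      mutate(
        surveyed = runif(n()) >= config$missing_week_prob,
        duration_min = ifelse(.data$surveyed,
                              pmax(10, rlnorm(n(), meanlog, sdlog)), NA_real_),
        quality = rnorm(n())
      )
    n_inc <- config$n_incidental_species
    if (n_inc > 0) {
      p0 <- runif(n_inc, config$incidental_p_range[1],
                  config$incidental_p_range[2])
      logit_p <- matrix(stats::qlogis(p0), nrow(d), n_inc, byrow = TRUE) +
        config$quality_coupling * d$quality
      listed <- matrix(rbinom(nrow(d) * n_inc, 1, stats::plogis(logit_p)),
                       nrow(d), n_inc)
      listed[!d$surveyed, ] <- 0L
      d$list_dev <- rowSums(listed) - sum(p0)
      idx <- which(listed == 1L, arr.ind = TRUE)
      incidental <- tibble(
        site_id = d$site_id[idx[, 1]], year = d$year[idx[, 1]],
        week = d$week[idx[, 1]], survey_date = d$date_mid[idx[, 1]],
        duration_min = d$duration_min[idx[, 1]],
        species_id = sprintf("inc%03d", idx[, 2]),
        count = 1L, surveyed = TRUE
      )
    } else {
      d$list_dev <- 0
    }
    d
  })

  design <- design |>
    left_join(effects$site, by = "site_id") |>
    left_join(effects$year, by = "year") |>
    left_join(effects$obs, by = c("site_id", "year"))

  # per-species flight-curve mass over each week's degree-day window
  surveys <- withr::with_seed(seeds[5], {
    purrr::map(seq_len(nrow(sp)), function(i) {
      peaks <- sp$brood_peaks_gdd[[i]]
      sdg <- sp$brood_sd_gdd[i]
      mass <- rowSums(vapply(
        peaks,
        function(mu) pnorm(design$gdd_hi, mu, sdg) - pnorm(design$gdd_lo, mu, sdg),
        numeric(nrow(design))
      )) / length(peaks)
      if (max(mass) < 1e-8) {
        warn(paste0("Degenerate flight curve for ", sp$species_id[i],
                    ": all mass outside the season; counts will be zero."))
      }
      lambda <- exp(sp$baseline_log_abundance[i] +
                      sp$annual_trend[i] * (design$year - year_mid) +
                      design$site_effect + design$year_effect +
                      design$obs_effect +
                      config$listlength_effect * design$list_dev) *
        mass * design$duration_min / config$duration_mean_minutes
      counts <- rep(NA_integer_, nrow(design))
      counts[design$surveyed] <- rpois(sum(design$surveyed),
                                       lambda[design$surveyed])
      tibble(
        site_id = design$site_id, year = design$year, week = design$week,
        survey_date = design$date_mid, duration_min = design$duration_min,
        species_id = sp$species_id[i],
        count = counts,
        surveyed = design$surveyed
      )
    }) |>
      purrr::list_rbind() |>
      bind_rows(incidental) |>
      arrange(.data$site_id, .data$year, .data$week, .data$species_id)
  })

  truth <- list(
    species = sp,
    site_effects = effects$site,
    year_effects = effects$year,
    obs_effects = effects$obs,
    survey_quality = design |>
      select("site_id", "year", "week", "quality", "list_dev"),
    year_mid = year_mid,
    config = config
  )
  structure(list(surveys = surveys, temperatures = temps, sites = sites,
                 truth = truth),
            class = "pollard_sim")
}

#' Simulate population-index rows directly from the trend model
#'
#' Draws site-by-year index rows straight from the trend GLMM's
#' generative structure — `lambda = exp(beta0 + beta_year * year_c +
#' beta_listlength * listlength_c + site + year + observation effects) *
#' duration`, `index ~ Poisson(lambda)` — skipping the weekly count and
#' phenology layers. Useful for validating the fitting machinery against
#' a truth expressed on the model's own scale.
#'
#' @param n_sites,n_years Design dimensions.
#' @param beta0 Intercept (log butterflies per minute).
#' @param beta_year Log-scale trend per centered year.
#' @param beta_listlength Log-scale slope per centered species listed.
#' @param sd_site,sd_year,sd_obs Random-effect SDs (log scale).
#' @param duration_min Projected duration offset (minutes).
#' @param first_year First calendar year.
#' @param seed Integer seed.
#' @return A tibble shaped like a `PopulationIndexTable` (one row per
#'   site-year), ready for [fit_trend_glmm()].
#' @export
simulate_index_rows <- function(n_sites = 20, n_years = 10,
                                beta0 = 1, beta_year = 0,
                                beta_listlength = 0.1,
                                sd_site = 0, sd_year = 0, sd_obs = 0,
                                duration_min = 2550,
                                first_year = 2000, seed = 1L) {
  stopifnot(n_sites >= 1, n_years >= 2)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      site_id = sprintf("s%03d", seq_len(n_sites)),
      year = first_year + seq_len(n_years) - 1L
    )
    site_eff <- setNames(rnorm(n_sites, 0, sd_site), unique(grid$site_id))
    year_eff <- setNames(rnorm(n_years, 0, sd_year),
                         as.character(unique(grid$year)))
    grid$mean_list_length <- pmax(1, rnorm(nrow(grid), 8, 2))
    grid$projected_duration_min <- duration_min
    eta <- beta0 + beta_year * (grid$year - mean(grid$year)) +
      beta_listlength * (grid$mean_list_length - mean(grid$mean_list_length)) +
      site_eff[grid$site_id] + year_eff[as.character(grid$year)] +
      rnorm(nrow(grid), 0, sd_obs)
    grid$index <- rpois(nrow(grid), exp(eta) * duration_min)
    grid$n_surveys <- 25L
    grid
  })
}

#' @export
print.pollard_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic Pollard-walk monitoring dataset\n")
  cat(sprintf("  %d sites x %d years x %d weeks, %d species\n",
              cfg$n_sites, cfg$n_years, cfg$weeks_per_season,
              nrow(cfg$species_specs)))
  sw <- distinct(x$surveys, .data$site_id, .data$year, .data$week,
                 .data$surveyed)
  cat(sprintf("  surveyed site-weeks: %.1f%%\n", 100 * mean(sw$surveyed)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d sites, %d years from %d, %d weeks/season, %d species\n",
    x$n_sites, x$n_years, x$first_year, x$weeks_per_season,
    nrow(x$species_specs)))
  cat(sprintf("  SDs site/year/obs: %.3f/%.3f/%.3f; missing week prob %.3f\n",
              x$sd_site, x$sd_year, x$sd_obs, x$missing_week_prob))
  invisible(x)
}
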