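# Shared fixtures, built in code (no stored data). Heavier objects are
# memoised so multiple test files can reuse one simulation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small full monitoring simulation used across phenology/index tests.
tiny_sim <- function() {
  memo("tiny_sim", {
    cfg <- sim_config(
      n_sites = 12, n_years = 6,
      species_specs = sim_species_specs(3, seed = 11),
      missing_week_prob = 0.2, seed = 401
    )
    suppressWarnings(simulate_monitoring(cfg))
  })
}

tiny_pipeline <- function() {
  memo("tiny_pipeline", suppressWarnings(run_abundance_pipeline(tiny_sim())))
}

# Index rows drawn directly from the trend model's generative structure
# (no phenology step); thin wrapper over simulate_index_rows().
make_index_data <- function(n_sites = 20, n_years = 10,
                            beta0 = 1, beta_year = 0, beta_ll = 0.1,
                            sd_site = 0, sd_year = 0, sd_obs = 0,
                            duration = 2550, seed = 1) {
  simulate_index_rows(n_sites = n_sites, n_years = n_years,
                      beta0 = beta0, beta_year = beta_year,
                      beta_listlength = beta_ll,
                      sd_site = sd_site, sd_year = sd_year, sd_obs = sd_obs,
                      duration_min = duration, seed = seed)
}

# Flight-curve training data with a known Gaussian-mixture truth.
make_phenology_data <- function(peaks, brood_sd = 100, n_sites = 30,
                                n_years = 5, baseline = 4, seed = 1) {
  spec <- tibble::tibble(
    species_id = "spX",
    voltinism = c("univoltine", "bivoltine", "multivoltine")[
      min(length(peaks), 3)],
    brood_peaks_gdd = list(peaks),
    brood_sd_gdd = brood_sd,
    baseline_log_abundance = baseline,
    annual_trend = 0,
    migratory = FALSE
  )
  cfg <- sim_config(n_sites = n_sites, n_years = n_years,
                    species_specs = spec, missing_week_prob = 0,
                    sd_site = 0, sd_year = 0, sd_obs = 0,
                    listlength_effect = 0, n_incidental_species = 0,
                    seed = seed)
  sim <- simulate_monitoring(cfg)
  prepare_survey_gdd(sim$surveys, sim$temperatures, sim$sites)
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
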