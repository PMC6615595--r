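test_that("degree-day accumulation does the expected arithmetic", {
  d <- tibble::tibble(tmin = c(10, 10, 10), tmax = c(20, 20, 20))
  out <- accumulate_degree_days(d, base = 5)
  expect_equal(out$gdd_increment, c(10, 10, 10))
  expect_equal(out$gdd, c(10, 20, 30))

  expect_equal(accumulate_degree_days(
    tibble::tibble(tmin = -5, tmax = 3), base = 5)$gdd, 0)

  out2 <- accumulate_degree_days(
    tibble::tibble(tmin = c(0, 10), tmax = c(4, 30)), base = 5)
  expect_equal(out2$gdd, c(0, 15))

  expect_error(accumulate_degree_days(
    tibble::tibble(tmin = 10, tmax = 5)), "tmax")
})

test_that("degree-day accumulation is invariant to chunked evaluation", {
  withr::with_seed(21, {
    d <- tibble::tibble(tmin = rnorm(100, 8, 5), tmax = rnorm(100, 18, 5))
    d$tmax <- pmax(d$tmax, d$tmin)
  })
  whole <- accumulate_degree_days(d)$gdd
  splits <- split(seq_len(100), rep(1:4, each = 25))
  chunked <- cumsum(unlist(
    lapply(splits, function(i) accumulate_degree_days(d[i, ])$gdd_increment)))
  expect_equal(whole, unname(chunked))
})

test_that("phenology eligibility keeps site-years with at least 5 surveys", {
  mk <- function(site, n_surveyed) {
    tibble::tibble(site_id = site, year = 2000, week = 1:10,
                   species_id = "sp1", count = 1L,
                   surveyed = c(rep(TRUE, n_surveyed),
                                rep(FALSE, 10 - n_surveyed)))
  }
  surveys <- dplyr::bind_rows(mk("four", 4), mk("five", 5), mk("nine", 9))
  kept <- eligible_for_phenology(surveys)
  expect_setequal(unique(kept$site_id), c("five", "nine"))
  expect_identical(dplyr::filter(kept, site_id == "five"),
                   dplyr::filter(surveys, site_id == "five"))
  empty <- surveys[0, ]
  expect_identical(eligible_for_phenology(empty), empty)
})

test_that("the fitted flight curve recovers a single simulated brood peak", {
  dat <- make_phenology_data(peaks = 600, brood_sd = 100, seed = 31)
  fit <- fit_flight_curve(dat, engine = "gam")
  grid <- tibble::tibble(
    gdd = seq(fit$gdd_range[1], fit$gdd_range[2], by = 1),
    lat = median(dat$lat), lon = median(dat$lon),
    year = dat$year[1], duration_min = 85
  )
  pred <- predict(fit, grid)
  expect_lt(abs(grid$gdd[which.max(pred)] - 600), 25)
  expect_true(all(pred >= 0))
})

test_that("a bivoltine truth yields two local maxima near the true peaks", {
  dat <- make_phenology_data(peaks = c(400, 900), brood_sd = 80,
                             baseline = 4.5, seed = 32)
  fit <- suppressWarnings(fit_flight_curve(dat, engine = "gam"))
  grid <- tibble::tibble(
    gdd = seq(fit$gdd_range[1], fit$gdd_range[2], by = 1),
    lat = median(dat$lat), lon = median(dat$lon),
    year = dat$year[1], duration_min = 85
  )
  y <- predict(fit, grid)
  is_peak <- which(diff(sign(diff(y))) == -2) + 1
  peaks_gdd <- grid$gdd[is_peak]
  expect_true(any(abs(peaks_gdd - 400) <= 50))
  expect_true(any(abs(peaks_gdd - 900) <= 50))
})

test_that("a flat truth produces an essentially flat fitted curve", {
  withr::with_seed(33, {
    dat <- tidyr::expand_grid(
      site_id = sprintf("s%02d", 1:20), rep = 1:40
    ) |>
      dplyr::mutate(
        gdd = runif(dplyr::n(), 100, 2000),
        lat = rep(runif(20, 39, 41), each = 40),
        lon = rep(runif(20, -84, -81), each = 40),
        year = 2000L, duration_min = 85,
        count = rpois(dplyr::n(), 5)
      )
  })
  fit <- fit_flight_curve(dat, engine = "gam")
  grid <- tibble::tibble(gdd = seq(150, 1950, by = 10),
                         lat = 40, lon = -82.5, year = 2000L,
                         duration_min = 85)
  pred <- predict(fit, grid)
  expect_lt(max(pred) / min(pred), 1.2)
})

test_that("flight-curve fitting refuses degenerate inputs", {
  dat <- make_phenology_data(peaks = 600, n_sites = 5, n_years = 2, seed = 34)
  allzero <- dplyr::mutate(dat, count = 0L)
  expect_error(fit_flight_curve(allzero), "no phenology signal")
  onesite <- dplyr::filter(dat, site_id == site_id[1])
  expect_error(fit_flight_curve(onesite), "Refusing")
  expect_error(fit_flight_curve(dplyr::slice_head(dat, n = 0)),
               "no phenology signal")
})

test_that("flight-curve predictions are invariant to training-row order", {
  dat <- make_phenology_data(peaks = 600, n_sites = 10, n_years = 2, seed = 35)
  shuffled <- withr::with_seed(1, dat[sample.int(nrow(dat)), ])
  grid <- tibble::tibble(gdd = seq(200, 1800, by = 50),
                         lat = 40, lon = -82.5, year = dat$year[1],
                         duration_min = 85)
  p1 <- predict(fit_flight_curve(dat, engine = "gam"), grid)
  p2 <- predict(fit_flight_curve(shuffled, engine = "gam"), grid)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("imputation preserves observed counts and fills only missing weeks", {
  sim <- tiny_sim()
  gdd <- prepare_survey_gdd(sim$surveys, sim$temperatures, sim$sites)
  sp <- sort(grep("^sp", unique(gdd$species_id), value = TRUE))[1]
  one <- dplyr::filter(eligible_for_phenology(gdd), species_id == sp)
  fit <- suppressWarnings(fit_flight_curve(one, engine = "gam"))
  completed <- impute_missing_counts(one, fit)

  obs <- dplyr::filter(completed, surveyed)
  expect_identical(obs$count, as.numeric(one$count[one$surveyed]))
  expect_true(all(!obs$imputed))
  expect_true(all(completed$imputed[!completed$surveyed &
                                      !is.na(completed$count)]))
  expect_true(all(completed$count[completed$imputed] >= 0))

  # no missing weeks -> identity on counts
  full <- dplyr::filter(one, surveyed)
  same <- impute_missing_counts(full, fit)
  expect_equal(as.numeric(same$count), as.numeric(full$count))
  expect_true(all(!same$imputed))
})

test_that("an all-missing site-year receives the full predicted curve", {
  dat <- make_phenology_data(peaks = 600, n_sites = 10, n_years = 2, seed = 36)
  fit <- fit_flight_curve(dat, engine = "gam")
  target <- dat |>
    dplyr::filter(site_id == site_id[1], year == year[1]) |>
    dplyr::mutate(count = NA_integer_, surveyed = FALSE,
                  duration_min = NA_real_)
  out <- impute_missing_counts(target, fit)
  expect_true(all(out$imputed))
  expect_true(all(is.finite(out$count)))
  # peak-week imputation exceeds tail-week imputation for a single brood
  peak_val <- out$count[which.min(abs(out$gdd - 600))]
  tail_val <- out$count[which.max(out$gdd)]
  expect_gt(peak_val, tail_val)
})
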