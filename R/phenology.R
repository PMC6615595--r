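#' Accumulate growing degree-days from daily temperature extremes
#'
#' The daily increment is the simple averaging estimator
#' `max(0, (tmin + tmax)/2 - base)`, accumulated from the first row of each
#' site-year (January 1 for full-year series).
#'
#' @param temperatures Tibble with `tmin` and `tmax` columns (degC), in
#'   day order; optional `site_id` and `year` columns define accumulation
#'   groups.
#' @param base Base temperature (degC), default 5.
#' @return The input with `gdd_increment` and accumulated `gdd` columns.
#' @export
accumulate_degree_days <- function(temperatures, base = 5) {
  if (!all(c("tmin", "tmax") %in% names(temperatures))) {
    abort("`temperatures` needs `tmin` and `tmax` columns.")
  }
  if (any(temperatures$tmax < temperatures$tmin)) {
    abort("tmax < tmin on at least one day.")
  }
  keys <- intersect(c("site_id", "year"), names(temperatures))
  temperatures |>
    group_by(across(dplyr::all_of(keys))) |>
    mutate(
      gdd_increment = pmax(0, (.data$tmin + .data$tmax) / 2 - base),
      gdd = cumsum(.data$gdd_increment)
    ) |>
    ungroup()
}

#' Degree-day positions of the weekly survey schedule
#'
#' Maps each monitoring week to its start/mid/end day of year and looks up
#' the accumulated degree-days at those days for every site-year. The
#' degree-day window (`gdd_lo`, `gdd_hi`) is what a flight curve is
#' integrated over for that week.
#'
#' @param temperatures Daily temperature tibble
#'   (`site_id`, `year`, `doy`, `tmin`, `tmax`).
#' @param weeks_per_season Number of weekly visits per season.
#' @param season_start_doy Day of year on which week 1 starts.
#' @param base Degree-day base temperature (degC).
#' @return Tibble with one row per site x year x week: `doy_mid`,
#'   `date_mid`, `gdd_lo`, `gdd`, `gdd_hi`.
#' @export
degree_day_schedule <- function(temperatures, weeks_per_season = 30,
                                season_start_doy = 91, base = 5) {
  gddtab <- accumulate_degree_days(temperatures, base = base)
  weeks <- tibble(
    week = seq_len(weeks_per_season),
    doy_lo = season_start_doy + (seq_len(weeks_per_season) - 1L) * 7L
  ) |>
    mutate(doy_mid = pmin(.data$doy_lo + 3L, 365L),
           doy_hi = pmin(.data$doy_lo + 7L, 365L))
  lookup <- function(doys) {
    gddtab |>
      select("site_id", "year", "doy", "gdd") |>
      filter(.data$doy %in% unique(doys))
  }
  tidyr::expand_grid(distinct(gddtab, .data$site_id, .data$year), weeks) |>
    left_join(lookup(weeks$doy_lo) |> rename(doy_lo = "doy", gdd_lo = "gdd"),
              by = c("site_id", "year", "doy_lo")) |>
    left_join(lookup(weeks$doy_mid) |> rename(doy_mid = "doy"),
              by = c("site_id", "year", "doy_mid")) |>
    left_join(lookup(weeks$doy_hi) |> rename(doy_hi = "doy", gdd_hi = "gdd"),
              by = c("site_id", "year", "doy_hi")) |>
    mutate(date_mid = as.Date(.data$doy_mid - 1,
                              origin = paste0(.data$year, "-01-01"))) |>
    select("site_id", "year", "week", "doy_mid", "date_mid",
           "gdd_lo", "gdd", "gdd_hi")
}

#' Restrict surveys to site-years usable for phenology fitting
#'
#' Flight-curve models are trained only on site-years with at least
#' `min_surveys` surveyed weeks (inclusive threshold). Retained rows are
#' returned unchanged.
#'
#' @param surveys Long survey tibble with `site_id`, `year`, `week` and a
#'   logical `surveyed` column.
#' @param min_surveys Minimum surveyed weeks per site-year (default 5).
#' @return The filtered tibble.
#' @export
eligible_for_phenology <- function(surveys, min_surveys = 5) {
  if (nrow(surveys) == 0) return(surveys)
  keep <- surveys |>
    filter(.data$surveyed) |>
    distinct(.data$site_id, .data$year, .data$week) |>
    dplyr::count(.data$site_id, .data$year) |>
    filter(.data$n >= min_surveys) |>
    select("site_id", "year")
  inner_join(surveys, keep, by = c("site_id", "year"))
}

#' Fit a regional flight-curve model for one species
#'
#' A penalized Poisson regression of weekly counts on accumulated
#' degree-days (cubic regression spline), a low-rank spatial smooth over
#' site coordinates, and year as a categorical term, with log survey
#' duration as an offset. One model pools all sites and years (the
#' "regional" approach). Smoothness is chosen by GCV; for large training
#' sets the fit switches to [mgcv::bam()] with fast REML and discretized
#' covariates.
#'
#' @param data Survey rows for one species joined to degree-days and site
#'   coordinates: columns `count`, `gdd`, `lat`, `lon`, `year`,
#'   `duration_min`, and optionally `surveyed` (only surveyed rows are
#'   used).
#' @param k_gdd Basis dimension of the degree-day spline (default 10).
#' @param k_space Basis dimension of the spatial smooth (default 10;
#'   reduced or dropped when few distinct sites are available).
#' @param min_nonzero Minimum number of nonzero-count surveys (spanning at
#'   least 2 sites) below which fitting refuses.
#' @param engine `"auto"` (bam above 8000 rows), `"gam"`, or `"bam"`.
#' @return An object of class `flight_curve` wrapping the mgcv fit with
#'   its training summary (degree-day range, n surveys, sites, years,
#'   effective df, deviance explained).
#' @export
fit_flight_curve <- function(data, k_gdd = 10, k_space = 10,
                             min_nonzero = 20, engine = c("auto", "gam", "bam")) {
  engine <- match.arg(engine)
  if ("surveyed" %in% names(data)) data <- filter(data, .data$surveyed)
  need <- c("count", "gdd", "lat", "lon", "year", "duration_min")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  data <- filter(data, !is.na(.data$count))
  nz <- filter(data, .data$count > 0)
  if (nrow(nz) == 0) abort("no phenology signal: all counts are zero.")
  n_nz_sites <- dplyr::n_distinct(nz$site_id %||% nz$lat)
  if (nrow(nz) < min_nonzero || n_nz_sites < 2) {
    abort(sprintf(
      "Refusing to fit: %d nonzero-count surveys at %d sites (need >= %d at >= 2 sites).",
      nrow(nz), n_nz_sites, min_nonzero))
  }

  df <- data |>
    mutate(year_f = factor(.data$year), log_dur = log(.data$duration_min))
  k_gdd_use <- max(4, min(k_gdd, dplyr::n_distinct(df$gdd) - 1))
  terms <- sprintf("s(gdd, bs = 'cr', k = %d)", k_gdd_use)
  n_loc <- nrow(distinct(df, .data$lat, .data$lon))
  has_spatial <- n_loc >= 5
  if (has_spatial) {
    terms <- c(terms, sprintf("s(lat, lon, k = %d)", max(4, min(k_space, n_loc - 1))))
  }
  has_year <- dplyr::n_distinct(df$year_f) > 1
  if (has_year) terms <- c(terms, "year_f")
  fml <- as.formula(paste("count ~", paste(terms, collapse = " + "),
                          "+ offset(log_dur)"))
  big <- engine == "bam" || (engine == "auto" && nrow(df) > 8000)
  model <- if (big) {
    mgcv::bam(fml, family = stats::poisson(), data = df,
              discrete = TRUE, method = "fREML")
  } else {
    mgcv::gam(fml, family = stats::poisson(), data = df, method = "GCV.Cp")
  }
  structure(list(
    model = model,
    gdd_range = range(df$gdd),
    year_levels = levels(df$year_f),
    n_train = nrow(df),
    n_nonzero = nrow(nz),
    duration_ref = mean(df$duration_min),
    n_sites = n_loc,
    has_spatial = has_spatial,
    has_year = has_year,
    edf = sum(model$edf),
    deviance_explained = 1 - model$deviance / model$null.deviance
  ), class = "flight_curve")
}

#' @export
print.flight_curve <- function(x, ...) {
  cat("Flight-curve model (penalized Poisson spline in degree-days)\n")
  cat(sprintf("  trained on %d surveys (%d nonzero) at %d sites, %d year(s)\n",
              x$n_train, x$n_nonzero, x$n_sites, length(x$year_levels)))
  cat(sprintf("  degree-day support [%.0f, %.0f]; edf %.1f; deviance explained %.1f%%\n",
              x$gdd_range[1], x$gdd_range[2], x$edf,
              100 * x$deviance_explained))
  invisible(x)
}

#' Predict expected counts from a flight-curve model
#'
#' @param object A `flight_curve`.
#' @param newdata Tibble with `gdd`, `lat`, `lon`, `year`, `duration_min`.
#' @param ... Unused.
#' @return Numeric vector of expected counts (response scale, nonnegative).
#'   Years outside the training levels produce an error.
#' @export
predict.flight_curve <- function(object, newdata, ...) {
  nd <- newdata |>
    mutate(year_f = factor(.data$year, levels = object$year_levels),
           log_dur = log(.data$duration_min))
  if (object$has_year && anyNA(nd$year_f)) {
    abort("newdata contains years outside the model's support.")
  }
  as.numeric(predict(object$model, newdata = nd, type = "response",
                     discrete = FALSE))
}

#' Fill unsurveyed weeks with flight-curve predictions
#'
#' Observed weeks pass through bit-exact; unsurveyed weeks receive the
#' model's expected count (a nonnegative real, not a sampled integer) at
#' that week's degree-days and the site-year's mean observed duration.
#' Weeks whose degree-days fall outside the model's training support are
#' flagged `extrapolated`. Site-years from years absent from the model's
#' support are returned unfilled with a warning.
#'
#' @param data Complete site x year x week grid for one species: columns
#'   `site_id`, `year`, `week`, `gdd`, `lat`, `lon`, `count` (NA where
#'   unsurveyed), `surveyed`, `duration_min` (NA where unsurveyed).
#' @param model A `flight_curve` for the same species.
#' @return `data` with `count` completed and logical `imputed` and
#'   `extrapolated` columns added.
#' @export
impute_missing_counts <- function(data, model) {
  stopifnot(inherits(model, "flight_curve"))
  out <- data |>
    group_by(.data$site_id, .data$year) |>
    mutate(dur_fill = ifelse(is.na(.data$duration_min),
                             mean(.data$duration_min, na.rm = TRUE),
                             .data$duration_min)) |>
    ungroup() |>
    mutate(dur_fill = ifelse(is.nan(.data$dur_fill),
                             mean(.data$duration_min, na.rm = TRUE),
                             .data$dur_fill),
           dur_fill = ifelse(is.finite(.data$dur_fill), .data$dur_fill,
                             model$duration_ref),
           imputed = !.data$surveyed,
           extrapolated = !.data$surveyed &
             (.data$gdd < model$gdd_range[1] | .data$gdd > model$gdd_range[2]))
  todo <- which(out$imputed)
  if (length(todo)) {
    in_support <- !model$has_year | out$year[todo] %in% model$year_levels
    if (any(!in_support)) {
      warn(sprintf(
        "%d unsurveyed weeks fall in years outside the model's support; left unfilled.",
        sum(!in_support)))
    }
    fill <- todo[in_support]
    if (length(fill)) {
      out$count[fill] <- predict(
        model,
        out[fill, ] |> mutate(duration_min = .data$dur_fill)
      )
    }
    out$imputed[todo[!in_support]] <- FALSE
  }
  select(out, -"dur_fill")
}

#' @rdname fit_flight_curve
#' @param object A `flight_curve`.
#' @param gdd_grid Degree-day values at which to evaluate the curve
#'   (default: 200 points over the training support).
#' @param ... Unused.
#' @details `autoplot()` draws the fitted seasonal curve at the training
#'   data's median coordinates and reference year, per minute of survey
#'   effort.
#' @method autoplot flight_curve
#' @export
autoplot.flight_curve <- function(object, gdd_grid = NULL, ...) {
  if (is.null(gdd_grid)) {
    gdd_grid <- seq(object$gdd_range[1], object$gdd_range[2], length.out = 200)
  }
  md <- object$model$model
  nd <- tibble(
    gdd = gdd_grid,
    lat = median(md$lat), lon = median(md$lon),
    year = object$year_levels[1] %||% NA,
    duration_min = 1
  )
  nd$expected <- predict(object, nd)
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$gdd, y = .data$expected)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(x = "Accumulated degree-days (base 5 °C)",
                  y = "Expected count per minute",
                  title = "Fitted flight curve") +
    ggplot2::theme_minimal()
}
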