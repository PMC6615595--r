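#' Tidy a trend fit
#'
#' @param x A `trend_fit`.
#' @param effects `"fixed"` (default), `"random"`, or `"all"`.
#' @param ... Unused.
#' @return A tibble of coefficient estimates (fixed) and/or random-effect
#'   SDs.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, effects = c("fixed", "random", "all"), ...) {
  effects <- match.arg(effects)
  fixed <- x$fixed |> mutate(effect = "fixed")
  random <- x$random |>
    rename(term = "group", estimate = "sd") |>
    mutate(effect = "ran_pars", std_error = NA_real_,
           statistic = NA_real_, p_value = NA_real_) |>
    select("term", "estimate", "std_error", "statistic", "p_value",
           "effect", "n_groups")
  switch(effects,
         fixed = fixed,
         random = random,
         all = bind_rows(fixed, random))
}

#' Glance at a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model type, n, log-likelihood, marginal and
#'   conditional R2, annual rate, and classification.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(
    model = x$type,
    nobs = x$n,
    log_likelihood = x$log_likelihood,
    marginal_r2 = x$marginal_r2,
    conditional_r2 = x$conditional_r2,
    annual_rate_percent = annualized_rate(x),
    classification = classify_trend(x)
  )
}

#' Tidy a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return The coefficient tibble.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' Glance at a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return One-row tibble with lambda, log-likelihood, R2 and n.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(lambda = x$lambda, log_likelihood = x$log_likelihood,
         r_squared = x$r_squared, n_species = x$n_species)
}

#' Tidy a trait OLS fit
#'
#' @param x A `trait_ols`.
#' @param ... Unused.
#' @return The coefficient tibble with the trait name attached.
#' @method tidy trait_ols
#' @export
tidy.trait_ols <- function(x, ...) {
  x$coefficients |> mutate(trait = x$trait)
}

#' Glance at a trait OLS fit
#'
#' @param x A `trait_ols`.
#' @param ... Unused.
#' @return One-row tibble with the adjusted R2 and n.
#' @method glance trait_ols
#' @export
glance.trait_ols <- function(x, ...) {
  tibble(trait = x$trait, adj_r_squared = x$adj_r_squared,
         n_species = x$n_species)
}

#' Tidy a smooth trend fit
#'
#' @param x A `trend_smooth`.
#' @param ... Unused.
#' @return The per-year expected abundance tibble.
#' @method tidy trend_smooth
#' @export
tidy.trend_smooth <- function(x, ...) x$per_year

#' Plot a fitted abundance trend
#'
#' Shows the fixed-effect trend line (relative to the first year) with
#' the per-year random-effect predictions as points, and the bootstrap
#' band when supplied.
#'
#' @param object A `trend_fit`.
#' @param ci Optional `trend_boot` for the confidence band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ci = NULL, ...) {
  years <- seq(object$year_range[1], object$year_range[2])
  beta <- trend_coef(object)$estimate
  line <- tibble(year = years,
                 relative = exp(beta * (years - object$year_mean)))
  line$relative <- line$relative / line$relative[1]
  p <- ggplot2::ggplot(line, ggplot2::aes(x = .data$year, y = .data$relative))
  if (!is.null(ci)) {
    p <- p + ggplot2::geom_ribbon(
      data = ci$per_year,
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80", alpha = 0.7)
  }
  if (object$type == "glmm") {
    re <- lme4::ranef(object$model)$year_f
    pts <- tibble(year = as.integer(rownames(re)),
                  relative = line$relative[match(as.integer(rownames(re)),
                                                 line$year)] * exp(re[, 1]))
    p <- p + ggplot2::geom_point(data = pts, colour = "grey30")
  }
  p +
    ggplot2::geom_line(colour = "#d7301f", linewidth = 0.9) +
    ggplot2::labs(x = "Year", y = "Relative abundance",
                  title = sprintf("Abundance trend: %+.1f%% per year",
                                  annualized_rate(object))) +
    ggplot2::theme_minimal()
}

#' Plot a smooth (nonlinear) trend
#'
#' @param object A `trend_smooth`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_smooth
#' @export
autoplot.trend_smooth <- function(object, ...) {
  py <- object$per_year |>
    mutate(rel = .data$expected / .data$expected[1],
           lo = .data$lower / .data$expected[1],
           hi = .data$upper / .data$expected[1])
  ggplot2::ggplot(py, ggplot2::aes(x = .data$year, y = .data$rel)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.9) +
    ggplot2::labs(x = "Year", y = "Relative abundance",
                  title = sprintf("Smooth trend: endpoint rate %+.2f%%/yr",
                                  object$annual_rate_percent)) +
    ggplot2::theme_minimal()
}

#' Plot the lambda profile of a PGLS fit
#'
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the profile log-likelihood over
#'   lambda with the ML estimate marked.
#' @method autoplot pgls_fit
#' @export
autoplot.pgls_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$lambda, y = .data$log_likelihood)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2,
                        colour = "#d7301f") +
    ggplot2::labs(x = expression(lambda), y = "Profile log-likelihood",
                  title = sprintf("Pagel's lambda = %.3f", object$lambda)) +
    ggplot2::theme_minimal()
}
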