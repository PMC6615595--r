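#' Fit the overdispersed Poisson trend model to population indices
#'
#' Population indices (rounded to the nearest integer for the count
#' likelihood) are modelled as overdispersed Poisson on the log link with
#' centered numeric year and centered mean list-length as fixed effects,
#' log projected duration as an offset (so the trend is a rate of
#' butterflies per minute), and crossed random intercepts for site, year,
#' and the site-by-year observation (the observation-level random effect
#' that absorbs extra-Poisson variance). Estimated by Laplace-approximated
#' maximum likelihood via [lme4::glmer()].
#'
#' @param data Index rows for one species or the total: `site_id`, `year`,
#'   `index`, `mean_list_length`, `projected_duration_min`.
#' @return An object of class `trend_fit`: fixed-effect estimates with
#'   Wald SEs, z statistics and p-values; random-effect SDs and group
#'   counts; marginal and conditional R2; log-likelihood; and the fitted
#'   lme4 model.
#' @export
fit_trend_glmm <- function(data) {
  df <- prepare_trend_data(data)
  fml <- round_index ~ year_c + listlength_c + (1 | site_id) + (1 | year_f) +
    (1 | obs_id) + offset(log_duration)
  model <- withCallingHandlers(
    tryCatch(
      lme4::glmer(fml, data = df, family = stats::poisson(),
                  control = lme4::glmerControl(calc.derivs = TRUE)),
      error = function(e) {
        abort(paste0("Trend GLMM did not converge: ", conditionMessage(e)))
      }),
    message = function(m) invokeRestart("muffleMessage")
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  grp_names <- c(site_id = "site", year_f = "year", obs_id = "observation")
  random <- tibble(
    group = unname(grp_names[vc$grp]),
    sd = vc$sdcor,
    n_groups = unname(vapply(vc$grp, function(g) {
      dplyr::n_distinct(df[[g]])
    }, integer(1)))
  )
  if (any(random$sd < 1e-8)) {
    warn(paste0("Singular fit: random-effect SD estimated as 0 for ",
                paste(random$group[random$sd < 1e-8], collapse = ", "), "."))
  }
  new_trend_fit(model, df, random, type = "glmm")
}

#' Poisson GLM alternative trend model (no random effects)
#'
#' The same fixed-effect structure and offset as [fit_trend_glmm()] but
#' fitted as a plain Poisson generalized linear model, used to validate
#' that the mixed-model machinery does not drive the trend estimate.
#'
#' @inheritParams fit_trend_glmm
#' @return A `trend_fit` with an empty random-effects table.
#' @export
fit_trend_glm <- function(data) {
  df <- prepare_trend_data(data)
  model <- stats::glm(
    round_index ~ year_c + listlength_c + offset(log_duration),
    data = df, family = stats::poisson())
  random <- tibble(group = character(), sd = numeric(), n_groups = integer())
  new_trend_fit(model, df, random, type = "glm")
}

prepare_trend_data <- function(data) {
  need <- c("site_id", "year", "index", "mean_list_length",
            "projected_duration_min")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) < 10) abort("Need at least 10 index rows to fit a trend.")
  if (dplyr::n_distinct(data$year) < 2) abort("Need at least 2 distinct years.")
  if (any(data$projected_duration_min <= 0)) abort("Durations must be positive.")
  if (any(data$index < 0)) abort("Indices must be nonnegative.")
  data |>
    mutate(
      round_index = round(.data$index),
      year_c = .data$year - mean(.data$year),
      listlength_c = .data$mean_list_length - mean(.data$mean_list_length),
      log_duration = log(.data$projected_duration_min),
      year_f = factor(.data$year),
      obs_id = factor(seq_len(n()))
    )
}

new_trend_fit <- function(model, df, random, type) {
  cf <- if (type == "glmm") {
    stats::coef(summary(model))
  } else {
    stats::coef(summary(model))
  }
  fixed <- tibble(
    term = rownames(cf),
    estimate = cf[, 1], std_error = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4]
  )
  fit <- structure(list(
    model = model,
    type = type,
    fixed = fixed,
    random = random,
    n = nrow(df),
    year_range = range(df$year),
    year_mean = mean(df$year),
    listlength_mean = mean(df$mean_list_length),
    data = df,
    log_likelihood = as.numeric(logLik(model))
  ), class = "trend_fit")
  r2 <- tryCatch(r2_glmm(fit), error = function(e) {
    tibble(marginal_r2 = NA_real_, conditional_r2 = NA_real_)
  })
  fit$marginal_r2 <- r2$marginal_r2
  fit$conditional_r2 <- r2$conditional_r2
  fit
}

trend_coef <- function(fit, term = "year_c") {
  i <- match(term, fit$fixed$term)
  if (is.na(i)) abort(paste0("Term ", term, " not in fit."))
  list(estimate = fit$fixed$estimate[i], se = fit$fixed$std_error[i],
       p = fit$fixed$p_value[i])
}

#' @export
print.trend_fit <- function(x, ...) {
  yr <- trend_coef(x)
  cat(sprintf("Trend %s fit on %d site-year indices (%d-%d)\n",
              toupper(x$type), x$n, x$year_range[1], x$year_range[2]))
  cat(sprintf("  year coefficient %.4f (SE %.4f, p = %.3g)\n",
              yr$estimate, yr$se, yr$p))
  cat(sprintf("  annual rate %+.1f%%; classification: %s\n",
              annualized_rate(x), classify_trend(x)))
  if (nrow(x$random)) {
    cat("  random-effect SDs: ",
        paste(sprintf("%s %.3f (%d)", x$random$group, x$random$sd,
                      x$random$n_groups), collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  R2 marginal %.2f / conditional %.2f\n",
              x$marginal_r2, x$conditional_r2))
  invisible(x)
}

#' Annualized rate of change implied by a log-linear trend
#'
#' Under the log-linear model the geometric-mean rate of change between
#' any two time points is constant, `100 * (exp(beta_year) - 1)` percent
#' per year (list-length at its mean and random effects excluded).
#'
#' @param object A `trend_fit`, or the year coefficient itself (log scale).
#' @param ... Unused.
#' @return Percent change per year.
#' @examples
#' annualized_rate(-0.0203) # -2.0
#' @export
annualized_rate <- function(object, ...) UseMethod("annualized_rate")

#' @export
annualized_rate.numeric <- function(object, ...) 100 * (exp(object) - 1)

#' @export
annualized_rate.trend_fit <- function(object, ...) {
  annualized_rate(trend_coef(object)$estimate)
}

#' Cumulative percent change over a study span
#'
#' `100 * (exp(beta_year * span_years) - 1)`.
#'
#' @param object A `trend_fit` or the year coefficient (log scale).
#' @param span_years Number of years spanned (>= 1).
#' @param ... Unused.
#' @return Cumulative percent change.
#' @examples
#' cumulative_change(-0.0203, 20) # about -33
#' @export
cumulative_change <- function(object, span_years, ...) {
  UseMethod("cumulative_change")
}

#' @export
cumulative_change.numeric <- function(object, span_years, ...) {
  if (span_years < 1) abort("`span_years` must be >= 1.")
  100 * (exp(object * span_years) - 1)
}

#' @export
cumulative_change.trend_fit <- function(object, span_years = NULL, ...) {
  span_years <- span_years %||% diff(object$year_range)
  cumulative_change(trend_coef(object)$estimate, span_years)
}

#' Classify a trend as positive, negative, or stable
#'
#' A trend is negative when its p-value is below `alpha` and the year
#' coefficient is negative, positive when significant and positive, and
#' stable otherwise.
#'
#' @param object A `trend_fit`, or a numeric vector of year coefficients.
#' @param p p-values (required when `object` is numeric).
#' @param alpha Significance threshold (default 0.05).
#' @param ... Unused.
#' @return Factor with levels negative, stable, positive.
#' @examples
#' classify_trend(c(-0.233, 0.047, -0.105), p = c(0.001, 0.022, 0.195))
#' @export
classify_trend <- function(object, ...) UseMethod("classify_trend")

#' @rdname classify_trend
#' @export
classify_trend.numeric <- function(object, p, alpha = 0.05, ...) {
  stopifnot(length(object) == length(p), alpha > 0, alpha < 1)
  out <- ifelse(p < alpha & object < 0, "negative",
                ifelse(p < alpha & object > 0, "positive", "stable"))
  factor(out, levels = c("negative", "stable", "positive"))
}

#' @rdname classify_trend
#' @export
classify_trend.trend_fit <- function(object, alpha = 0.05, ...) {
  yr <- trend_coef(object)
  classify_trend(yr$estimate, p = yr$p, alpha = alpha)
}

#' Parametric bootstrap confidence interval for the trend
#'
#' Simulates responses from the fitted model (drawing new random effects
#' and new Poisson noise), refits, and collects the year coefficient;
#' percentile intervals are returned on the coefficient and annual-rate
#' scales, along with per-year fixed-effect predictions.
#'
#' @param fit A `trend_fit` from [fit_trend_glmm()].
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param seed Integer seed (same seed gives identical intervals).
#' @param level Interval coverage (default 0.95).
#' @return A list of class `trend_boot`: `beta_draws`, `ci` (one-row
#'   tibble), `per_year` (fixed-effect relative abundance with percentile
#'   bands), `n_fail`.
#' @export
bootstrap_trend_ci <- function(fit, n_boot = 500, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "trend_fit"))
  if (n_boot < 1) abort("`n_boot` must be at least 1.")
  if (fit$type != "glmm") abort("Bootstrap is defined for GLMM fits.")
  model <- fit$model
  sims <- simulate(model, nsim = n_boot, seed = seed)
  draws <- purrr::map(sims, function(y) {
    tryCatch({
      m <- suppressMessages(suppressWarnings(lme4::refit(model, newresp = y)))
      lme4::fixef(m)[c("(Intercept)", "year_c")]
    }, error = function(e) c(`(Intercept)` = NA_real_, year_c = NA_real_))
  })
  b <- do.call(rbind, draws)
  n_fail <- sum(is.na(b[, "year_c"]))
  if (n_fail > 0.2 * n_boot) {
    abort(sprintf("%d of %d bootstrap refits failed (> 20%%).", n_fail, n_boot))
  }
  ok <- b[!is.na(b[, "year_c"]), , drop = FALSE]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qb <- quantile(ok[, "year_c"], probs, names = FALSE)
  years <- seq(fit$year_range[1], fit$year_range[2])
  rel <- exp(outer(years - fit$year_mean, ok[, "year_c"]))
  rel <- sweep(rel, 2, rel[1, ], "/")
  per_year <- tibble(
    year = years,
    relative = exp(trend_coef(fit)$estimate * (years - fit$year_mean)),
    lower = apply(rel, 1, quantile, probs[1]),
    upper = apply(rel, 1, quantile, probs[2])
  ) |>
    mutate(relative = .data$relative / .data$relative[1])
  structure(list(
    beta_draws = ok[, "year_c"],
    ci = tibble(level = level,
                beta_lower = qb[1], beta_upper = qb[2],
                annual_lower = annualized_rate(qb[1]),
                annual_upper = annualized_rate(qb[2])),
    per_year = per_year,
    n_fail = n_fail
  ), class = "trend_boot")
}

#' @export
print.trend_boot <- function(x, ...) {
  cat(sprintf("Parametric bootstrap (%d draws, %d failed)\n",
              length(x$beta_draws) + x$n_fail, x$n_fail))
  cat(sprintf("  %.0f%% CI for annual rate: [%+.1f%%, %+.1f%%]\n",
              100 * x$ci$level, x$ci$annual_lower, x$ci$annual_upper))
  invisible(x)
}

#' Marginal and conditional R2 for a trend model
#'
#' Variance explained on the link scale: marginal R2 is the fixed-effect
#' variance over the total (fixed + random + observation-level +
#' distribution-specific) variance; conditional R2 adds the random-effect
#' variance to the numerator. The distribution-specific variance for the
#' log-link Poisson uses the lognormal approximation
#' `log(1 + 1/lambda_bar)` with `lambda_bar` the model-implied mean count.
#'
#' @param fit A `trend_fit`.
#' @return A one-row tibble with `marginal_r2` and `conditional_r2`.
#' @export
r2_glmm <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  df <- fit$data
  beta <- fit$fixed$estimate[match(c("year_c", "listlength_c"), fit$fixed$term)]
  eta_fixed <- as.matrix(df[, c("year_c", "listlength_c")]) %*% beta
  var_f <- var(as.numeric(eta_fixed))
  var_r <- sum(fit$random$sd^2)
  lambda_bar <- mean(fitted(fit$model))
  var_d <- log(1 + 1 / lambda_bar)
  total <- var_f + var_r + var_d
  if (total <= 0) abort("Zero total variance: R2 undefined.")
  tibble(marginal_r2 = var_f / total,
         conditional_r2 = (var_f + var_r) / total)
}

#' Nonlinear (smooth) trend model
#'
#' Replaces the linear year term with a penalized spline of year, keeping
#' the list-length covariate, the log-duration offset, and random
#' intercepts for site and observation (as random-effect smooths). Used to
#' check that the log-linear trend is not an artifact of linearity.
#'
#' @inheritParams fit_trend_glmm
#' @param k Basis dimension for the year smooth (default: number of
#'   distinct years capped at 10).
#' @return An object of class `trend_smooth` with `per_year` fixed-effect
#'   predictions (relative to the first year) and the endpoint-to-endpoint
#'   annualized rate `annual_rate_percent`.
#' @export
fit_trend_smooth <- function(data, k = NULL) {
  df <- prepare_trend_data(data)
  n_years <- dplyr::n_distinct(df$year)
  if (n_years < 5) abort("Need at least 5 distinct years for a smooth trend.")
  k <- k %||% min(10, n_years - 1)
  df$site_f <- factor(df$site_id)
  model <- mgcv::gam(
    round_index ~ s(year_c, k = k) + listlength_c + s(site_f, bs = "re") +
      s(obs_id, bs = "re") + offset(log_duration),
    data = df, family = stats::poisson(), method = "REML")
  years <- seq(min(df$year), max(df$year))
  nd <- tibble(
    year_c = years - mean(df$year),
    listlength_c = 0,
    site_f = factor(levels(df$site_f)[1], levels = levels(df$site_f)),
    obs_id = factor(levels(df$obs_id)[1], levels = levels(df$obs_id)),
    log_duration = mean(df$log_duration)
  )
  pr <- predict(model, newdata = nd, type = "link", se.fit = TRUE,
                exclude = c("s(site_f)", "s(obs_id)"))
  per_year <- tibble(
    year = years,
    expected = exp(as.numeric(pr$fit)),
    lower = exp(as.numeric(pr$fit - 1.96 * pr$se.fit)),
    upper = exp(as.numeric(pr$fit + 1.96 * pr$se.fit))
  )
  span <- diff(range(years))
  rate <- 100 * ((per_year$expected[nrow(per_year)] / per_year$expected[1])^(1 / span) - 1)
  structure(list(
    model = model,
    per_year = per_year,
    annual_rate_percent = rate,
    n = nrow(df),
    year_range = range(df$year)
  ), class = "trend_smooth")
}

#' @export
print.trend_smooth <- function(x, ...) {
  cat(sprintf("Smooth trend fit (%d indices, %d-%d)\n",
              x$n, x$year_range[1], x$year_range[2]))
  cat(sprintf("  endpoint annualized rate %+.2f%% per year\n",
              x$annual_rate_percent))
  invisible(x)
}

#' One-row summary of a fitted trend
#'
#' @param fit A `trend_fit`.
#' @param span_years Span for the cumulative change (default: the fitted
#'   year range).
#' @param alpha Classification threshold.
#' @param ci Optional `trend_boot` from [bootstrap_trend_ci()] supplying
#'   interval bounds.
#' @return A one-row tibble: coefficient, SE, p, annual and cumulative
#'   percent rates, classification, and CI bounds when available.
#' @export
summarize_trend <- function(fit, span_years = NULL, alpha = 0.05, ci = NULL) {
  yr <- trend_coef(fit)
  span_years <- span_years %||% diff(fit$year_range)
  tibble(
    beta_year = yr$estimate,
    std_error = yr$se,
    p_value = yr$p,
    annual_rate_percent = annualized_rate(yr$estimate),
    cumulative_percent = cumulative_change(yr$estimate, span_years),
    span_years = span_years,
    classification = classify_trend(yr$estimate, p = yr$p, alpha = alpha),
    annual_lower = if (!is.null(ci)) ci$ci$annual_lower else NA_real_,
    annual_upper = if (!is.null(ci)) ci$ci$annual_upper else NA_real_
  )
}
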