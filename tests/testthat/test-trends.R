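test_that("annualized and cumulative rates follow the log-linear closed forms", {
  expect_equal(round(annualized_rate(-0.0203), 1), -2.0)
  expect_equal(annualized_rate(0), 0)
  expect_equal(annualized_rate(log(1.05)), 5, tolerance = 1e-12)
  expect_equal(round(cumulative_change(-0.0203, 20)), -33)
  expect_equal(round(annualized_rate(-0.070)), -7)
  expect_equal(cumulative_change(0, 15), 0)
  expect_error(cumulative_change(0.1, 0), "span_years")
})

test_that("annual and cumulative rates are mutually consistent", {
  withr::with_seed(2, {
    for (i in 1:25) {
      beta <- runif(1, -0.3, 0.3)
      span <- sample(1:40, 1)
      annual <- annualized_rate(beta)
      cumulative <- cumulative_change(beta, span)
      lhs <- (1 + annual / 100)^span
      rhs <- 1 + cumulative / 100
      expect_lt(abs(lhs - rhs), 1e-12 * max(1, abs(rhs)))
    }
  })
})

test_that("trend classification applies the sign and significance rule", {
  expect_equal(as.character(classify_trend(-0.233, p = 0.0005)), "negative")
  expect_equal(as.character(classify_trend(0.047, p = 0.022)), "positive")
  expect_equal(as.character(classify_trend(-0.105, p = 0.195)), "stable")
  # monotone in alpha: non-stable at 0.01 stays non-stable at 0.05
  withr::with_seed(3, {
    beta <- rnorm(200, 0, 0.1)
    p <- runif(200)
    strict <- classify_trend(beta, p = p, alpha = 0.01)
    loose <- classify_trend(beta, p = p, alpha = 0.05)
    expect_true(all(loose[strict != "stable"] != "stable"))
    expect_true(all(strict[strict != "stable"] == loose[strict != "stable"]))
  })
})

test_that("the Poisson GLM trend matches a hand-rolled IRLS oracle", {
  dat <- make_index_data(n_sites = 8, n_years = 12, beta0 = 0.5,
                         beta_year = -0.03, beta_ll = 0.08, seed = 10)
  fit <- fit_trend_glm(dat)

  # independent IRLS for Poisson regression with offset
  X <- cbind(1, dat$year - mean(dat$year),
             dat$mean_list_length - mean(dat$mean_list_length))
  y <- round(dat$index)
  off <- log(dat$projected_duration_min)
  beta <- rep(0, 3)
  for (i in 1:60) {
    eta <- X %*% beta + off
    mu <- exp(eta)
    W <- as.numeric(mu)
    z <- eta - off + (y - mu) / mu
    beta_new <- solve(t(X) %*% (X * W), t(X) %*% (W * z))
    if (max(abs(beta_new - beta)) < 1e-12) break
    beta <- beta_new
  }
  expect_equal(unname(fit$fixed$estimate), as.numeric(beta), tolerance = 1e-6)
})

test_that("the GLMM collapses to the GLM when random-effect variance is absent", {
  dat <- make_index_data(n_sites = 15, n_years = 10, beta0 = 1,
                         beta_year = -0.02, seed = 11)
  glmm <- suppressWarnings(fit_trend_glmm(dat))
  glm_fit <- fit_trend_glm(dat)
  expect_equal(glmm$fixed$estimate, glm_fit$fixed$estimate, tolerance = 1e-3)
})

test_that("the GLMM recovers variance components and a null trend", {
  dat <- make_index_data(n_sites = 30, n_years = 12, beta0 = 1,
                         beta_year = 0, sd_site = 0.4, sd_year = 0.12,
                         sd_obs = 0.28, seed = 12)
  fit <- fit_trend_glmm(dat)
  yr <- dplyr::filter(fit$fixed, term == "year_c")
  expect_lt(abs(yr$estimate), 2 * yr$std_error)
  sds <- setNames(fit$random$sd, fit$random$group)
  expect_equal(unname(sds["site"]), 0.4, tolerance = 0.5)
  expect_equal(unname(sds["observation"]), 0.28, tolerance = 0.4)
  expect_equal(fit$random$n_groups[fit$random$group == "site"], 30L)
  expect_equal(fit$random$n_groups[fit$random$group == "year"], 12L)
})

test_that("trend fits reject undersized or malformed inputs", {
  dat <- make_index_data(n_sites = 5, n_years = 3, seed = 13)
  expect_error(fit_trend_glmm(dat[1:5, ]), "at least 10")
  one_year <- dplyr::mutate(dat, year = 2000L)
  expect_error(fit_trend_glmm(one_year), "2 distinct years")
  bad_dur <- dplyr::mutate(dat, projected_duration_min = 0)
  expect_error(fit_trend_glmm(bad_dur), "positive")
  expect_error(fit_trend_glm(dat[0, ]), "at least 10")
})

test_that("the year coefficient is invariant to year relabelling and offset scaling", {
  dat <- make_index_data(n_sites = 12, n_years = 10, beta0 = 0.8,
                         beta_year = -0.025, seed = 14)
  base <- fit_trend_glm(dat)
  shifted <- fit_trend_glm(dplyr::mutate(dat, year = year + 100L))
  expect_equal(shifted$fixed$estimate[shifted$fixed$term == "year_c"],
               base$fixed$estimate[base$fixed$term == "year_c"],
               tolerance = 1e-6)
  doubled <- fit_trend_glm(dplyr::mutate(
    dat, projected_duration_min = 2 * projected_duration_min))
  expect_equal(doubled$fixed$estimate[doubled$fixed$term == "year_c"],
               base$fixed$estimate[base$fixed$term == "year_c"],
               tolerance = 1e-6)
  expect_equal(doubled$fixed$estimate[doubled$fixed$term == "(Intercept)"],
               base$fixed$estimate[base$fixed$term == "(Intercept)"] - log(2),
               tolerance = 1e-6)

  glmm_base <- suppressWarnings(fit_trend_glmm(dat))
  glmm_doubled <- suppressWarnings(fit_trend_glmm(dplyr::mutate(
    dat, projected_duration_min = 2 * projected_duration_min)))
  expect_equal(
    glmm_doubled$fixed$estimate[glmm_doubled$fixed$term == "year_c"],
    glmm_base$fixed$estimate[glmm_base$fixed$term == "year_c"],
    tolerance = 1e-4)
})

test_that("marginal and conditional R2 behave structurally", {
  null_dat <- make_index_data(n_sites = 15, n_years = 10, beta0 = 1,
                              beta_year = 0, beta_ll = 0, seed = 15)
  null_fit <- fit_trend_glm(null_dat)
  r2_null <- r2_glmm(null_fit)
  expect_lt(r2_null$marginal_r2, 0.05)
  expect_equal(r2_null$marginal_r2, r2_null$conditional_r2) # no REs

  re_dat <- make_index_data(n_sites = 25, n_years = 12, beta0 = 1,
                            beta_year = -0.02, sd_site = 0.4,
                            sd_obs = 0.28, seed = 16)
  re_fit <- suppressWarnings(fit_trend_glmm(re_dat))
  r2_re <- r2_glmm(re_fit)
  expect_gt(r2_re$conditional_r2, r2_re$marginal_r2)
  expect_true(all(unlist(r2_re) >= 0 & unlist(r2_re) <= 1))
})

test_that("the smooth trend agrees with the GLMM on log-linear truth", {
  dat <- make_index_data(n_sites = 20, n_years = 15, beta0 = 1,
                         beta_year = -0.03, sd_site = 0.2, sd_obs = 0.1,
                         seed = 17)
  glmm <- suppressWarnings(fit_trend_glmm(dat))
  smooth <- fit_trend_smooth(dat)
  expect_lt(abs(smooth$annual_rate_percent - annualized_rate(glmm)), 0.5)
  expect_equal(nrow(smooth$per_year), 15)
  few_years <- dplyr::filter(dat, year < 2004)
  expect_error(fit_trend_smooth(few_years), "5 distinct years")
})

test_that("the smooth trend stays flat when the truth is flat", {
  dat <- make_index_data(n_sites = 25, n_years = 12, beta0 = 1.5,
                         beta_year = 0, seed = 18)
  smooth <- fit_trend_smooth(dat)
  rel <- smooth$per_year$expected / mean(smooth$per_year$expected)
  expect_lt(max(abs(rel - 1)), 0.05)
})

test_that("the parametric bootstrap is deterministic and honours its contract", {
  dat <- make_index_data(n_sites = 10, n_years = 8, beta0 = 1,
                         beta_year = 0, sd_site = 0.2, sd_obs = 0.15,
                         seed = 19)
  fit <- suppressWarnings(fit_trend_glmm(dat))
  expect_error(bootstrap_trend_ci(fit, n_boot = 0), "n_boot")
  b1 <- bootstrap_trend_ci(fit, n_boot = 30, seed = 5)
  b2 <- bootstrap_trend_ci(fit, n_boot = 30, seed = 5)
  expect_identical(b1$ci, b2$ci)
  # null truth: the interval should cover zero
  expect_lt(b1$ci$beta_lower, 0)
  expect_gt(b1$ci$beta_upper, 0)
  glm_fit <- fit_trend_glm(dat)
  expect_error(bootstrap_trend_ci(glm_fit, n_boot = 10), "GLMM")
})

test_that("trend summaries and tidiers expose the fitted quantities", {
  dat <- make_index_data(n_sites = 15, n_years = 12, beta0 = 1,
                         beta_year = -0.05, sd_site = 0.2, sd_obs = 0.1,
                         seed = 20)
  fit <- suppressWarnings(fit_trend_glmm(dat))
  s <- summarize_trend(fit, span_years = 20)
  expect_equal(s$cumulative_percent,
               cumulative_change(s$beta_year, 20), tolerance = 1e-12)
  td <- tidy(fit, effects = "all")
  expect_true(all(c("(Intercept)", "year_c", "listlength_c") %in% td$term))
  expect_true(all(c("site", "year", "observation") %in%
                    td$term[td$effect == "ran_pars"]))
  g <- glance(fit)
  expect_equal(g$nobs, nrow(dat))
  expect_s3_class(autoplot(fit), "ggplot")
})
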