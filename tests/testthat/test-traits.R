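test_that("the Brownian covariance matrix follows shared path lengths", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(brownian_vcv(two)), diag(2))
  three <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- brownian_vcv(three, species = c("A", "B", "C"))
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["A", "A"], 2)
  star <- ape::read.tree(text = "(A:1,B:2,C:3);")
  expect_true(all(brownian_vcv(star)[upper.tri(diag(3))] == 0))
  expect_error(brownian_vcv(three, species = c("A", "Z")), "Z")
})

test_that("Brownian covariance matrices are symmetric positive semi-definite", {
  for (seed in 1:5) {
    tr <- withr::with_seed(seed, ape::rcoal(20))
    V <- brownian_vcv(tr)
    expect_true(isSymmetric(V))
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("the lambda transform scales only the off-diagonal", {
  V <- brownian_vcv(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(unname(lambda_transform(V, 0)), diag(diag(V)))
  half <- lambda_transform(V, 0.5)
  expect_equal(half["A", "B"], 0.5)
  expect_equal(diag(half), diag(V))
  expect_error(lambda_transform(V, 1.2), "lambda")
  expect_error(lambda_transform(V, -0.1), "lambda")
})

test_that("PGLS with lambda fixed at zero reproduces OLS exactly", {
  withr::with_seed(41, {
    tr <- ape::rcoal(30)
    dat <- tibble::tibble(
      species_id = tr$tip.label,
      trait = rnorm(30),
      beta_year = 0.5 * trait + rnorm(30, 0, 0.2)
    )
  })
  pg <- fit_pgls(dat, beta_year ~ trait, tr, lambda = 0)
  ols <- lm(beta_year ~ trait, data = dat)
  expect_equal(pg$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
})

test_that("the profile likelihood peaks at the returned lambda", {
  withr::with_seed(42, {
    tr <- ape::rcoal(40)
    x <- ape::rTraitCont(tr, sigma = 1)
    y <- 0.4 * x + ape::rTraitCont(tr, sigma = 0.5)
    dat <- tibble::tibble(species_id = tr$tip.label, trait = x, beta_year = y)
  })
  fit <- fit_pgls(dat, beta_year ~ trait, tr)
  expect_true(all(fit$log_likelihood >= fit$profile$log_likelihood - 1e-6))
  expect_gte(fit$lambda, 0)
  expect_lte(fit$lambda, 1)
})

test_that("PGLS agrees with the gls/corPagel reference implementation", {
  skip_if_not_installed("nlme")
  withr::with_seed(43, {
    tr <- ape::rcoal(35)
    x <- ape::rTraitCont(tr, sigma = 1)
    y <- 0.3 * x + ape::rTraitCont(tr, sigma = 0.7)
    dat <- tibble::tibble(species_id = tr$tip.label, trait = x, beta_year = y)
  })
  # at a fixed lambda the two implementations are the same GLS
  fixed <- fit_pgls(dat, beta_year ~ trait, tr, lambda = 0.7)
  ref_fixed <- nlme::gls(
    beta_year ~ trait, data = as.data.frame(dat),
    correlation = ape::corPagel(0.7, tr, form = ~species_id, fixed = TRUE),
    method = "ML")
  expect_equal(unname(fixed$coefficients$estimate), unname(coef(ref_fixed)),
               tolerance = 1e-6)

  # and the two ML profiles land on nearby lambda values
  mine <- fit_pgls(dat, beta_year ~ trait, tr)
  ref <- nlme::gls(
    beta_year ~ trait, data = as.data.frame(dat),
    correlation = ape::corPagel(0.5, tr, form = ~species_id),
    method = "ML")
  lambda_ref <- unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(mine$lambda, lambda_ref, tolerance = 0.05)
})

test_that("an exact linear response on a star tree gives R2 of one", {
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", 1:12), collapse = ","), ");"))
  dat <- tibble::tibble(species_id = star$tip.label,
                        trait = seq(-1, 1, length.out = 12),
                        beta_year = 2 + 3 * trait)
  fit <- suppressWarnings(fit_pgls(dat, beta_year ~ trait, star))
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-12)
  expect_equal(fit$coefficients$estimate, c(2, 3), tolerance = 1e-8)
})

test_that("species absent from the tree are dropped with a warning", {
  withr::with_seed(44, {
    tr <- ape::rcoal(15)
    dat <- tibble::tibble(
      species_id = c(tr$tip.label, "ghost"),
      trait = rnorm(16),
      beta_year = rnorm(16)
    )
  })
  expect_warning(fit <- fit_pgls(dat, beta_year ~ trait, tr), "ghost")
  expect_equal(fit$n_species, 15)
})

test_that("univariate trait models report coefficients and adjusted R2", {
  withr::with_seed(45, {
    dat <- tibble::tibble(
      species_id = sprintf("sp%d", 1:20),
      wing_length_mm = runif(20, 15, 45),
      host_category = sample(c("forb", "woody"), 20, replace = TRUE),
      migratory = rep(c(TRUE, FALSE), c(4, 16)),
      beta_year = -0.1 + 0.004 * wing_length_mm
    )
  })
  exact <- suppressWarnings(fit_trait_ols(dat, "wing_length_mm"))
  expect_equal(exact$adj_r_squared, 1, tolerance = 1e-10)
  expect_error(fit_trait_ols(dplyr::mutate(dat, host_category = "forb"),
                             "host_category"), "constant")
  toy <- dat[1:5, ]
  toy$migratory <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  sub <- suppressWarnings(fit_trait_ols(toy, "wing_length_mm", exclude_migratory = TRUE))
  expect_equal(sub$n_species, 3)
})

test_that("adjusted R2 is centred on zero under a pure-noise response", {
  r2 <- withr::with_seed(46, {
    trait <- rnorm(81)
    replicate(200, {
      dat <- tibble::tibble(species_id = sprintf("sp%d", 1:81),
                            trait = trait, beta_year = rnorm(81))
      fit_trait_ols(dat, "trait")$adj_r_squared
    })
  })
  expect_lt(abs(mean(r2)), 0.02)
})

test_that("the trait scan assembles OLS and PGLS rows per trait", {
  withr::with_seed(47, {
    tr <- ape::rcoal(20)
    dat <- tibble::tibble(
      species_id = tr$tip.label,
      voltinism = sample(c("univoltine", "bivoltine"), 20, replace = TRUE),
      wing_length_mm = runif(20, 15, 45),
      migratory = FALSE,
      beta_year = rnorm(20, -0.02, 0.05)
    )
  })
  scan <- suppressWarnings(
    fit_trait_models(dat, c("voltinism", "wing_length_mm"), tree = tr))
  expect_setequal(unique(scan$method), c("ols", "pgls"))
  expect_setequal(unique(scan$trait), c("voltinism", "wing_length_mm"))
  expect_true(all(is.na(scan$lambda[scan$method == "ols"])))
  expect_true(all(scan$lambda[scan$method == "pgls"] >= 0 &
                    scan$lambda[scan$method == "pgls"] <= 1))
  # reference level is the alphabetically first: bivoltine absorbed in intercept
  expect_true("voltinismunivoltine" %in% scan$term)
})
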