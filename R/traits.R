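#' Brownian-motion covariance matrix from a phylogeny
#'
#' Under Brownian motion the covariance between two species equals the
#' shared branch length from the root to their most recent common
#' ancestor; the diagonal is each tip's root-to-tip depth.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param species Optional character vector: require exactly these tips
#'   (an error lists any absentees) and return the matrix in this order.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
brownian_vcv <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    abort("Tree must have finite branch lengths.")
  }
  if (anyDuplicated(tree$tip.label)) abort("Tip labels must be unique.")
  V <- ape::vcv.phylo(tree)
  if (!is.null(species)) {
    absent <- setdiff(species, rownames(V))
    if (length(absent)) {
      abort(paste0("Species missing from the tree: ",
                   paste(absent, collapse = ", ")))
    }
    V <- V[species, species, drop = FALSE]
  }
  V
}

#' Pagel's lambda transformation of a phylogenetic covariance matrix
#'
#' Scales the off-diagonal (shared-history) covariances by
#' `lambda` in `[0, 1]`, leaving the diagonal unchanged: `lambda = 0`
#' gives the OLS (star-phylogeny) structure, `lambda = 1` returns the
#' matrix unchanged.
#'
#' @param V Symmetric covariance matrix.
#' @param lambda Scalar in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single value in [0, 1].")
  }
  if (!isSymmetric(unname(V))) abort("`V` must be symmetric.")
  W <- lambda * V
  diag(W) <- diag(V)
  W
}

pgls_loglik <- function(lambda, y, X, V) {
  n <- length(y)
  W <- lambda_transform(V, lambda)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  # whiten: solve L' z = x  with W = L'L (chol gives upper U, W = U'U)
  wy <- backsolve(ch, y, transpose = TRUE)
  wX <- backsolve(ch, X, transpose = TRUE)
  qrX <- qr(wX)
  beta <- qr.coef(qrX, wy)
  r <- wy - wX %*% beta
  sigma2 <- sum(r^2) / n
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' Regresses species-level trend coefficients on a trait while modelling
#' residual covariance as a Brownian-motion structure whose off-diagonal
#' entries are scaled by Pagel's lambda. Lambda is estimated by bounded
#' scalar optimization of the profile log-likelihood over `[0, 1]`
#' (tolerance 1e-6) unless fixed via `lambda`.
#'
#' @param data Tibble with a `species_id` column, the response and the
#'   trait column(s) named in `formula`. Species absent from the tree are
#'   dropped with a warning.
#' @param formula Model formula, e.g. `beta_year ~ voltinism`.
#' @param tree An [ape::phylo] tree whose tips cover the species.
#' @param lambda Optional fixed lambda in `[0, 1]`; `NULL` (default)
#'   estimates it by maximum likelihood.
#' @return An object of class `pgls_fit`: coefficient table (estimates,
#'   SEs, t statistics, p-values on `n - p` df), `lambda`,
#'   `log_likelihood`, the 21-point profile over lambda, `r_squared`, and
#'   `n_species`.
#' @export
fit_pgls <- function(data, formula, tree, lambda = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!"species_id" %in% names(data)) abort("`data` needs a `species_id` column.")
  in_tree <- data$species_id %in% tree$tip.label
  if (!all(in_tree)) {
    warn(paste0("Dropping species not in the tree: ",
                paste(data$species_id[!in_tree], collapse = ", ")))
    data <- data[in_tree, ]
  }
  if (nrow(data) < 10) abort("Need at least 10 species for PGLS.")
  mf <- stats::model.frame(formula, data = as.data.frame(data))
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) abort("Singular design matrix.")
  V <- brownian_vcv(ape::keep.tip(tree, data$species_id),
                    species = data$species_id)

  lambda_grid <- seq(0, 1, length.out = 21)
  profile <- tibble(
    lambda = lambda_grid,
    log_likelihood = purrr::map_dbl(lambda_grid, pgls_loglik,
                                    y = y, X = X, V = V)
  )
  if (is.null(lambda)) {
    opt <- optimize(pgls_loglik, c(0, 1), y = y, X = X, V = V,
                    maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective, profile$log_likelihood[c(1, 21)])
    lambda_hat <- cand[which.max(ll)]
    if (diff(range(profile$log_likelihood[is.finite(profile$log_likelihood)])) < 1.92) {
      warn("Profile likelihood is nearly flat in lambda (wide profile).")
    }
  } else {
    lambda_hat <- lambda
  }

  W <- lambda_transform(V, lambda_hat)
  ch <- chol(W)
  wy <- backsolve(ch, y, transpose = TRUE)
  wX <- backsolve(ch, X, transpose = TRUE)
  qrX <- qr(wX)
  beta <- qr.coef(qrX, wy)
  r <- wy - wX %*% beta
  n <- length(y)
  p <- ncol(X)
  sigma2 <- sum(r^2) / (n - p)
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(0, sigma2 * diag(XtX_inv)))
  tstat <- as.numeric(beta) / ifelse(se > 0, se, NA_real_)
  # null (intercept-only) GLS residuals for an R-squared on the whitened scale
  w1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  mu0 <- sum(w1 * wy) / sum(w1^2)
  r0 <- wy - w1 * mu0
  r_squared <- if (sum(r0^2) > 0) 1 - sum(r^2) / sum(r0^2) else NA_real_

  structure(list(
    coefficients = tibble(
      term = colnames(X),
      estimate = as.numeric(beta),
      std_error = se,
      statistic = tstat,
      p_value = 2 * pt(abs(tstat), df = n - p, lower.tail = FALSE)
    ),
    lambda = lambda_hat,
    lambda_fixed = !is.null(lambda),
    log_likelihood = pgls_loglik(lambda_hat, y, X, V),
    profile = profile,
    sigma2 = sigma2,
    r_squared = r_squared,
    n_species = n,
    formula = formula
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (%d species), Pagel's lambda %s= %.3f, logLik %.2f\n",
              x$n_species, if (x$lambda_fixed) "fixed " else "", x$lambda,
              x$log_likelihood))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Univariate linear model of trend on one life-history trait
#'
#' Ordinary least squares of species' trend coefficients on a single
#' trait, reporting level-wise coefficients and the adjusted R-squared.
#' Optionally excludes migratory species, whose trends are driven by
#' factors outside the monitored region.
#'
#' @param data Species-level tibble with the response, the trait, and
#'   (if `exclude_migratory`) a logical `migratory` column.
#' @param trait Trait column name (string).
#' @param response Response column name (default `"beta_year"`).
#' @param exclude_migratory Drop migratory species before fitting.
#' @return An object of class `trait_ols`: the lm fit, coefficient table,
#'   `adj_r_squared`, and `n_species`.
#' @export
fit_trait_ols <- function(data, trait, response = "beta_year",
                          exclude_migratory = FALSE) {
  if (!trait %in% names(data)) abort(paste0("Trait column not found: ", trait))
  if (exclude_migratory) data <- filter(data, !.data$migratory)
  if (nrow(data) < 3) abort("Need at least 3 species.")
  if (dplyr::n_distinct(data[[trait]]) < 2) {
    abort(paste0("Trait is constant: ", trait))
  }
  fml <- stats::reformulate(trait, response = response)
  model <- lm(fml, data = as.data.frame(data))
  cf <- stats::coef(summary(model))
  structure(list(
    model = model,
    trait = trait,
    coefficients = tibble(
      term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
      statistic = cf[, 3], p_value = cf[, 4]
    ),
    adj_r_squared = summary(model)$adj.r.squared,
    n_species = nrow(data)
  ), class = "trait_ols")
}

#' @export
print.trait_ols <- function(x, ...) {
  cat(sprintf("OLS trait model: %s (%d species), adj. R2 = %.3f\n",
              x$trait, x$n_species, x$adj_r_squared))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Scan all life-history traits with OLS and PGLS
#'
#' Fits one univariate model per trait: always OLS, and PGLS with
#' ML Pagel's lambda when a tree is supplied. Categorical traits are
#' dummy-coded with the alphabetically first level as reference.
#'
#' @param data Species-level tibble: `species_id`, the response, trait
#'   columns, and `migratory`.
#' @param traits Character vector of trait column names.
#' @param tree Optional [ape::phylo] tree enabling the PGLS fits.
#' @param response Response column (default `"beta_year"`).
#' @param exclude_migratory Drop migratory species first.
#' @return A tidy tibble: `trait`, `method` (`"ols"`/`"pgls"`), `term`,
#'   `estimate`, `std_error`, `p_value`, `adj_r_squared` (OLS),
#'   `lambda` (PGLS), `n_species`.
#' @export
fit_trait_models <- function(data, traits, tree = NULL,
                             response = "beta_year",
                             exclude_migratory = FALSE) {
  if (exclude_migratory) data <- filter(data, !.data$migratory)
  purrr::map(traits, function(tr) {
    ols <- fit_trait_ols(data, tr, response = response)
    out <- ols$coefficients |>
      mutate(trait = tr, method = "ols", adj_r_squared = ols$adj_r_squared,
             lambda = NA_real_, n_species = ols$n_species)
    if (!is.null(tree)) {
      pg <- fit_pgls(data, stats::reformulate(tr, response = response), tree)
      out <- bind_rows(out, pg$coefficients |>
                         mutate(trait = tr, method = "pgls",
                                adj_r_squared = NA_real_,
                                lambda = pg$lambda,
                                n_species = pg$n_species))
    }
    out
  }) |>
    purrr::list_rbind() |>
    select("trait", "method", "term", "estimate", "std_error",
           "statistic", "p_value", "adj_r_squared", "lambda", "n_species")
}

#' Random coalescent phylogeny over a species set
#'
#' Convenience wrapper producing an ultrametric tree whose tips are the
#' supplied species identifiers, for simulation studies of the
#' comparative methods.
#'
#' @param species_ids Character vector of tip labels.
#' @param seed Integer seed.
#' @return An [ape::phylo] tree.
#' @export
sim_phylogeny <- function(species_ids, seed = 1L) {
  withr::with_seed(seed, {
    tr <- ape::rcoal(length(species_ids))
    tr$tip.label <- species_ids
    tr
  })
}
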