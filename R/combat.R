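#' Fit a ComBat harmonization model
#'
#' Parametric empirical-Bayes location/scale harmonization of a
#' patients-by-features table across sites (institutions/scanners). Each
#' feature is standardized by its grand mean and pooled standard deviation;
#' per-site additive effects gamma and multiplicative effects delta are then
#' shrunk towards parametric priors (normal on gamma, inverse-gamma on
#' delta^2) with the usual iterative conditional update, run until the
#' relative change falls below `tol` (default 1e-6) or `max_iter` iterations.
#'
#' Outcome labels are never used; the covariate design defaults to
#' intercept-only. Features with zero pooled variance are passed through
#' unchanged with a warning.
#'
#' @param features numeric data.frame/matrix, patients x features, no
#'   missing values.
#' @param site per-patient site labels (>= 2 sites, each with >= 2 patients).
#' @param covariates optional numeric design matrix of biological covariates
#'   to preserve (no intercept column; added internally).
#' @param tol,max_iter empirical-Bayes iteration control.
#' @return An object of class `combat_model`.
#' @export
fit_combat <- function(features, site, covariates = NULL,
                       tol = 1e-6, max_iter = 500L) {
  X <- as.matrix(features)
  if (!is.numeric(X) || anyNA(X) || !all(is.finite(X)))
    stop("features must be a finite numeric table with no missing values")
  site <- as.character(site)
  if (length(site) != nrow(X)) stop("site must have one label per patient")
  sites <- sort(unique(site))
  if (length(sites) < 2L) stop("at least 2 sites are required to harmonize")
  ni <- table(site)
  if (any(ni < 2L)) stop("every site needs >= 2 patients")
  n <- nrow(X); G <- ncol(X)

  B <- stats::model.matrix(~ factor(site, levels = sites) - 1)
  colnames(B) <- sites
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    design <- cbind(B, C)
  } else { C <- NULL; design <- B }
  beta_hat <- solve(crossprod(design), crossprod(design, X))  # per-feature OLS
  gamma_hat0 <- beta_hat[seq_along(sites), , drop = FALSE]
  wts <- as.numeric(ni[sites]) / n
  grand_mean <- as.numeric(crossprod(wts, gamma_hat0))
  stand_mean <- matrix(grand_mean, n, G, byrow = TRUE)
  if (!is.null(C))
    stand_mean <- stand_mean + C %*% beta_hat[-seq_along(sites), , drop = FALSE]
  var_pooled <- colMeans((X - design %*% beta_hat)^2)
  zero_var <- var_pooled <= .Machine$double.eps
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance feature(s) passed through unchanged")
    var_pooled[zero_var] <- 1
  }
  sig <- sqrt(var_pooled)
  Z <- sweep(X - stand_mean, 2L, sig, "/")

  gamma_star <- delta2_star <- matrix(NA_real_, length(sites), G,
                                      dimnames = list(sites, colnames(X)))
  priors <- list()
  for (s in sites) {
    zi <- Z[site == s, , drop = FALSE]
    m <- nrow(zi)
    g_hat <- colMeans(zi)
    d_hat <- apply(zi, 2L, var)
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    dm <- mean(d_hat); ds2 <- var(d_hat)
    if (!is.finite(ds2) || ds2 <= 0) ds2 <- 1e-8
    a_prior <- (2 * ds2 + dm^2) / ds2          # inverse-gamma moments
    b_prior <- (dm * ds2 + dm^3) / ds2
    g_new <- g_hat; d_new <- d_hat
    ssq <- function(gam) colMeans(sweep(zi, 2L, gam, "-")^2) * m
    for (it in seq_len(max_iter)) {
      g_old <- g_new; d_old <- d_new
      g_new <- (m * t2 * g_hat + d_new * g_bar) / (m * t2 + d_new)
      d_new <- (b_prior + 0.5 * ssq(g_new)) / (m / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      if (change < tol) break
    }
    gamma_star[s, ] <- g_new
    delta2_star[s, ] <- d_new
    priors[[s]] <- list(gamma_bar = g_bar, tau2 = t2,
                        lambda = a_prior, theta = b_prior, n = m)
  }
  structure(list(sites = sites, grand_mean = grand_mean,
                 beta_cov = if (is.null(C)) NULL
                            else beta_hat[-seq_along(sites), , drop = FALSE],
                 sigma = sig, zero_var = zero_var,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 priors = priors, features = colnames(X)),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d features, %d sites (%s)\n",
              length(x$features), length(x$sites),
              paste(x$sites, collapse = ", ")))
  invisible(x)
}

#' Serialize a ComBat model to JSON
#'
#' Stores the grand means, pooled SDs, per-site empirical-Bayes effects and
#' prior hyperparameters.
#'
#' @param model a [fit_combat()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_combat_json <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  obj <- list(sites = model$sites, features = model$features,
              grand_mean = model$grand_mean, sigma = unname(model$sigma),
              zero_var = unname(model$zero_var),
              gamma_star = setNames(lapply(model$sites, function(s)
                unname(model$gamma_star[s, ])), model$sites),
              delta2_star = setNames(lapply(model$sites, function(s)
                unname(model$delta2_star[s, ])), model$sites),
              priors = model$priors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply a fitted ComBat model to a feature table
#'
#' `y* = sigma * (z - gamma*) / delta* + alpha (+ covariate part)` where `z`
#' is the standardized value. Zero-variance features are returned unchanged.
#'
#' @param model a [fit_combat()] result.
#' @param features patients x features table with the model's feature
#'   columns.
#' @param site per-patient site labels; all must be known to the model.
#' @param covariates covariate matrix matching the one used at fit time.
#' @return data.frame of harmonized features, same shape as `features`.
#' @export
apply_combat <- function(model, features, site, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  X <- as.matrix(features)
  if (!identical(colnames(X), model$features))
    X <- X[, model$features, drop = FALSE]
  site <- as.character(site)
  if (!all(site %in% model$sites))
    stop("unseen site label(s): ",
         paste(setdiff(site, model$sites), collapse = ", "))
  n <- nrow(X); G <- ncol(X)
  stand_mean <- matrix(model$grand_mean, n, G, byrow = TRUE)
  if (!is.null(model$beta_cov)) {
    if (is.null(covariates)) stop("model was fitted with covariates")
    stand_mean <- stand_mean + as.matrix(covariates) %*% model$beta_cov
  }
  Z <- sweep(X - stand_mean, 2L, model$sigma, "/")
  out <- Z
  for (s in unique(site)) {
    rows <- site == s
    zi <- sweep(Z[rows, , drop = FALSE], 2L, model$gamma_star[s, ], "-")
    out[rows, ] <- sweep(zi, 2L, sqrt(model$delta2_star[s, ]), "/")
  }
  out <- sweep(out, 2L, model$sigma, "*") + stand_mean
  out[, model$zero_var] <- X[, model$zero_var]
  as.data.frame(out)
}
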