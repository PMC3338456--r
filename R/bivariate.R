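#' Fractional logistic regression for proportion responses
#'
#' Quasi-likelihood logit-link regression for responses in the closed unit
#' interval (occupancy rates built from a handful of surveys). Coefficients
#' maximize the Bernoulli quasi-log-likelihood
#' `sum(y * log(mu) + (1 - y) * log(1 - mu))` with `mu = plogis(X %*% beta)`;
#' standard errors are heteroskedasticity-robust (sandwich, HC0), since the
#' quasi-likelihood variance function is not assumed correct.
#'
#' @param y Numeric response in `[0, 1]`.
#' @param X Covariates: data frame, matrix, or NULL for an intercept-only
#'   model. An intercept column is always added.
#' @return Object of class `fractional_logit_fit`: coefficients, robust
#'   SEs, z statistics and p-values, fitted values, fractional-response
#'   deviance residuals, Spearman correlation of predicted vs observed,
#'   and a `converged` flag (FALSE with a `diagnostic` message under
#'   perfect separation).
#' @examples
#' f <- fit_fractional_logit(c(0, 1/3, 2/3, 1), data.frame(w = 1:4))
#' f$coefficients
#' @export
fit_fractional_logit <- function(y, X = NULL) {
  assert_that(is.numeric(y) && all(is.finite(y)) && all(y >= 0 & y <= 1),
              "y must be proportions in [0, 1]")
  n <- length(y)
  if (is.null(X)) {
    Xm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xd <- as.data.frame(X)
    assert_that(nrow(Xd) == n, "X must have one row per observation")
    Xm <- cbind("(Intercept)" = 1, as.matrix(Xd))
  }
  assert_that(qr(Xm)$rank == ncol(Xm), "X (with intercept) must be full column rank")

  fit <- suppressWarnings(
    glm.fit(Xm, y, family = quasibinomial("logit"),
            control = list(maxit = 100))
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  eps <- 1e-10
  separated <- !fit$converged || any(mu < eps | mu > 1 - eps) ||
    max(abs(beta)) > 30
  diagnostic <- if (separated)
    "quasi-likelihood maximization did not converge (possible perfect separation)"
  else NA_character_

  # sandwich (HC0): bread = (X'WX)^-1 with W = mu(1-mu); meat from the
  # score x_i * (y_i - mu_i)
  w <- mu * (1 - mu)
  bread <- solve(crossprod(Xm * sqrt(w)))
  sc <- Xm * (y - mu)
  vc <- bread %*% crossprod(sc) %*% bread
  se <- sqrt(diag(vc))
  z <- beta / se
  pv <- 2 * pnorm(-abs(z))

  # fractional-response deviance residuals (0*log(0) treated as 0)
  term <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  d2 <- 2 * (term(y, mu) + term(1 - y, 1 - mu))
  dres <- sign(y - mu) * sqrt(pmax(d2, 0))

  rho <- if (length(unique(y)) < 2L || length(unique(mu)) < 2L)
    NA_real_ else spearman_rho(mu, y, warn = FALSE)

  structure(list(
    coefficients = beta, se = se, z = z, p_values = pv, vcov = vc,
    fitted = mu, deviance_residuals = dres, spearman_pred_obs = rho,
    converged = !separated, diagnostic = diagnostic, n = n,
    quasi_loglik = sum(ifelse(y == 0, 0, y * log(mu)) +
                         ifelse(y == 1, 0, (1 - y) * log(1 - mu)))
  ), class = "fractional_logit_fit")
}

#' @export
print.fractional_logit_fit <- function(x, ...) {
  cat("Fractional logistic regression (robust SEs)\n")
  print(data.frame(estimate = x$coefficients, se = x$se, p = x$p_values))
  cat(sprintf("Spearman rho (pred vs obs): %.3f; converged: %s\n",
              x$spearman_pred_obs, x$converged))
  invisible(x)
}

# Profile log-likelihood of the Box-Cox transform at lambda (includes the
# Jacobian term (lambda - 1) * sum(log y))
boxcox_profile_ll <- function(y, x, lambda, degree = 1L) {
  yt <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  X <- stats::poly(x, degree = degree, raw = TRUE)
  r <- stats::lm.fit(cbind(1, X), yt)$residuals
  n <- length(y)
  -n / 2 * log(sum(r^2) / n) + (lambda - 1) * sum(log(y))
}

#' Linear/quadratic regression with AIC selection and optional Box-Cox
#'
#' Fits degree-1 and (optionally) degree-2 polynomial OLS regressions of
#' `y` on `x` and selects the model minimizing
#' `AIC = n * log(RSS / n) + 2k` (k = number of estimated parameters
#' including the error variance). If `box_cox = TRUE`, the Box-Cox
#' exponent maximizing the profile log-likelihood (Jacobian included) is
#' estimated first and the response is transformed before fitting; AIC is
#' then reported on the transformed scale with the Jacobian correction so
#' values remain comparable across lambda.
#'
#' @param y Numeric response (strictly positive when `box_cox = TRUE`).
#' @param x Numeric covariate.
#' @param allow_quadratic Also fit a quadratic and let AIC choose.
#' @param box_cox Estimate a Box-Cox transformation of `y` first.
#' @return Object of class `linear_fit`: `degree`, `coefficients`
#'   (intercept first), `r_squared`, `p_values`, `aic` (selected model),
#'   `aic_by_degree`, `box_cox_lambda` (NULL unless requested), `fitted`,
#'   `residuals`.
#' @export
fit_linear_aic <- function(y, x, allow_quadratic = TRUE, box_cox = FALSE) {
  assert_that(is.numeric(y) && is.numeric(x) && length(y) == length(x),
              "y and x must be equal-length numeric vectors")
  n <- length(y)
  assert_that(n >= 4, "at least 4 observations required")
  lambda <- NULL
  jac <- 0
  if (box_cox) {
    assert_that(all(y > 0), "Box-Cox requires strictly positive y")
    opt <- optimize(function(l) boxcox_profile_ll(y, x, l),
                    interval = c(-2, 2), maximum = TRUE, tol = 1e-6)
    lambda <- opt$maximum
    jac <- -2 * (lambda - 1) * sum(log(y))   # AIC correction term
    y <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  }
  degrees <- if (allow_quadratic) 1:2 else 1L
  fits <- lapply(degrees, function(d) lm(y ~ stats::poly(x, d, raw = TRUE)))
  aics <- vapply(seq_along(degrees), function(i) {
    # floor the RSS near machine precision so an exactly-fitting lower
    # degree is preferred over an equally-exact higher degree
    rss <- max(sum(fits[[i]]$residuals^2),
               .Machine$double.eps * sum(y^2))
    k <- degrees[i] + 2   # coefficients + error variance
    n * log(rss / n) + 2 * k + jac
  }, numeric(1))
  best <- which.min(aics)
  fit <- fits[[best]]
  sm <- summary(fit)
  cf <- unname(coef(fit))
  structure(list(
    degree = degrees[best],
    coefficients = cf,
    r_squared = sm$r.squared,
    p_values = unname(sm$coefficients[, 4]),
    aic = aics[best],
    aic_by_degree = setNames(aics, paste0("degree", degrees)),
    box_cox_lambda = lambda,
    fitted = unname(fit$fitted.values),
    residuals = unname(fit$residuals),
    n = n
  ), class = "linear_fit")
}

#' Spearman rank correlation
#'
#' Rank correlation using average (mid-) ranks for ties. Constant input has
#' no defined rank correlation and yields `NA` with a warning.
#'
#' @param a,b Equal-length numeric vectors, length >= 3.
#' @param warn Warn on constant input (default TRUE).
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(a, b, warn = TRUE) {
  assert_that(length(a) == length(b) && length(a) >= 3,
              "a and b must have equal length >= 3")
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    if (warn) warning("Spearman correlation undefined for constant input")
    return(NA_real_)
  }
  cor(rank(a), rank(b))
}

#' Normality summary for deviance residuals
#'
#' Reports skewness, excess kurtosis and a Shapiro-Wilk omnibus test for
#' the deviance residuals of a fractional-logit fit (or any numeric
#' vector). Intended for goodness-of-fit reporting; it does not gate the
#' pipeline.
#'
#' @param fit A `fractional_logit_fit` or numeric vector of residuals.
#' @return List with `skewness`, `kurtosis_excess`, `statistic` (W),
#'   `p_value`, `test` ("shapiro-wilk") and `degenerate` (TRUE when the
#'   residuals are essentially constant, in which case the test is NA).
#' @export
deviance_residual_normality <- function(fit) {
  r <- if (inherits(fit, "fractional_logit_fit")) fit$deviance_residuals
       else as.numeric(fit)
  assert_that(length(r) >= 3, "need at least 3 residuals")
  if (sd(r) < 1e-12) {
    return(list(skewness = NA_real_, kurtosis_excess = NA_real_,
                statistic = NA_real_, p_value = NA_real_,
                test = "shapiro-wilk", degenerate = TRUE))
  }
  mo <- sample_moments(r)
  sw <- shapiro.test(r)
  list(skewness = mo$skewness, kurtosis_excess = mo$kurtosis_excess,
       statistic = unname(sw$statistic), p_value = sw$p.value,
       test = "shapiro-wilk", degenerate = FALSE)
}

#' Exploratory bivariate regression table for a meadow-year dataset
#'
#' Reproduces the exploratory stage on meadow-level aggregates: occupancy
#' rate vs wetness (fractional logit, optionally with utilization and a
#' utilization-by-wetness interaction), and linear/quadratic fits of
#' utilization, fecal density, peak biomass and forage quality against the
#' composite hydrologic rank.
#'
#' @param meadow_years Meadow-year table from [simulate_study()] (or CSV
#'   with the same columns).
#' @param interaction Include the utilization x wetness product term in
#'   the occupancy-rate model.
#' @return A tidy data frame: model, term, estimate, se, p, statistic
#'   columns (`r_squared`, `spearman`, `aic`, `lambda` where applicable).
#' @export
bivariate_table <- function(meadow_years, interaction = TRUE) {
  my <- meadow_years[!duplicated(meadow_years$meadow), ]
  w <- my$composite_rank
  util <- rowMeans(my[, grep("^utilization_", names(my)), drop = FALSE])
  rows <- list()
  add <- function(model, term, estimate, se = NA, p = NA,
                  r_squared = NA, spearman = NA, aic = NA, lambda = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, term = term, estimate = estimate, se = se, p = p,
      r_squared = r_squared, spearman = spearman, aic = aic, lambda = lambda)
  }

  fl <- fit_fractional_logit(my$occupancy_rate, data.frame(wetness = w))
  for (i in seq_along(fl$coefficients))
    add("occupancy_rate~wetness", names(fl$coefficients)[i],
        fl$coefficients[i], fl$se[i], fl$p_values[i],
        spearman = fl$spearman_pred_obs)

  Xo <- data.frame(wetness = w, utilization = util)
  if (interaction) Xo$wetness_x_utilization <- w * util
  # tiny or degenerate designs can make this model rank deficient; the
  # richer occupancy model is then skipped rather than aborting the table
  fl2 <- tryCatch(fit_fractional_logit(my$occupancy_rate, Xo),
                  meadowsem_validation_error = function(e) NULL)
  if (!is.null(fl2))
    for (i in seq_along(fl2$coefficients))
      add("occupancy_rate~wetness+utilization", names(fl2$coefficients)[i],
          fl2$coefficients[i], fl2$se[i], fl2$p_values[i],
          spearman = fl2$spearman_pred_obs)

  lin <- function(model, yv, xv = w) {
    f <- fit_linear_aic(yv, xv)
    add(model, "slope", f$coefficients[2],
        p = f$p_values[2], r_squared = f$r_squared, aic = f$aic)
  }
  lin("utilization~wetness", util)
  lin("fecal_density~wetness", my$fecal_density)
  lin("biomass~wetness", rowMeans(my[, grep("^biomass_", names(my)), drop = FALSE]))
  for (q in c("cp", "tp", "adf"))
    lin(paste0(q, "~wetness"),
        rowMeans(my[, grep(paste0("^", q, "_"), names(my)), drop = FALSE]))
  f <- fit_linear_aic(my$fecal_density, util)
  add("fecal_density~utilization", "slope", f$coefficients[2],
      p = f$p_values[2], r_squared = f$r_squared, aic = f$aic)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
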