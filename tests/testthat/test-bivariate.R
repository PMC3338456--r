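# independent quasi-likelihood oracle: direct numeric maximization
quasi_ll <- function(beta, y, Xm) {
  mu <- plogis(drop(Xm %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(ifelse(y == 0, 0, y * log(mu)) + ifelse(y == 1, 0, (1 - y) * log(1 - mu)))
}

test_that("fractional logit closed-form cases", {
  f <- fit_fractional_logit(rep(0.5, 8))
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  expect_equal(unname(f$fitted), rep(0.5, 8), tolerance = 1e-8)

  # saturated two-group model: slope = logit(p1) - logit(p0)
  g <- rep(0:1, each = 6)
  y <- c(rep(0.25, 6), rep(0.8, 6))
  f2 <- fit_fractional_logit(y, data.frame(g = g))
  expect_equal(unname(f2$coefficients[2]), qlogis(0.8) - qlogis(0.25),
               tolerance = 1e-7)
  expect_equal(unname(f2$coefficients[1]), qlogis(0.25), tolerance = 1e-7)
})

test_that("fractional logit matches a brute-force quasi-likelihood optimizer", {
  set.seed(14)
  for (r in 1:3) {
    x1 <- rnorm(20)
    x2 <- runif(20)
    y <- pmin(1, pmax(0, round(plogis(0.4 * x1 - 0.8 * x2 + rnorm(20, 0, 0.8)) * 3) / 3))
    f <- fit_fractional_logit(y, data.frame(x1 = x1, x2 = x2))
    Xm <- cbind(1, x1, x2)
    opt <- optim(c(0, 0, 0), function(b) -quasi_ll(b, y, Xm),
                 method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
    expect_lt(max(abs(unname(f$coefficients) - opt$par)), 1e-5)
  }
})

test_that("fractional logit with binary response equals ordinary logistic regression", {
  set.seed(3)
  x <- rnorm(40)
  y <- rbinom(40, 1, plogis(0.7 * x))
  f <- fit_fractional_logit(y, data.frame(x = x))
  g <- glm(y ~ x, family = binomial)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
})

test_that("perfect separation is reported, not silently returned", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(1, 2, 3, 10, 11, 12)
  f <- fit_fractional_logit(y, data.frame(x = x))
  expect_false(f$converged)
  expect_match(f$diagnostic, "separation")
})

test_that("deviance residuals have the fractional-response form", {
  sim <- default_sim()
  my <- sim$meadow_years[!duplicated(sim$meadow_years$meadow), ]
  f <- fit_fractional_logit(my$occupancy_rate,
                            data.frame(w = my$composite_rank))
  expect_length(f$deviance_residuals, nrow(my))
  expect_true(all(is.finite(f$deviance_residuals)))
  expect_true(all(f$fitted > 0 & f$fitted < 1))
  # residual sign tracks observed minus fitted
  expect_true(all(sign(f$deviance_residuals) ==
                    sign(my$occupancy_rate - f$fitted) |
                    my$occupancy_rate == f$fitted))
})

test_that("linear/quadratic AIC selection handles exact fits", {
  x <- seq(-3, 3, length.out = 12)
  # base R warns about the essentially perfect fit; that is the point here
  f <- suppressWarnings(fit_linear_aic(2 * x + 1, x))
  expect_equal(f$degree, 1L)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$coefficients, c(1, 2), tolerance = 1e-8)

  f2 <- fit_linear_aic(1 + x - 0.5 * x^2 + rnorm(12, 0, 1e-8), x)
  expect_equal(f2$degree, 2L)
  expect_lt(f2$aic_by_degree["degree2"], f2$aic_by_degree["degree1"])
})

test_that("AIC model choice is invariant to affine rescaling of x", {
  set.seed(8)
  x <- runif(30, 0, 10)
  y <- 3 + 0.6 * x + 0.2 * x^2 + rnorm(30)
  f1 <- fit_linear_aic(y, x)
  f2 <- fit_linear_aic(y, 5 * x - 7)
  expect_equal(f1$degree, f2$degree)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("Box-Cox lambda estimate matches a profile-likelihood grid oracle", {
  set.seed(12)
  x <- runif(60, 0, 3)
  y <- exp(x + rnorm(60, 0, 0.02))
  f <- fit_linear_aic(y, x, box_cox = TRUE)
  grid <- seq(-2, 2, by = 0.01)
  ll <- vapply(grid, function(l)
    meadowsem:::boxcox_profile_ll(y, x, l), numeric(1))
  lambda_grid <- grid[which.max(ll)]
  expect_lt(abs(f$box_cox_lambda - lambda_grid), 0.011)
  expect_lt(abs(f$box_cox_lambda), 0.1)   # log-scale data
})

test_that("Box-Cox with lambda = 1 shifts y by -1 and leaves the fit shape alone", {
  set.seed(2)
  x <- runif(25, 0, 4)
  y <- 5 + 2 * x + rnorm(25, 0, 0.3)
  lam1 <- meadowsem:::boxcox_profile_ll(y, x, 1)
  expect_true(is.finite(lam1))
  f_raw <- fit_linear_aic(y - 1, x, box_cox = FALSE)
  # transform at lambda = 1 is exactly y - 1
  yt <- (y^1 - 1) / 1
  f_t <- fit_linear_aic(yt, x, box_cox = FALSE)
  expect_equal(f_raw$coefficients, f_t$coefficients, tolerance = 1e-12)
  expect_equal(f_raw$r_squared, f_t$r_squared, tolerance = 1e-12)
})

test_that("Box-Cox requires positive responses", {
  expect_error(fit_linear_aic(c(-1, 2, 3, 4), 1:4, box_cox = TRUE),
               "positive")
})

test_that("spearman_rho handles monotone, reversed, tied and constant input", {
  expect_equal(spearman_rho(1:8, (1:8)^3), 1)
  expect_equal(spearman_rho(1:8, -(1:8)), -1)
  # hand-computed: ranks (1,2,3,4) vs (2,1,4,3): 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3)), 0.6)
  expect_warning(out <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("deviance residual normality summary behaves on reference inputs", {
  set.seed(99)
  r <- rnorm(60)
  s <- deviance_residual_normality(r)
  expect_false(s$degenerate)
  expect_gt(s$p_value, 0.05)   # seeded standard-normal sample
  expect_lt(abs(s$skewness), 0.6)

  s2 <- deviance_residual_normality(rep(0.3, 10))
  expect_true(s2$degenerate)
  expect_true(is.na(s2$p_value))

  f <- fit_fractional_logit(c(0, 1/3, 1/3, 2/3, 1, 1),
                            data.frame(x = c(0, 1, 2, 3, 4, 5)))
  s3 <- deviance_residual_normality(f)
  expect_true(is.finite(s3$skewness))
})

test_that("bivariate_table emits a tidy table with the expected models", {
  tab <- bivariate_table(default_sim()$meadow_years)
  expect_true(all(c("model", "term", "estimate", "p") %in% names(tab)))
  expect_true("occupancy_rate~wetness" %in% tab$model)
  expect_true(any(tab$term == "wetness_x_utilization"))
  expect_true("fecal_density~utilization" %in% tab$model)
  tab2 <- bivariate_table(default_sim()$meadow_years, interaction = FALSE)
  expect_false(any(tab2$term == "wetness_x_utilization"))
})
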