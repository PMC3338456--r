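test_that("standardize centers and scales with an exact inverse", {
  df <- data.frame(a = c(2, 4, 6), b = c(1, 1.5, 3.5))
  st <- standardize(df)
  expect_equal(st$data$a, c(-1, 0, 1))
  expect_equal(mean(st$data$b), 0, tolerance = 1e-12)
  expect_equal(sd(st$data$b), 1, tolerance = 1e-12)

  # idempotence on an already standardized column
  st2 <- standardize(st$data)
  expect_equal(st2$data$a, st$data$a, tolerance = 1e-12)

  # exact round trip
  back <- unstandardize(st$data, st$scaling)
  expect_equal(back$a, df$a, tolerance = 1e-10)
  expect_equal(back$b, df$b, tolerance = 1e-10)

  expect_error(standardize(data.frame(ok = 1:3, flat = rep(2, 3))), "flat")
})

test_that("prepare_sem_data builds an indexed standardized table per season", {
  sdat <- default_sem_data("mid")
  expect_s3_class(sdat, "sem_data")
  expect_equal(sdat$n, 48L)
  expect_equal(sdat$M, 24L)
  expect_equal(sdat$A, 3L)
  expect_equal(sdat$Tn, 2L)
  for (v in c("W", "cp", "tp", "adf", "P", "U")) {
    expect_equal(mean(sdat[[v]]), 0, tolerance = 1e-10)
    expect_equal(sd(sdat[[v]]), 1, tolerance = 1e-10)
  }
  expect_true(all(sdat$O %in% c(0L, 1L)))

  my <- default_sim()$meadow_years
  my$cp_mid[3] <- NA
  expect_message(dropped <- prepare_sem_data(my, "mid"), "dropped")
  expect_equal(dropped$n, 47L)
})

test_that("log_posterior on one row with zero coefficients equals the hand sum", {
  dat <- one_row_sem_data()
  p <- flat_params()
  # hand computation: three unit-normal measurement terms at mean 0,
  # independent standard bivariate for (Q=0, P), unit normal for U,
  # Bernoulli(1/2), standard-normal random intercepts at 0, plus priors
  hand_lik <- dnorm(dat$cp, 0, 1, log = TRUE) +
    dnorm(dat$tp, 0, 1, log = TRUE) + dnorm(dat$adf, 0, 1, log = TRUE) +
    dnorm(0, 0, 1, log = TRUE) + dnorm(dat$P, 0, 1, log = TRUE) +
    dnorm(dat$U, 0, 1, log = TRUE) + log(0.5)
  hand_re <- 4 * 3 * dnorm(0, 0, 1, log = TRUE)
  hand_prior <- 9 * dnorm(0, 0, 10, log = TRUE) +
    9 * (log(2) + dnorm(1, 0, 1, log = TRUE)) + log(0.5)
  out <- log_posterior(sem_spec("early"), p, dat, components = TRUE)
  expect_equal(out$log_lik, hand_lik, tolerance = 1e-12)
  expect_equal(out$log_re, hand_re, tolerance = 1e-12)
  expect_equal(out$log_prior, hand_prior, tolerance = 1e-12)
  expect_equal(out$total, hand_lik + hand_re + hand_prior, tolerance = 1e-12)
})

test_that("doubling the dataset doubles the likelihood component exactly", {
  sdat <- default_sem_data("mid")
  doubled <- meadowsem:::sem_data_subset(sdat, rep(seq_len(sdat$n), 2))
  p <- flat_params(n = sdat$n, M = sdat$M, A = sdat$A, Tn = sdat$Tn)
  p$Q <- rnorm(sdat$n)
  p2 <- p
  p2$Q <- rep(p$Q, 2)
  l1 <- log_posterior(sem_spec("mid"), p, sdat, components = TRUE)
  l2 <- log_posterior(sem_spec("mid"), p2, doubled, components = TRUE)
  expect_equal(l2$log_lik, 2 * l1$log_lik, tolerance = 1e-10)
  expect_equal(l2$log_re, l1$log_re, tolerance = 1e-12)
})

test_that("non-positive SDs are rejected before evaluation", {
  dat <- one_row_sem_data()
  p <- flat_params()
  p$sd_q <- 0
  expect_error(log_posterior(sem_spec("early"), p, dat),
               class = "meadowsem_param_error")
  p$sd_q <- 1
  p$rho_qp <- 1
  expect_error(log_posterior(sem_spec("early"), p, dat),
               class = "meadowsem_param_error")
})

test_that("the likelihood is invariant to a joint sign flip of the latent factor", {
  # flipping Q together with all loadings, the wetness->quality path, the
  # quality->utilization path and the disturbance correlation leaves the
  # likelihood unchanged; the fixed CP loading is what forbids the
  # sampler from exploring that mirrored solution
  sdat <- default_sem_data("mid")
  p <- flat_params(n = sdat$n, M = sdat$M, A = sdat$A, Tn = sdat$Tn)
  set.seed(4)
  p$Q <- rnorm(sdat$n)
  p$gamma_wq <- -0.6; p$lambda_tp <- 0.8; p$lambda_adf <- -0.7
  p$beta_qu <- 0.5; p$rho_qp <- 0.3
  p$re$q <- lapply(p$re$q, function(x) rnorm(length(x), 0, 0.2))
  flip <- p
  flip$Q <- -p$Q
  flip$lambda_cp <- -1
  flip$lambda_tp <- -p$lambda_tp
  flip$lambda_adf <- -p$lambda_adf
  flip$gamma_wq <- -p$gamma_wq
  flip$beta_qu <- -p$beta_qu
  flip$rho_qp <- -p$rho_qp
  flip$re$q <- lapply(p$re$q, function(x) -x)
  spec <- sem_spec("mid")
  l0 <- log_posterior(spec, p, sdat, components = TRUE)
  l1 <- log_posterior(spec, flip, sdat, components = TRUE)
  expect_equal(l1$log_lik, l0$log_lik, tolerance = 1e-10)
})

test_that("sampler is deterministic given the seed", {
  sdat <- default_sem_data("mid")
  spec <- sem_spec("mid")
  f1 <- sample_posterior(spec, sdat, n_chains = 2, n_iter = 300,
                         burn_in = 100, seed = 12)
  f2 <- sample_posterior(spec, sdat, n_chains = 2, n_iter = 300,
                         burn_in = 100, seed = 12)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$lp, f2$lp)
})

test_that("sampler's cached log posterior equals an independent evaluation", {
  fit <- default_fit()
  sdat <- default_sem_data("mid")
  spec <- sem_spec("mid")
  for (ch in 1:2) for (it in c(1, 57, fit$n_keep)) {
    p <- draw_params(fit, ch, it)
    expect_equal(log_posterior(spec, p, sdat), fit$lp[ch, it],
                 tolerance = 1e-8)
  }
})

test_that("pure Gaussian sub-model recovers the conjugate regression posterior", {
  # with random-effect and disturbance noise switched off in generation,
  # the productivity path has a closed-form conjugate posterior given the
  # true residual SD: precision = sum(W^2)/sd^2 + 1/100
  p <- true_params(sd_meadow = 0, sd_allotment = 0, sd_year = 0)
  tab <- direct_sem_table(77, M = 40, Tn = 2, p = p)
  sdat <- prepare_sem_data(tab, "mid")
  spec <- sem_spec("mid", include_occupancy = FALSE)
  fit <- sample_posterior(spec, sdat, n_chains = 2, n_iter = 1500,
                          burn_in = 600, seed = 5)
  sm <- posterior_summary(fit, "gamma_wp")
  W <- sdat$W
  P <- sdat$P
  # true residual SD on the standardized scale used in the fit
  sc_p <- sdat$scaling$scale[sdat$scaling$column == "P"]
  sd_std <- p$sd_p / sc_p
  prec <- sum(W^2) / sd_std^2 + 1 / 100
  conj_mean <- sum(W * P) / sd_std^2 / prec
  expect_lt(abs(sm$mean - conj_mean), 3 * sm$sd)
  # and the wetness->quality path is also close to its generative value
  smq <- posterior_summary(fit, "gamma_wq")
  expect_lt(abs(smq$mean - p$gamma_wq), 4 * smq$sd)
})

test_that("significance flags follow the credible-interval rules", {
  expect_equal(unname(significance_flags(list(a = rep(1, 500)))), "**")
  expect_equal(unname(significance_flags(list(a = c(-(1:100), 1:100)))), "NS")
  set.seed(6)
  draws <- rnorm(40000, 0.2, 0.1)   # analytic 95% CI (0.004, 0.396)
  expect_equal(unname(significance_flags(list(a = draws))), "**")
  draws90 <- rnorm(40000, 0.18, 0.1) # 90% CI excludes 0, 95% does not
  expect_equal(unname(significance_flags(list(a = draws90))), "*")
})

test_that("posterior_summary reports all scalar parameters once", {
  fit <- default_fit()
  sm <- posterior_summary(fit)
  expect_equal(sort(sm$parameter), sort(fit$scalars))
  expect_false(any(duplicated(sm$parameter)))
  expect_true(all(is.finite(sm$mean)))
  expect_true(all(sm$flag %in% c("**", "*", "NS")))
})
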