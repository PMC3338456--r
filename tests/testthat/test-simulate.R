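test_that("identical seeds give identical simulated tables", {
  d <- small_design()
  s1 <- simulate_study(d, true_params(), seed = 5)
  s2 <- simulate_study(d, true_params(), seed = 5)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$meadow_years, s2$meadow_years)
  s3 <- simulate_study(d, true_params(), seed = 6)
  expect_false(identical(s1$sites, s3$sites))
})

test_that("emitted records satisfy the type invariants across random designs", {
  set.seed(21)
  for (i in 1:4) {
    na <- sample(1:3, 1)
    d <- make_design(list(
      n_allotments = na,
      meadows_per_allotment = sample(2:6, na, replace = TRUE),
      sites_per_meadow = sample(2:6, 1),
      years = 2006:2008))
    sim <- simulate_study(d, true_params(), seed = 100 + i)
    s <- sim$sites
    expect_true(all(s$site_rank %in% 0:6))
    expect_true(all(s$utilization >= 0 & s$utilization <= 1))
    expect_true(all(s$cp > 0 & s$tp > 0 & s$adf > 0 & s$biomass > 0))
    expect_equal(nrow(s), d$n_sites * length(d$years) * 3)
    my <- sim$meadow_years
    expect_true(all(my$occupancy %in% c(0L, 1L)))
    # occupancy rate from three annual surveys lies on thirds
    expect_true(all(abs(my$occupancy_rate * 3 - round(my$occupancy_rate * 3)) < 1e-12))
    expect_true(all(my$composite_rank %in% 0:6))
    expect_equal(my$composite_rank,
                 as.integer(floor(my$mean_score + 0.5)))
  }
})

test_that("noise-free limit with a saturating wetness effect pins occupancy to the wet side", {
  p <- true_params(beta_wo = 50, alpha = 0, beta_uo = 0,
                   sd_q = 0, sd_p = 0, sd_u = 0, sd_cp = 0, sd_tp = 0,
                   sd_adf = 0, sd_meadow = 0, sd_allotment = 0,
                   sd_year = 0, sd_site = 0)
  sim <- simulate_study(make_design(), p, seed = 9)
  my <- sim$meadow_years
  w_meadow <- tapply(my$mean_score, my$meadow, unique)
  w <- (my$mean_score - mean(w_meadow)) / sd(w_meadow)
  clear <- abs(w) > 0.2
  expect_true(all(my$occupancy[clear] == as.integer(w[clear] > 0)))
})

test_that("sample corr(wetness, CP) matches the analytic generative covariance", {
  # oracle: under the linear-Gaussian generative equations with
  # standardized wetness W, cov(W, CP_z) = lambda_cp * gamma_wq and
  # var(CP_z) = lambda_cp^2 * var(Q) + sd_cp^2 + sd_site^2 with
  # var(Q) = gamma_wq^2 + sd_meadow^2 + sd_allotment^2 + sd_year^2 + sd_q^2
  p <- true_params()
  var_q <- p$gamma_wq^2 + p$sd_meadow^2 + p$sd_allotment^2 +
    p$sd_year^2 + p$sd_q^2
  rho_expected <- p$lambda_cp * p$gamma_wq /
    sqrt(p$lambda_cp^2 * var_q + p$sd_cp^2 + p$sd_site^2)

  d <- make_design(list(n_allotments = 2,
                        meadows_per_allotment = c(250, 250),
                        sites_per_meadow = 2, years = 2007))
  sim <- simulate_study(d, p, seed = 31)
  s <- sim$sites
  w_meadow <- tapply(sim$meadow_years$mean_score, sim$meadow_years$meadow, unique)
  w_z <- (w_meadow - mean(w_meadow)) / sd(w_meadow)
  rho_obs <- cor(w_z[s$meadow], s$cp)
  expect_lt(abs(rho_obs - rho_expected), 0.05)
  expect_lt(rho_obs, 0)
})

test_that("with beta_uo = 0 occupancy is conditionally independent of utilization given wetness", {
  # permutation test on utilization residuals (after removing the wetness
  # trend from both utilization and occupancy); with a true null path it
  # should fail to reject at alpha = 0.05 in >= 90% of replicates
  d <- make_design(list(n_allotments = 2, meadows_per_allotment = c(250, 250),
                        sites_per_meadow = 2, years = 2007))
  reject <- logical(10)
  for (r in 1:10) {
    sim <- simulate_study(d, true_params(), seed = 400 + r)
    my <- sim$meadow_years
    u <- rowMeans(my[, grep("^utilization_", names(my))])
    w <- my$mean_score
    e_u <- residuals(lm(u ~ w))
    e_o <- my$occupancy - fitted(glm(my$occupancy ~ w, family = binomial))
    t_obs <- abs(cor(e_u, e_o))
    set.seed(500 + r)
    t_perm <- replicate(199, abs(cor(sample(e_u), e_o)))
    reject[r] <- mean(c(t_perm, t_obs) >= t_obs) <= 0.05
  }
  expect_gte(sum(!reject), 9)
})

test_that("write_simulation emits CSVs and a truth file that round-trips", {
  dir <- withr::local_tempdir()
  sim <- default_sim()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  sites <- read.csv(paths["sites"])
  expect_equal(nrow(sites), nrow(sim$sites))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$gamma_wq, sim$params$gamma_wq)
  expect_equal(truth$seed, 42)
})
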