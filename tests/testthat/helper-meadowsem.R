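# Shared fixtures. Everything is generated in code; heavier objects are
# built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# small two-year study matching the occupancy-survey design
small_design <- function() make_design(list(years = c(2007, 2008)))

default_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_study(small_design(), true_params(), seed = 42)
  .fixtures$sim
}

default_sem_data <- function(season = "mid") {
  key <- paste0("sem_data_", season)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- prepare_sem_data(default_sim()$meadow_years, season)
  .fixtures[[key]]
}

# one moderate-length shared fit, reused by sem / diagnostics / validation
# tests (3 chains x 2500 iterations keeps the whole suite fast)
default_fit <- function() {
  if (is.null(.fixtures$fit))
    .fixtures$fit <- sample_posterior(sem_spec("mid"), default_sem_data(),
                                      n_chains = 3, n_iter = 2500,
                                      burn_in = 1000, seed = 7)
  .fixtures$fit
}

# hand-built single-row standardized dataset (bypasses standardization,
# which needs > 1 row); numbers chosen small and exact
one_row_sem_data <- function(cp = 0.3, tp = -0.2, adf = 0.1,
                             P = 0.5, U = -0.4, W = 1, O = 1L) {
  structure(list(
    n = 1L, W = W, cp = cp, tp = tp, adf = adf, P = P, U = U, O = O,
    mi = 1L, ai = 1L, ti = 1L, M = 1L, A = 1L, Tn = 1L,
    meadow_ids = 1, year_ids = 2007,
    scaling = data.frame(), season = "early", n_dropped = 0L
  ), class = "sem_data")
}

# zeroed parameter state: all coefficients 0, unit SDs, flat random effects
flat_params <- function(n = 1, M = 1, A = 1, Tn = 1, occupancy = TRUE) {
  eqs <- if (occupancy) c("q", "p", "u", "o") else c("q", "p", "u")
  re <- lapply(setNames(eqs, eqs), function(e)
    list(meadow = numeric(M), allotment = numeric(A), year = numeric(Tn)))
  list(gamma_wq = 0, gamma_wp = 0, beta_qu = 0, beta_pu = 0,
       lambda_cp = 1, lambda_tp = 0, lambda_adf = 0,
       alpha = 0, beta_wo = 0, beta_uo = 0,
       sd_cp = 1, sd_tp = 1, sd_adf = 1, sd_q = 1, sd_p = 1, sd_u = 1,
       sd_meadow = 1, sd_allotment = 1, sd_year = 1, rho_qp = 0,
       Q = numeric(n), re = re)
}

# meadow-year table drawn exactly from the SEM equations (no site-level
# aggregation), for sampler checks against a perfectly matching model
direct_sem_table <- function(seed, M = 24, Tn = 2, p = true_params(),
                             season = "mid") {
  set.seed(seed)
  mi <- rep(seq_len(M), each = Tn)
  ai <- rep(rep(1:3, length.out = M), each = Tn)
  ti <- rep(seq_len(Tn), M)
  n <- M * Tn
  W <- rnorm(M)[mi]
  W <- (W - mean(W)) / sd(W)
  zq <- rnorm(n)
  Q <- p$gamma_wq * W + p$sd_q * zq
  P <- p$gamma_wp * W +
    p$sd_p * (p$rho_qp * zq + sqrt(1 - p$rho_qp^2) * rnorm(n))
  U <- p$beta_qu * Q + p$beta_pu * P + p$sd_u * rnorm(n)
  out <- data.frame(
    meadow = mi, allotment = ai, year = 2006 + ti, composite_rank = W,
    occupancy = rbinom(n, 1, plogis(p$alpha + p$beta_wo * W + p$beta_uo * U)))
  out[[paste0("cp_", season)]] <- Q + p$sd_cp * rnorm(n)
  out[[paste0("tp_", season)]] <- p$lambda_tp * Q + p$sd_tp * rnorm(n)
  out[[paste0("adf_", season)]] <- p$lambda_adf * Q + p$sd_adf * rnorm(n)
  out[[paste0("biomass_", season)]] <- P
  out[[paste0("utilization_", season)]] <- U
  out
}
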