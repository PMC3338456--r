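# Hierarchical Bayesian SEM: joint density and Metropolis-within-Gibbs
# sampler. Gaussian blocks (latent quality, path-coefficient pairs, free
# loadings, random intercepts) use conjugate full conditionals; the
# occupancy block, the SDs (log scale) and the disturbance correlation
# use random-walk Metropolis. Three structural devices keep the chains
# out of known pathologies of this posterior (see the methods vignette):
# partially collapsed variance/coefficient updates with latent quality
# integrated out analytically, non-centred random intercepts, and a
# latent-scale jump move across the mirrored mode created by the fixed
# CP loading. Step sizes adapt during burn-in only.

# random-intercept sum for each row of the data
re_rows <- function(re_eq, data)
  re_eq$meadow[data$mi] + re_eq$allotment[data$ai] + re_eq$year[data$ti]

# centered bivariate normal log density summed over rows
bv_loglik <- function(rq, rp, sd_q, sd_p, rho) {
  zq <- rq / sd_q
  zp <- rp / sd_p
  om <- 1 - rho^2
  n <- length(rq)
  -n * (log(2 * pi) + log(sd_q) + log(sd_p) + 0.5 * log(om)) -
    sum(zq^2 - 2 * rho * zq * zp + zp^2) / (2 * om)
}

half_normal_lp <- function(sd) log(2) + dnorm(sd, 0, 1, log = TRUE)

#' Joint log posterior of the meadow SEM
#'
#' Evaluates log prior + log likelihood for a full parameter state
#' (structural coefficients, loadings, SDs, disturbance correlation, latent
#' quality values, and random intercepts). Priors: Normal(0, 10^2) on
#' coefficients and free loadings, half-Normal(0, 1) on SDs, Uniform(-1, 1)
#' on the disturbance correlation. The likelihood sums Gaussian measurement
#' densities for CP/TP/ADF given latent quality, a bivariate Gaussian for
#' the (quality, productivity) structural disturbances, a Gaussian for
#' utilization, a Bernoulli-logit for occupancy (when in the spec), and
#' Gaussian densities for all random intercepts.
#'
#' @param spec A [sem_spec()].
#' @param params Parameter state: named list with the scalar parameters of
#'   `sem_param_names(spec)` plus `Q` (latent vector) and `re` (per-equation
#'   lists of `meadow`/`allotment`/`year` intercepts). `lambda_cp` defaults
#'   to 1 when absent.
#' @param data A [prepare_sem_data()] object.
#' @param components If TRUE, return a list with `log_prior`, `log_lik`
#'   (observation terms only), `log_re` and `total`.
#' @return The log posterior (or component list).
#' @export
log_posterior <- function(spec, params, data, components = FALSE) {
  assert_that(inherits(data, "sem_data"), "data must come from prepare_sem_data()")
  p <- params
  if (is.null(p$lambda_cp)) p$lambda_cp <- 1
  sds <- c("sd_cp", "sd_tp", "sd_adf", "sd_q", "sd_p", "sd_u",
           "sd_meadow", "sd_allotment", "sd_year")
  for (s in sds)
    assert_that(is.numeric(p[[s]]) && p[[s]] > 0,
                paste0(s, " must be > 0"), class = "meadowsem_param_error")
  assert_that(abs(p$rho_qp) < 1, "rho_qp must lie in (-1, 1)",
              class = "meadowsem_param_error")
  assert_that(length(p$Q) == data$n, "Q must have one value per row",
              class = "meadowsem_structure_error")

  coefs <- c(p$gamma_wq, p$gamma_wp, p$beta_qu, p$beta_pu,
             p$lambda_tp, p$lambda_adf)
  if (spec$include_occupancy) coefs <- c(coefs, p$alpha, p$beta_wo, p$beta_uo)
  log_prior <- sum(dnorm(coefs, 0, 10, log = TRUE)) +
    sum(vapply(sds, function(s) half_normal_lp(p[[s]]), numeric(1))) +
    log(0.5)

  mu_q <- p$gamma_wq * data$W + re_rows(p$re$q, data)
  mu_p <- p$gamma_wp * data$W + re_rows(p$re$p, data)
  mu_u <- p$beta_qu * p$Q + p$beta_pu * data$P + re_rows(p$re$u, data)

  log_lik <-
    sum(dnorm(data$cp,  p$lambda_cp  * p$Q, p$sd_cp,  log = TRUE)) +
    sum(dnorm(data$tp,  p$lambda_tp  * p$Q, p$sd_tp,  log = TRUE)) +
    sum(dnorm(data$adf, p$lambda_adf * p$Q, p$sd_adf, log = TRUE)) +
    bv_loglik(p$Q - mu_q, data$P - mu_p, p$sd_q, p$sd_p, p$rho_qp) +
    sum(dnorm(data$U, mu_u, p$sd_u, log = TRUE))
  if (spec$include_occupancy) {
    eta <- p$alpha + p$beta_wo * data$W + p$beta_uo * data$U +
      re_rows(p$re$o, data)
    log_lik <- log_lik + bern_loglik(data$O, eta)
  }

  eqs <- names(p$re)
  log_re <- 0
  for (eq in eqs) {
    log_re <- log_re +
      sum(dnorm(p$re[[eq]]$meadow,    0, p$sd_meadow,    log = TRUE)) +
      sum(dnorm(p$re[[eq]]$allotment, 0, p$sd_allotment, log = TRUE)) +
      sum(dnorm(p$re[[eq]]$year,      0, p$sd_year,      log = TRUE))
  }

  total <- log_prior + log_lik + log_re
  if (components)
    list(log_prior = log_prior, log_lik = log_lik, log_re = log_re,
         total = total)
  else total
}

# draw from a bivariate normal with precision matrix A and linear term b
# (closed-form 2x2 inverse and Cholesky)
draw_mvn2 <- function(A, b) {
  det <- A[1, 1] * A[2, 2] - A[1, 2]^2
  s11 <- A[2, 2] / det; s22 <- A[1, 1] / det; s12 <- -A[1, 2] / det
  m1 <- s11 * b[1] + s12 * b[2]
  m2 <- s12 * b[1] + s22 * b[2]
  l11 <- sqrt(s11)
  l21 <- s12 / l11
  l22 <- sqrt(s22 - l21^2)
  zn <- rnorm(2)
  c(m1 + l11 * zn[1], m2 + l21 * zn[1] + l22 * zn[2])
}

new_re <- function(M, A, Tn, eqs) {
  one <- function() list(meadow = numeric(M), allotment = numeric(A),
                         year = numeric(Tn))
  setNames(lapply(eqs, function(e) one()), eqs)
}

#' Sample the SEM posterior by Metropolis-within-Gibbs MCMC
#'
#' Runs `n_chains` independent chains from overdispersed starting values
#' (method-of-moments centres jittered and inflated by `1 + chain/2`).
#' Latent quality values, path-coefficient pairs, free loadings and
#' (non-centred) random intercepts are drawn from conjugate Gaussian full
#' conditionals; occupancy coefficients and intercepts, SDs (log scale)
#' and the disturbance correlation use random-walk Metropolis. Variance
#' parameters and Q-coupled coefficients are additionally refreshed
#' against the marginal posterior with latent quality integrated out, and
#' a latent-scale Metropolis jump lets chains cross the mirrored mode
#' created by the fixed CP loading (see the methods vignette). Proposal
#' step sizes are tuned during burn-in (every `adapt_interval`
#' iterations) and frozen afterwards, preserving detailed balance for the
#' retained draws. Identical seeds give identical draws.
#'
#' @param spec A [sem_spec()].
#' @param data A [prepare_sem_data()] object.
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Iterations per chain (including burn-in).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param seed Integer seed.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param adapt_interval Burn-in adaptation cadence.
#' @return Object of class `posterior_samples`: `draws` maps each scalar
#'   parameter to a chains x iterations matrix (latent vectors to
#'   chains x iterations x dim arrays), plus log-posterior values (`lp`),
#'   acceptance rates, iteration metadata and the seed.
#' @export
sample_posterior <- function(spec, data, n_chains = 3, n_iter = 6000,
                             burn_in = 2000, seed = 1, thin = 1,
                             adapt_interval = 50) {
  assert_that(inherits(spec, "sem_spec"), "spec must come from sem_spec()")
  assert_that(inherits(data, "sem_data"), "data must come from prepare_sem_data()")
  assert_that(is_count(n_chains) && n_chains >= 1, "n_chains must be >= 1")
  assert_that(is_count(n_iter) && is_count(burn_in + 1) && burn_in < n_iter,
              "need 0 <= burn_in < n_iter")
  occ <- spec$include_occupancy
  eqs <- if (occ) c("q", "p", "u", "o") else c("q", "p", "u")
  scalars <- sem_param_names(spec)
  keep_idx <- seq(burn_in + 1L, n_iter, by = thin)
  n_keep <- length(keep_idx)

  chains <- lapply(seq_len(n_chains), function(ch)
    run_sem_chain(spec, data, ch, n_iter, keep_idx,
                  as.integer(seed), adapt_interval, burn_in, eqs))

  draws <- list()
  for (pn in scalars)
    draws[[pn]] <- do.call(rbind, lapply(chains, function(x) x$scal[, pn]))
  draws$Q <- aperm(simplify2array(lapply(chains, function(x) x$Q)), c(3, 1, 2))
  for (eq in eqs) for (lv in c("meadow", "allotment", "year")) {
    nm <- paste0("re_", eq, "_", lv)
    draws[[nm]] <- aperm(simplify2array(
      lapply(chains, function(x) x$re_store[[eq]][[lv]])), c(3, 1, 2))
  }
  lp <- do.call(rbind, lapply(chains, function(x) x$lp))

  structure(list(
    draws = draws, lp = lp,
    scalars = scalars, structural = sem_structural_names(spec),
    n_chains = n_chains, n_iter = n_iter, burn_in = burn_in, thin = thin,
    n_keep = n_keep, seed = as.integer(seed), spec = spec,
    accept_rates = lapply(chains, function(x) x$accept),
    data_n = data$n
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("SEM posterior: %d chains x %d kept draws (%d iterations, %d burn-in, thin %d)\n",
              x$n_chains, x$n_keep, x$n_iter, x$burn_in, x$thin))
  cat("Scalar parameters:", paste(x$scalars, collapse = ", "), "\n")
  invisible(x)
}

# one MCMC chain; returns kept draws and acceptance bookkeeping
run_sem_chain <- function(spec, data, chain, n_iter, keep_idx, seed,
                          adapt_interval, burn_in, eqs) {
  set.seed(seed + 1000L * chain)
  occ <- spec$include_occupancy
  n <- data$n; M <- data$M; A <- data$A; Tn <- data$Tn
  W <- data$W; P <- data$P; U <- data$U; O <- data$O
  cp <- data$cp; tp <- data$tp; adf <- data$adf
  mi <- data$mi; ai <- data$ai; ti <- data$ti
  nM <- gcount(mi, M); nA <- gcount(ai, A); nT <- gcount(ti, Tn)
  ssq_cp <- sum(cp^2); ssq_tp <- sum(tp^2); ssq_adf <- sum(adf^2)
  # 0/1 indicator matrices: group sums as a single matrix product
  ind_mat <- function(idx, K) {
    Im <- matrix(0, K, length(idx))
    Im[cbind(idx, seq_along(idx))] <- 1
    Im
  }
  Im_m <- ind_mat(mi, M); Im_a <- ind_mat(ai, A); Im_t <- ind_mat(ti, Tn)
  gs <- function(Im, x) as.numeric(Im %*% x)
  over <- 1 + chain / 2   # overdispersion factor

  # ---- initial state --------------------------------------------------
  # crude method-of-moments centres (CP carries the unit loading, so CP is
  # a direct proxy for Q), jittered with chain-dependent overdispersion
  mom <- list(
    gamma_wq = sum(W * cp) / sum(W^2),
    gamma_wp = sum(W * P) / sum(W^2),
    lambda_tp = sum(cp * tp) / sum(cp^2),
    lambda_adf = sum(cp * adf) / sum(cp^2))
  uu <- lm.fit(cbind(cp, P), U)$coefficients
  mom$beta_qu <- uu[1]; mom$beta_pu <- uu[2]
  jit <- function(m) m * exp(rnorm(1, 0, 0.25) * over) +
    rnorm(1, 0, 0.2) * over
  st <- list(
    gamma_wq = jit(mom$gamma_wq), gamma_wp = jit(mom$gamma_wp),
    beta_qu = jit(mom$beta_qu), beta_pu = jit(mom$beta_pu),
    lambda_tp = jit(mom$lambda_tp), lambda_adf = jit(mom$lambda_adf),
    sd_cp = exp(rnorm(1, -0.5, 0.3) * over), sd_tp = exp(rnorm(1, -0.5, 0.3) * over),
    sd_adf = exp(rnorm(1, -0.5, 0.3) * over), sd_q = exp(rnorm(1, -0.3, 0.3) * over),
    sd_p = exp(rnorm(1, -0.3, 0.3) * over), sd_u = exp(rnorm(1, -0.5, 0.3) * over),
    sd_meadow = exp(rnorm(1, -0.7, 0.3) * over),
    sd_allotment = exp(rnorm(1, -0.7, 0.3) * over),
    sd_year = exp(rnorm(1, -0.7, 0.3) * over),
    rho_qp = runif(1, -0.5, 0.5),
    lambda_cp = 1
  )
  if (occ) {
    st$alpha <- rnorm(1, 0, 0.5) * over
    st$beta_wo <- rnorm(1, 0, 0.5) * over
    st$beta_uo <- rnorm(1, 0, 0.5) * over
  }
  Q <- cp + 0.1 * rnorm(n)          # CP carries the fixed unit loading
  # non-centered random intercepts: actual intercept = sd_level * z
  z <- new_re(M, A, Tn, eqs)
  for (eq in eqs) for (lv in c("meadow", "allotment", "year"))
    z[[eq]][[lv]] <- rnorm(length(z[[eq]][[lv]]), 0, 0.5)

  # ---- MH proposal steps and acceptance bookkeeping -------------------
  sd_names <- c("sd_cp", "sd_tp", "sd_adf", "sd_q", "sd_p", "sd_u",
                "sd_meadow", "sd_allotment", "sd_year")
  steps <- c(setNames(rep(0.4, length(sd_names)), sd_names),
             rho_qp = 0.3,
             m_gamma_wq = 0.3, m_beta_qu = 0.3, m_lambda_tp = 0.3,
             m_lambda_adf = 0.3,
             if (occ) c(occ_coef = 0.5, occ_meadow = 0.6, occ_allot = 0.6,
                        occ_year = 0.6))
  acc <- n_try <- setNames(numeric(length(steps) + 1L),
                           c(names(steps), "scale_move"))
  bump <- function(name, accepted, w = 1) {
    acc[name] <<- acc[name] + sum(accepted)
    n_try[name] <<- n_try[name] + w
  }

  scalars <- sem_param_names(spec)
  n_keep <- length(keep_idx)
  scal <- matrix(NA_real_, n_keep, length(scalars),
                 dimnames = list(NULL, scalars))
  Qs <- matrix(NA_real_, n_keep, n)
  re_store <- lapply(setNames(eqs, eqs), function(eq)
    list(meadow = matrix(NA_real_, n_keep, M),
         allotment = matrix(NA_real_, n_keep, A),
         year = matrix(NA_real_, n_keep, Tn)))
  lp <- numeric(n_keep)
  pos_lookup <- integer(n_iter)
  pos_lookup[keep_idx] <- seq_along(keep_idx)

  prior_prec_coef <- 1 / 100        # Normal(0, 10^2) prior

  # marginal (Q integrated out) log likelihood of the Gaussian sub-model,
  # given random effects on the data scale; v holds the scalar parameters
  marg_names <- c("gamma_wq", "gamma_wp", "beta_qu", "beta_pu",
                  "lambda_tp", "lambda_adf", "sd_cp", "sd_tp", "sd_adf",
                  "sd_q", "sd_p", "sd_u", "rho_qp")

  for (it in seq_len(n_iter)) {
    # ---- Q-collapsed block: random-walk Metropolis on the marginal
    # posterior with latent quality integrated out analytically. The
    # Q-conditional density has a degenerate spike at sd_q -> 0 and a
    # mirrored small-amplitude mode in the loadings; collapsed updates
    # of the SDs, the correlation and the Q-coupled coefficients let
    # chains cross both. Q is redrawn from its full conditional
    # immediately afterwards, before any block that conditions on it.
    zr <- lapply(z, function(e)
      list(meadow = e$meadow[mi], allotment = e$allotment[ai],
           year = e$year[ti]))
    re_row <- function(eq, sdm, sda, sdt)
      sdm * zr[[eq]]$meadow + sda * zr[[eq]]$allotment + sdt * zr[[eq]]$year
    reQ <- re_row("q", st$sd_meadow, st$sd_allotment, st$sd_year)
    reP <- re_row("p", st$sd_meadow, st$sd_allotment, st$sd_year)
    reU <- re_row("u", st$sd_meadow, st$sd_allotment, st$sd_year)

    # sufficient statistics: every marginal evaluation below is O(1)
    Pc <- P - st$gamma_wp * W - reP
    u_off <- U - st$beta_pu * P - reU
    G <- crossprod(cbind(cp, tp, adf, W, reQ, Pc, u_off))
    ssq_uoff <- G[7, 7]
    A1 <- G[4, 4]; A2 <- G[4, 5]; A3 <- G[5, 5]
    B1 <- G[6, 6]; B2 <- G[4, 6]; B3 <- G[5, 6]

    # cscale rescales the quality equation's random effects (used only by
    # the latent-scale jump below, which maps reQ -> cscale * reQ)
    marg_ll <- function(v, cscale = 1) {
      om <- 1 - v$rho_qp^2
      s11 <- 1 / (v$sd_q^2 * om)
      s12 <- -v$rho_qp / (v$sd_q * v$sd_p * om)
      a <- st$lambda_cp^2 / v$sd_cp^2 + v$lambda_tp^2 / v$sd_tp^2 +
        v$lambda_adf^2 / v$sd_adf^2 + s11 + v$beta_qu^2 / v$sd_u^2
      w <- c(st$lambda_cp / v$sd_cp^2, v$lambda_tp / v$sd_tp^2,
             v$lambda_adf / v$sd_adf^2, s11 * v$gamma_wq, s11 * cscale,
             -s12, v$beta_qu / v$sd_u^2)
      sumb2 <- sum(w * (G %*% w))
      Sqq <- v$gamma_wq^2 * A1 + 2 * v$gamma_wq * cscale * A2 + cscale^2 * A3
      Sqp <- v$gamma_wq * B2 + cscale * B3
      bv0 <- -n * (log(2 * pi) + log(v$sd_q) + log(v$sd_p) +
                     0.5 * log(om)) -
        (Sqq / v$sd_q^2 + 2 * v$rho_qp * Sqp / (v$sd_q * v$sd_p) +
           B1 / v$sd_p^2) / (2 * om)
      c0 <- -2 * n * log(2 * pi) -
        n * (log(v$sd_cp) + log(v$sd_tp) + log(v$sd_adf) + log(v$sd_u)) -
        ssq_cp / (2 * v$sd_cp^2) - ssq_tp / (2 * v$sd_tp^2) -
        ssq_adf / (2 * v$sd_adf^2) - ssq_uoff / (2 * v$sd_u^2) + bv0
      c0 + sumb2 / (2 * a) + n * 0.5 * log(2 * pi / a)
    }
    v <- st[marg_names]
    ll_cur <- marg_ll(v)
    for (nm in c("sd_cp", "sd_tp", "sd_adf", "sd_q", "sd_p", "sd_u")) {
      prop <- v[[nm]] * exp(steps[[nm]] * rnorm(1))
      v2 <- v; v2[[nm]] <- prop
      ll_prop <- marg_ll(v2)
      dlp <- ll_prop - ll_cur +
        half_normal_lp(prop) - half_normal_lp(v[[nm]]) +
        log(prop) - log(v[[nm]])
      ok <- is.finite(dlp) && log(runif(1)) < dlp
      if (ok) { v <- v2; ll_cur <- ll_prop }
      bump(nm, ok)
    }
    for (nm in c("gamma_wq", "beta_qu", "lambda_tp", "lambda_adf")) {
      snm <- paste0("m_", nm)
      prop <- v[[nm]] + steps[[snm]] * rnorm(1)
      v2 <- v; v2[[nm]] <- prop
      ll_prop <- marg_ll(v2)
      dlp <- ll_prop - ll_cur +
        dnorm(prop, 0, 10, log = TRUE) - dnorm(v[[nm]], 0, 10, log = TRUE)
      ok <- is.finite(dlp) && log(runif(1)) < dlp
      if (ok) { v <- v2; ll_cur <- ll_prop }
      bump(snm, ok)
    }
    prop <- v$rho_qp + steps[["rho_qp"]] * rnorm(1)  # Uniform(-1,1) prior
    if (abs(prop) < 1) {
      v2 <- v; v2$rho_qp <- prop
      ll_prop <- marg_ll(v2)
      dlp <- ll_prop - ll_cur
      ok <- is.finite(dlp) && log(runif(1)) < dlp
      if (ok) { v <- v2; ll_cur <- ll_prop }
      bump("rho_qp", ok)
    } else bump("rho_qp", FALSE)

    # ---- latent-scale jump: Q -> c*Q with loadings and slopes on Q
    # rescaled by 1/c. The fixed CP loading makes the posterior
    # asymmetric between the unit-loading mode and its mirrored,
    # shrunken image; this deterministic-map Metropolis move lets chains
    # hop between the two basins (Jacobian |c|^(n_z - 1) for the scaled
    # z intercepts and scalar parameters).
    cc <- sample(c(-1, 1), 1) * exp(rnorm(1, 0, 1))
    v2 <- v
    v2$gamma_wq <- cc * v$gamma_wq
    v2$lambda_tp <- v$lambda_tp / cc
    v2$lambda_adf <- v$lambda_adf / cc
    v2$beta_qu <- v$beta_qu / cc
    v2$sd_q <- abs(cc) * v$sd_q
    v2$rho_qp <- sign(cc) * v$rho_qp
    zq2 <- lapply(z$q, function(x) cc * x)
    ll_prop <- marg_ll(v2, cscale = cc)
    dlp <- ll_prop - ll_cur +
      sum(dnorm(c(v2$gamma_wq, v2$lambda_tp, v2$lambda_adf, v2$beta_qu),
                0, 10, log = TRUE)) -
      sum(dnorm(c(v$gamma_wq, v$lambda_tp, v$lambda_adf, v$beta_qu),
                0, 10, log = TRUE)) +
      half_normal_lp(v2$sd_q) - half_normal_lp(v$sd_q) +
      sum(dnorm(unlist(zq2), log = TRUE)) -
      sum(dnorm(unlist(z$q), log = TRUE)) +
      (M + A + Tn - 1) * log(abs(cc))
    ok <- is.finite(dlp) && log(runif(1)) < dlp
    if (ok) {
      v <- v2; ll_cur <- ll_prop
      z$q <- zq2
      zr$q <- lapply(zr$q, function(x) cc * x)
      reQ <- cc * reQ
    }
    bump("scale_move", ok)

    st[marg_names] <- v

    om <- 1 - st$rho_qp^2
    s11 <- 1 / (st$sd_q^2 * om)
    s22 <- 1 / (st$sd_p^2 * om)
    s12 <- -st$rho_qp / (st$sd_q * st$sd_p * om)
    mu_q0 <- st$gamma_wq * W + reQ
    mu_p0 <- st$gamma_wp * W + reP
    u_off <- U - st$beta_pu * P - reU

    # ---- latent quality Q (conjugate, vectorized over rows) ----------
    prec_q <- st$lambda_cp^2 / st$sd_cp^2 + st$lambda_tp^2 / st$sd_tp^2 +
      st$lambda_adf^2 / st$sd_adf^2 + s11 + st$beta_qu^2 / st$sd_u^2
    bq <- st$lambda_cp * cp / st$sd_cp^2 + st$lambda_tp * tp / st$sd_tp^2 +
      st$lambda_adf * adf / st$sd_adf^2 +
      s11 * mu_q0 - s12 * (P - mu_p0) + st$beta_qu * u_off / st$sd_u^2
    Q <- bq / prec_q + rnorm(n) / sqrt(prec_q)

    # ---- (gamma_wq, gamma_wp): joint conjugate (shared covariate W) --
    vq <- Q - reQ
    vp <- P - reP
    S <- matrix(c(s11, s12, s12, s22), 2)
    Amat <- sum(W^2) * S + diag(prior_prec_coef, 2)
    bvec <- S %*% c(sum(W * vq), sum(W * vp))
    g <- draw_mvn2(Amat, bvec)
    st$gamma_wq <- g[1]; st$gamma_wp <- g[2]

    # ---- (beta_qu, beta_pu): conjugate -------------------------------
    X2 <- cbind(Q, P)
    Amat <- crossprod(X2) / st$sd_u^2 + diag(prior_prec_coef, 2)
    bvec <- crossprod(X2, U - reU) / st$sd_u^2
    bpair <- draw_mvn2(Amat, bvec)
    st$beta_qu <- bpair[1]; st$beta_pu <- bpair[2]

    # ---- free loadings: conjugate ------------------------------------
    sq <- sum(Q^2)
    pr <- sq / st$sd_tp^2 + prior_prec_coef
    st$lambda_tp <- sum(Q * tp) / st$sd_tp^2 / pr + rnorm(1) / sqrt(pr)
    pr <- sq / st$sd_adf^2 + prior_prec_coef
    st$lambda_adf <- sum(Q * adf) / st$sd_adf^2 / pr + rnorm(1) / sqrt(pr)

    # ---- Gaussian random intercepts (non-centered, conjugate) --------
    # quality / productivity equations share the bivariate disturbance;
    # row caches reQ/reP/reU and zr are updated incrementally
    lvl <- list(meadow = list(mi, M, nM, st$sd_meadow, Im_m),
                allotment = list(ai, A, nA, st$sd_allotment, Im_a),
                year = list(ti, Tn, nT, st$sd_year, Im_t))
    Qres0 <- Q - st$gamma_wq * W
    Pres0 <- P - st$gamma_wp * W
    for (lv in names(lvl)) {
      idx <- lvl[[lv]][[1]]; K <- lvl[[lv]][[2]]
      nK <- lvl[[lv]][[3]]; s_lv <- lvl[[lv]][[4]]; Im <- lvl[[lv]][[5]]
      # quality equation: residual excluding this level's intercepts
      reQ_o <- reQ - s_lv * zr$q[[lv]]
      q0 <- Qres0 - reQ_o
      rp <- Pres0 - reP
      lin <- s_lv * gs(Im, s11 * q0 + s12 * rp)
      prk <- nK * s_lv^2 * s11 + 1
      z$q[[lv]] <- lin / prk + rnorm(K) / sqrt(prk)
      zr$q[[lv]] <- z$q[[lv]][idx]
      reQ <- reQ_o + s_lv * zr$q[[lv]]
      # productivity equation
      reP_o <- reP - s_lv * zr$p[[lv]]
      p0 <- Pres0 - reP_o
      rq <- Qres0 - reQ
      lin <- s_lv * gs(Im, s22 * p0 + s12 * rq)
      prk <- nK * s_lv^2 * s22 + 1
      z$p[[lv]] <- lin / prk + rnorm(K) / sqrt(prk)
      zr$p[[lv]] <- z$p[[lv]][idx]
      reP <- reP_o + s_lv * zr$p[[lv]]
      # utilization equation
      reU_o <- reU - s_lv * zr$u[[lv]]
      u0 <- U - st$beta_qu * Q - st$beta_pu * P - reU_o
      lin <- s_lv * gs(Im, u0) / st$sd_u^2
      prk <- nK * s_lv^2 / st$sd_u^2 + 1
      z$u[[lv]] <- lin / prk + rnorm(K) / sqrt(prk)
      zr$u[[lv]] <- z$u[[lv]][idx]
      reU <- reU_o + s_lv * zr$u[[lv]]
    }

    # ---- occupancy block (random-walk Metropolis) --------------------
    if (occ) {
      th <- c(st$alpha, st$beta_wo, st$beta_uo)
      eta <- th[1] + th[2] * W + th[3] * U +
        re_row("o", st$sd_meadow, st$sd_allotment, st$sd_year)
      th2 <- th + steps[["occ_coef"]] * rnorm(3)
      eta2 <- eta + (th2[1] - th[1]) + (th2[2] - th[2]) * W +
        (th2[3] - th[3]) * U
      dlp <- bern_loglik(O, eta2) - bern_loglik(O, eta) +
        sum(dnorm(th2, 0, 10, log = TRUE) - dnorm(th, 0, 10, log = TRUE))
      ok <- is.finite(dlp) && log(runif(1)) < dlp
      if (ok) { th <- th2; eta <- eta2 }
      bump("occ_coef", ok)
      st$alpha <- th[1]; st$beta_wo <- th[2]; st$beta_uo <- th[3]

      occ_lvls <- list(occ_meadow = list("meadow", mi, M, st$sd_meadow, Im_m),
                       occ_allot = list("allotment", ai, A, st$sd_allotment, Im_a),
                       occ_year = list("year", ti, Tn, st$sd_year, Im_t))
      for (snm in names(occ_lvls)) {
        lv <- occ_lvls[[snm]][[1]]; idx <- occ_lvls[[snm]][[2]]
        K <- occ_lvls[[snm]][[3]]; s_lv <- occ_lvls[[snm]][[4]]
        Im <- occ_lvls[[snm]][[5]]
        cur <- z$o[[lv]]
        prop <- cur + steps[[snm]] * rnorm(K)
        eta2 <- eta + s_lv * (prop - cur)[idx]
        dll <- gs(Im, O * eta2 - log1pexp(eta2) - (O * eta - log1pexp(eta)))
        dpr <- dnorm(prop, log = TRUE) - dnorm(cur, log = TRUE)
        okv <- log(runif(K)) < dll + dpr
        cur[okv] <- prop[okv]
        eta <- eta + s_lv * (cur - z$o[[lv]])[idx]
        z$o[[lv]] <- cur
        zr$o[[lv]] <- cur[idx]
        bump(snm, okv, w = K)
      }
    }

    # ---- hierarchical SDs: MH with intercepts on the unit (z) scale --
    Ures0 <- U - st$beta_qu * Q - st$beta_pu * P
    if (occ) eta0 <- st$alpha + st$beta_wo * W + st$beta_uo * U
    hier_ll <- function(sdm, sda, sdt) {
      ll <- bv_loglik(Qres0 - re_row("q", sdm, sda, sdt),
                      Pres0 - re_row("p", sdm, sda, sdt),
                      st$sd_q, st$sd_p, st$rho_qp)
      ru <- Ures0 - re_row("u", sdm, sda, sdt)
      ll <- ll - n * log(st$sd_u) - sum(ru^2) / (2 * st$sd_u^2) -
        n * 0.5 * log(2 * pi)
      if (occ)
        ll <- ll + bern_loglik(O, eta0 + re_row("o", sdm, sda, sdt))
      ll
    }
    hier <- c(sd_meadow = st$sd_meadow, sd_allotment = st$sd_allotment,
              sd_year = st$sd_year)
    for (j in seq_along(hier)) {
      nm <- names(hier)[j]
      cur <- hier[[j]]
      prop <- cur * exp(steps[[nm]] * rnorm(1))
      h2 <- hier; h2[[j]] <- prop
      dlp <- hier_ll(h2[[1]], h2[[2]], h2[[3]]) -
        hier_ll(hier[[1]], hier[[2]], hier[[3]]) +
        half_normal_lp(prop) - half_normal_lp(cur) + log(prop) - log(cur)
      ok <- is.finite(dlp) && log(runif(1)) < dlp
      if (ok) { hier[[j]] <- prop; st[[nm]] <- prop }
      bump(nm, ok)
    }

    # ---- burn-in step adaptation -------------------------------------
    if (it <= burn_in && it %% adapt_interval == 0L) {
      nms <- names(steps)
      rate <- ifelse(n_try[nms] > 0, acc[nms] / n_try[nms], NA)
      target <- ifelse(nms == "occ_coef", 0.25, 0.44)
      adj <- exp(ifelse(is.na(rate), 0, rate - target))
      steps <- pmin(pmax(steps * adj, 1e-3), 10)
      acc[] <- 0; n_try[] <- 0
    }

    # ---- record ------------------------------------------------------
    pos <- pos_lookup[it]
    if (pos > 0L) {
      k <- pos
      scal[k, ] <- unlist(st[scalars], use.names = FALSE)
      Qs[k, ] <- Q
      sds_lv <- c(meadow = st$sd_meadow, allotment = st$sd_allotment,
                  year = st$sd_year)
      re_now <- lapply(setNames(eqs, eqs), function(eq)
        list(meadow = st$sd_meadow * z[[eq]]$meadow,
             allotment = st$sd_allotment * z[[eq]]$allotment,
             year = st$sd_year * z[[eq]]$year))
      for (eq in eqs) for (lv in c("meadow", "allotment", "year"))
        re_store[[eq]][[lv]][k, ] <- re_now[[eq]][[lv]]
      prm <- c(st, list(Q = Q, re = re_now))
      lp[k] <- log_posterior(spec, prm, data)
    }
  }

  list(scal = scal, Q = Qs, re_store = re_store, lp = lp,
       accept = ifelse(n_try > 0, acc / n_try, NA), steps = steps)
}

#' Extract one posterior draw as a full parameter state
#'
#' Rebuilds the parameter list (scalars, latent quality vector, random
#' intercepts) for a given chain and kept iteration, in the format
#' [log_posterior()] evaluates.
#'
#' @param samples A `posterior_samples` object.
#' @param chain Chain index.
#' @param iter Kept-iteration index.
#' @return Named parameter list.
#' @export
draw_params <- function(samples, chain, iter) {
  d <- samples$draws
  st <- lapply(setNames(samples$scalars, samples$scalars),
               function(p) d[[p]][chain, iter])
  st$lambda_cp <- 1
  eqs <- if (samples$spec$include_occupancy) c("q", "p", "u", "o")
         else c("q", "p", "u")
  st$Q <- d$Q[chain, iter, ]
  st$re <- lapply(setNames(eqs, eqs), function(eq)
    list(meadow = d[[paste0("re_", eq, "_meadow")]][chain, iter, ],
         allotment = d[[paste0("re_", eq, "_allotment")]][chain, iter, ],
         year = d[[paste0("re_", eq, "_year")]][chain, iter, ]))
  st
}

#' Posterior-mean parameter state
#'
#' Averages every parameter over all chains and kept draws; SDs are
#' averaged on the log scale (and back-transformed) to avoid boundary
#' artifacts in DIC's plug-in deviance.
#'
#' @param samples A `posterior_samples` object.
#' @return Named parameter list in [log_posterior()] format.
#' @export
posterior_mean_params <- function(samples) {
  d <- samples$draws
  st <- lapply(setNames(samples$scalars, samples$scalars), function(p) {
    x <- as.numeric(d[[p]])
    if (startsWith(p, "sd_")) exp(mean(log(x))) else mean(x)
  })
  st$lambda_cp <- 1
  eqs <- if (samples$spec$include_occupancy) c("q", "p", "u", "o")
         else c("q", "p", "u")
  st$Q <- apply(d$Q, 3, mean)
  st$re <- lapply(setNames(eqs, eqs), function(eq)
    list(meadow = apply(d[[paste0("re_", eq, "_meadow")]], 3, mean),
         allotment = apply(d[[paste0("re_", eq, "_allotment")]], 3, mean),
         year = apply(d[[paste0("re_", eq, "_year")]], 3, mean)))
  st
}

#' Conditional deviance function for a fitted SEM
#'
#' Returns `D(params) = -2 * log_lik(params)` over the observation terms
#' (measurement, structural, utilization, occupancy), conditional on latent
#' quality and random intercepts -- the BUGS-style conditional deviance
#' used for DIC.
#'
#' @param spec A [sem_spec()].
#' @param data A [prepare_sem_data()] object.
#' @return A function mapping a parameter state to its deviance.
#' @export
sem_deviance_fn <- function(spec, data) {
  function(params)
    -2 * log_posterior(spec, params, data, components = TRUE)$log_lik
}
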