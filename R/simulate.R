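#' Simulate a meadow grazing/occupancy study
#'
#' Generates site-level and meadow-year-level tables from the causal
#' structure the package's SEM targets. On a standardized scale, per
#' meadow-season-year: latent forage quality `Q = gamma_wq * W + re + zeta_Q`
#' and productivity `P = gamma_wp * W + re + zeta_P` with
#' `corr(zeta_Q, zeta_P) = rho_qp`; indicators `CP = Q + e`,
#' `TP = lambda_tp * Q + e`, `ADF = lambda_adf * Q + e`; utilization
#' `U = beta_qu * Q + beta_pu * P + re + eps`. Breeding occupancy is drawn
#' once per meadow-year as
#' `Bernoulli(plogis(alpha + beta_wo * W + beta_uo * Ubar + re))`, where
#' `Ubar` is the seasonal mean utilization. `re` denotes meadow-in-allotment
#' and year random intercepts (independent per equation, SDs shared across
#' equations). `W` is the meadow mean site wetness rank, standardized
#' across meadows; site ranks are a latent normal per site centred on a
#' meadow-level mean, rounded and clamped to 0..6. Standardized values are
#' mapped affinely to field units (see [true_params()]).
#'
#' @param design A [make_design()] object.
#' @param params A [true_params()] object.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `meadow_sim`: list with `sites` (one row per
#'   site-season-year), `meadow_years` (one row per meadow-year, with
#'   composite ranks, occupancy, occupancy rate, fecal density and
#'   season-level means), `params` (echo of the generating truth) and
#'   `design`.
#' @examples
#' sim <- simulate_study(make_design(), true_params(), seed = 1)
#' nrow(sim$sites)  # 120 sites x 3 years x 3 seasons
#' @export
simulate_study <- function(design, params = true_params(), seed = 1) {
  assert_that(inherits(design, "study_design"), "design must come from make_design()")
  if (!inherits(params, "true_params")) params <- true_params(params)
  validate_params(params)
  assert_that(is_count(seed + 1), "seed must be a single integer")
  set.seed(as.integer(seed))
  p <- params
  M <- design$n_meadows
  A <- design$n_allotments
  Tn <- length(design$years)
  S <- design$sites_per_meadow
  seasons <- design$seasons

  allot_of_meadow <- rep.int(seq_len(A), design$meadows_per_allotment)

  # --- site wetness ranks (one-time, fixed scale) ---------------------
  meadow_mu <- p$rank_mean + p$rank_meadow_sd * rnorm(M)
  site_lat <- rep(meadow_mu, each = S) + p$rank_site_sd * rnorm(M * S)
  site_rank <- pmin(6L, pmax(0L, as.integer(round_half_up(site_lat))))

  mean_score <- colMeans(matrix(site_rank, nrow = S))
  sd_w <- sd(mean_score)
  assert_that(sd_w > 0,
              "degenerate design: meadow wetness has zero variance",
              class = "meadowsem_param_error")
  W <- (mean_score - mean(mean_score)) / sd_w   # standardized meadow wetness

  # --- random intercepts: equations q, p, u (Gaussian) and o (logit) --
  re <- list()
  for (eq in c("q", "p", "u", "o")) {
    re[[eq]] <- list(
      meadow    = p$sd_meadow    * rnorm(M),
      allotment = p$sd_allotment * rnorm(A),
      year      = p$sd_year      * rnorm(Tn)
    )
  }
  re_row <- function(eq, mi, ai, ti)
    re[[eq]]$meadow[mi] + re[[eq]]$allotment[ai] + re[[eq]]$year[ti]

  # --- meadow-season-year structural values (z scale) -----------------
  msy <- expand.grid(meadow = seq_len(M), year_i = seq_len(Tn),
                     season = seasons, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  msy$allot <- allot_of_meadow[msy$meadow]
  n_msy <- nrow(msy)

  zq <- rnorm(n_msy)
  zp_ind <- rnorm(n_msy)
  zeta_q <- p$sd_q * zq
  zeta_p <- p$sd_p * (p$rho_qp * zq + sqrt(1 - p$rho_qp^2) * zp_ind)

  msy$W <- W[msy$meadow]
  msy$Q <- p$gamma_wq * msy$W + re_row("q", msy$meadow, msy$allot, msy$year_i) + zeta_q
  msy$P <- p$gamma_wp * msy$W + re_row("p", msy$meadow, msy$allot, msy$year_i) + zeta_p
  msy$U <- p$beta_qu * msy$Q + p$beta_pu * msy$P +
    re_row("u", msy$meadow, msy$allot, msy$year_i) + p$sd_u * rnorm(n_msy)
  msy$cp_z  <- p$lambda_cp  * msy$Q + p$sd_cp  * rnorm(n_msy)
  msy$tp_z  <- p$lambda_tp  * msy$Q + p$sd_tp  * rnorm(n_msy)
  msy$adf_z <- p$lambda_adf * msy$Q + p$sd_adf * rnorm(n_msy)

  # --- site-level records ---------------------------------------------
  idx <- rep(seq_len(n_msy), each = S)
  maps <- unit_maps()
  site_noise <- function() p$sd_site * rnorm(n_msy * S)
  pos <- function(x, map) pmax(x, 0.01 * map[["center"]])
  sites <- data.frame(
    allotment = msy$allot[idx],
    meadow = msy$meadow[idx],
    site = rep(seq_len(S), times = n_msy) + (msy$meadow[idx] - 1L) * S,
    year = design$years[msy$year_i[idx]],
    season = msy$season[idx],
    site_rank = site_rank[(msy$meadow[idx] - 1L) * S + rep(seq_len(S), times = n_msy)],
    cp      = pos(z_to_unit(msy$cp_z[idx]  + site_noise(), maps$cp),  maps$cp),
    tp      = pos(z_to_unit(msy$tp_z[idx]  + site_noise(), maps$tp),  maps$tp),
    adf     = pos(z_to_unit(msy$adf_z[idx] + site_noise(), maps$adf), maps$adf),
    biomass = pos(z_to_unit(msy$P[idx]     + site_noise(), maps$biomass), maps$biomass),
    utilization = pmin(1, pmax(0, z_to_unit(msy$U[idx] + site_noise(), maps$util)))
  )

  # --- occupancy: once per meadow-year --------------------------------
  my <- expand.grid(meadow = seq_len(M), year_i = seq_len(Tn),
                    KEEP.OUT.ATTRS = FALSE)
  my$allotment <- allot_of_meadow[my$meadow]
  ubar <- with(msy, tapply(U, list(meadow, year_i), mean))
  my$ubar_z <- ubar[cbind(my$meadow, my$year_i)]
  my$W <- W[my$meadow]
  eta <- p$alpha + p$beta_wo * my$W + p$beta_uo * my$ubar_z +
    re_row("o", my$meadow, my$allotment, my$year_i)
  my$occupancy <- rbinom(nrow(my), 1L, plogis(eta))
  occ_rate <- tapply(my$occupancy, my$meadow, mean)

  # --- fecal pat density: cumulative-use indicator, final-year late use
  late_last <- msy[msy$season == seasons[3L] & msy$year_i == Tn, ]
  late_last <- late_last[order(late_last$meadow), ]
  fecal_z <- 0.9 * late_last$U + sqrt(1 - 0.9^2) * rnorm(M)
  fecal <- pmax(0, z_to_unit(fecal_z, maps$fecal))

  # --- meadow-year table ----------------------------------------------
  cr <- composite_rank_table(sites)
  meadow_years <- data.frame(
    meadow = my$meadow,
    allotment = my$allotment,
    year = design$years[my$year_i],
    mean_score = cr$mean_score[my$meadow],
    composite_rank = cr$composite_rank[my$meadow],
    occupancy = my$occupancy,
    occupancy_rate = as.numeric(occ_rate[my$meadow]),
    fecal_density = fecal[my$meadow]
  )
  # season-level means of site measurements per meadow-year
  agg_vars <- c("cp", "tp", "adf", "biomass", "utilization")
  for (s in seasons) {
    sub <- sites[sites$season == s, ]
    ag <- aggregate(sub[agg_vars], by = sub[c("meadow", "year")], FUN = mean)
    names(ag)[-(1:2)] <- paste0(agg_vars, "_", s)
    meadow_years <- merge(meadow_years, ag, by = c("meadow", "year"),
                          sort = FALSE)
  }
  meadow_years <- meadow_years[order(meadow_years$meadow, meadow_years$year), ]
  rownames(meadow_years) <- NULL

  structure(list(sites = sites, meadow_years = meadow_years,
                 params = p, design = design, seed = as.integer(seed)),
            class = "meadow_sim")
}

#' Write a simulated study to disk
#'
#' Writes `sites.csv`, `meadow_years.csv` and `truth.json` (the generating
#' parameters) into `dir`.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  assert_that(inherits(sim, "meadow_sim"), "sim must come from simulate_study()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sites = file.path(dir, "sites.csv"),
    meadow_years = file.path(dir, "meadow_years.csv"),
    truth = file.path(dir, "truth.json")
  )
  write.csv(sim$sites, paths["sites"], row.names = FALSE)
  write.csv(sim$meadow_years, paths["meadow_years"], row.names = FALSE)
  jsonlite::write_json(c(unclass(sim$params), list(seed = sim$seed)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
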