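#' Generating ("true") parameters for the synthetic meadow system
#'
#' Parameterizes the causal structure used by [simulate_study()]: on a
#' standardized scale, meadow wetness W drives a latent forage-quality
#' factor Q (measured by crude protein CP, total phosphorus TP, and acid
#' detergent fiber ADF) and observed productivity P; Q and P drive
#' herbaceous utilization U by cattle; and W (and, optionally, U) drives
#' toad breeding occupancy on the logit scale. Forage quality and
#' productivity decline with wetness, ADF loads negatively on quality
#' (higher fiber = lower digestibility), and the default utilization
#' effect on occupancy is exactly zero, so the wetness pathway is the only
#' true driver of occupancy.
#'
#' Defaults (standardized/logit scale): `gamma_wq = -0.6`,
#' `gamma_wp = -0.45`, `beta_qu = 0.5`, `beta_pu = 0.5`, `alpha = 0`,
#' `beta_wo = 1.8`, `beta_uo = 0`; loadings `lambda_cp = 1` (fixed,
#' identifies the latent scale), `lambda_tp = 0.8`, `lambda_adf = -0.7`;
#' structural disturbance SDs `sd_q = 0.6`, `sd_p = 0.8`, `sd_u = 0.6`
#' with disturbance correlation `rho_qp = 0`; meadow-level indicator
#' residual SDs `sd_cp = 0.5`, `sd_tp = 0.6`, `sd_adf = 0.6`; random-effect
#' SDs `sd_meadow = 0.3`, `sd_allotment = 0.2`, `sd_year = 0.2`; site-level
#' scatter `sd_site = 0.3`; site-rank process `rank_mean = 3`,
#' `rank_meadow_sd = 1.3`, `rank_site_sd = 1`.
#'
#' @param ... Named overrides of any default.
#' @return An object of class `true_params` (named list).
#' @examples
#' p <- true_params(beta_wo = 2.5)
#' p$lambda_cp  # always 1
#' @export
true_params <- function(...) {
  defaults <- list(
    # structural path coefficients
    gamma_wq = -0.6, gamma_wp = -0.45,
    beta_qu = 0.5, beta_pu = 0.5,
    alpha = 0, beta_wo = 1.8, beta_uo = 0,
    # measurement model
    lambda_cp = 1, lambda_tp = 0.8, lambda_adf = -0.7,
    sd_cp = 0.5, sd_tp = 0.6, sd_adf = 0.6,
    # structural disturbances
    sd_q = 0.6, sd_p = 0.8, sd_u = 0.6, rho_qp = 0,
    # hierarchical random-effect SDs (shared across equations)
    sd_meadow = 0.3, sd_allotment = 0.2, sd_year = 0.2,
    # site-level scatter around meadow-season values (z scale)
    sd_site = 0.3,
    # site wetness-rank process (latent normal, discretized to 0..6)
    rank_mean = 3, rank_meadow_sd = 1.3, rank_site_sd = 1
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(defaults))
  assert_that(length(unknown) == 0L,
              paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")),
              class = "meadowsem_param_error")
  p <- modifyList(defaults, over)
  validate_params(p)
  structure(p, class = "true_params")
}

validate_params <- function(p) {
  assert_that(isTRUE(all.equal(p$lambda_cp, 1)),
              "lambda_cp is the fixed scale-setting loading and must equal 1",
              class = "meadowsem_param_error")
  sds <- c("sd_cp", "sd_tp", "sd_adf", "sd_q", "sd_p", "sd_u",
           "sd_meadow", "sd_allotment", "sd_year", "sd_site",
           "rank_meadow_sd", "rank_site_sd")
  for (s in sds)
    assert_that(is.numeric(p[[s]]) && p[[s]] >= 0,
                paste0(s, " must be a nonnegative number"),
                class = "meadowsem_param_error")
  assert_that(is.numeric(p$rho_qp) && abs(p$rho_qp) < 1,
              "rho_qp must lie strictly inside (-1, 1)",
              class = "meadowsem_param_error")
  invisible(TRUE)
}

# Affine maps taking standardized (z) values to realistic field units.
# Centers/half-ranges are chosen so +/-2.5 SD spans the observed gradients:
# CP 6-22 % DM, TP 0.07-0.30 % DM, ADF 15-39 % DM, biomass 1000-3200
# kg/ha, utilization 4-49 % of herbaceous biomass.
unit_maps <- function() {
  list(
    cp      = c(center = 14,    scale = 3.2),
    tp      = c(center = 0.185, scale = 0.046),
    adf     = c(center = 27,    scale = 4.8),
    biomass = c(center = 2100,  scale = 440),
    util    = c(center = 0.265, scale = 0.09),
    fecal   = c(center = 10,    scale = 5)
  )
}

z_to_unit <- function(z, map) unname(map["center"] + map["scale"] * z)
unit_to_z <- function(x, map) unname((x - map["center"]) / map["scale"])
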