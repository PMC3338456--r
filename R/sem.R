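#' Specify the hierarchical meadow SEM
#'
#' Declares the structural graph fitted by [sample_posterior()]: observed
#' meadow wetness W drives latent forage quality Q (indicators CP, TP, ADF;
#' the CP loading is fixed at 1 to set the latent scale, ADF is expected to
#' load negatively) and observed productivity P, with correlated (Q, P)
#' disturbances; Q and P drive observed cattle utilization U; W and U drive
#' binary breeding occupancy O through a logit link. Every equation carries
#' random intercepts for meadow (nested in allotment) and year; intercept
#' SDs are shared across equations.
#'
#' @param season Season label the fit applies to (`"early"`, `"mid"`,
#'   `"late"`); data preparation selects the matching seasonal columns.
#' @param include_occupancy If FALSE, the Bernoulli occupancy node is
#'   dropped and the model is purely Gaussian (used for conjugate
#'   cross-checks).
#' @return Object of class `sem_spec`.
#' @export
sem_spec <- function(season = "early", include_occupancy = TRUE) {
  structure(list(
    season = season,
    nodes = c(W = "observed", Q = "latent", P = "observed",
              U = "observed", O = if (include_occupancy) "observed" else NA),
    edges = list(c("W", "Q"), c("W", "P"), c("Q", "U"), c("P", "U"),
                 if (include_occupancy) c("W", "O"),
                 if (include_occupancy) c("U", "O")),
    indicators = list(Q = c(cp = "fixed@1", tp = "free", adf = "free")),
    disturbance_correlation = c("Q", "P"),
    grouping = list(meadow = "nested in allotment", year = "crossed"),
    include_occupancy = include_occupancy
  ), class = "sem_spec")
}

# Scalar parameters of the SEM, in canonical order
sem_param_names <- function(spec) {
  base <- c("gamma_wq", "gamma_wp", "beta_qu", "beta_pu",
            "lambda_tp", "lambda_adf",
            "sd_cp", "sd_tp", "sd_adf", "sd_q", "sd_p", "sd_u",
            "sd_meadow", "sd_allotment", "sd_year", "rho_qp")
  if (spec$include_occupancy) c(base, "alpha", "beta_wo", "beta_uo") else base
}

# Structural path coefficients (the acceptance surface)
sem_structural_names <- function(spec) {
  base <- c("gamma_wq", "gamma_wp", "beta_qu", "beta_pu",
            "lambda_tp", "lambda_adf")
  if (spec$include_occupancy) c(base, "alpha", "beta_wo", "beta_uo") else base
}

#' Standardize continuous columns of a data frame
#'
#' Centers and scales each requested column to sample mean 0 and SD 1
#' (denominator n - 1), recording the transform so it can be inverted
#' exactly with [unstandardize()].
#'
#' @param data A data frame.
#' @param cols Character vector of columns to standardize (default: all
#'   numeric columns).
#' @return List with `data` (transformed) and `scaling` (data frame of
#'   column, center, scale).
#' @export
standardize <- function(data, cols = NULL) {
  assert_that(is.data.frame(data), "data must be a data frame")
  if (is.null(cols))
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  assert_that(all(cols %in% names(data)), "unknown column in cols")
  center <- scale <- numeric(length(cols))
  for (i in seq_along(cols)) {
    x <- data[[cols[i]]]
    s <- sd(x)
    assert_that(is.finite(s) && s > 0,
                paste0("column '", cols[i], "' has zero variance and cannot be standardized"))
    center[i] <- mean(x)
    scale[i] <- s
    data[[cols[i]]] <- (x - center[i]) / s
  }
  list(data = data,
       scaling = data.frame(column = cols, center = center, scale = scale,
                            stringsAsFactors = FALSE))
}

#' Invert a standardization
#'
#' @param data Standardized data frame.
#' @param scaling The `scaling` record from [standardize()].
#' @return Data frame on the original scale.
#' @export
unstandardize <- function(data, scaling) {
  for (i in seq_len(nrow(scaling))) {
    cl <- scaling$column[i]
    data[[cl]] <- data[[cl]] * scaling$scale[i] + scaling$center[i]
  }
  data
}

#' Prepare a standardized meadow-year table for one seasonal SEM fit
#'
#' Selects the season's forage-quality, biomass and utilization columns
#' from a meadow-year table, standardizes all continuous variables, drops
#' rows with missing values (count reported via message), and indexes
#' meadows, allotments and years for the hierarchical model.
#'
#' @param meadow_years Meadow-year table ([simulate_study()] layout).
#' @param season Season label matching the design's seasons.
#' @return Object of class `sem_data` with standardized vectors `W`, `cp`,
#'   `tp`, `adf`, `P`, `U`, binary `O`, grouping indices and sizes, and
#'   the `scaling` record.
#' @export
prepare_sem_data <- function(meadow_years, season = "early") {
  need <- c("meadow", "allotment", "year", "composite_rank", "occupancy",
            paste0(c("cp_", "tp_", "adf_", "biomass_", "utilization_"), season))
  missing_cols <- setdiff(need, names(meadow_years))
  assert_that(length(missing_cols) == 0L,
              paste0("meadow_years lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  df <- meadow_years[, need]
  names(df) <- c("meadow", "allotment", "year", "W", "O",
                 "cp", "tp", "adf", "P", "U")
  keep <- complete.cases(df)
  if (any(!keep))
    message(sum(!keep), " row(s) with missing values dropped before SEM fit")
  df <- df[keep, ]
  st <- standardize(df, cols = c("W", "cp", "tp", "adf", "P", "U"))
  d <- st$data
  mi <- as.integer(factor(d$meadow, levels = unique(d$meadow)))
  ai <- as.integer(factor(d$allotment, levels = unique(d$allotment)))
  ti <- as.integer(factor(d$year, levels = unique(d$year)))
  structure(list(
    n = nrow(d), W = d$W, cp = d$cp, tp = d$tp, adf = d$adf,
    P = d$P, U = d$U, O = as.integer(d$O),
    mi = mi, ai = ai, ti = ti,
    M = max(mi), A = max(ai), Tn = max(ti),
    meadow_ids = unique(df$meadow), year_ids = unique(df$year),
    scaling = st$scaling, season = season, n_dropped = sum(!keep)
  ), class = "sem_data")
}

# Subset a sem_data object to rows `keep` (used by leave-one-out refits).
# Group sizes are kept so random-effect vectors keep their length even if
# a group loses all its rows.
sem_data_subset <- function(data, keep) {
  out <- data
  for (f in c("W", "cp", "tp", "adf", "P", "U", "O", "mi", "ai", "ti"))
    out[[f]] <- data[[f]][keep]
  out$n <- length(out$W)
  out
}

#' Significance flags from posterior credible intervals
#'
#' A parameter is flagged `**` when its equal-tailed 95% credible interval
#' excludes zero, `*` when the 90% interval excludes zero but the 95% does
#' not, and `NS` otherwise.
#'
#' @param samples A `posterior_samples` object (or a named list of numeric
#'   draw vectors).
#' @param params Parameter names to flag; defaults to the structural path
#'   coefficients when `samples` is a `posterior_samples` object, else all
#'   names.
#' @return Named character vector of flags.
#' @export
significance_flags <- function(samples, params = NULL) {
  draws <- pooled_draws(samples, params)
  vapply(draws, function(x) {
    assert_that(length(x) > 0, "empty draws")
    q95 <- quantile(x, c(0.025, 0.975), names = FALSE)
    q90 <- quantile(x, c(0.05, 0.95), names = FALSE)
    if (q95[1] > 0 || q95[2] < 0) "**"
    else if (q90[1] > 0 || q90[2] < 0) "*"
    else "NS"
  }, character(1))
}

# Pool chains into one draw vector per requested scalar parameter
pooled_draws <- function(samples, params = NULL) {
  if (inherits(samples, "posterior_samples")) {
    if (is.null(params)) params <- samples$structural
    lapply(setNames(params, params), function(p) as.numeric(samples$draws[[p]]))
  } else {
    if (is.null(params)) params <- names(samples)
    lapply(setNames(params, params), function(p) as.numeric(samples[[p]]))
  }
}

#' Posterior summary table
#'
#' Means, SDs, equal-tailed credible intervals, significance flags and
#' split-chain-free Gelman-Rubin R-hat for each scalar parameter.
#'
#' @param samples A `posterior_samples` object.
#' @param params Parameters to summarize (default: all scalars).
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame with one row per parameter.
#' @export
posterior_summary <- function(samples, params = NULL, prob = 0.95) {
  assert_that(inherits(samples, "posterior_samples"),
              "samples must come from sample_posterior()")
  if (is.null(params)) params <- samples$scalars
  a <- (1 - prob) / 2
  rows <- lapply(params, function(p) {
    m <- samples$draws[[p]]          # chains x iterations
    pooled <- as.numeric(m)
    data.frame(
      parameter = p, mean = mean(pooled), sd = sd(pooled),
      lower = quantile(pooled, a, names = FALSE),
      upper = quantile(pooled, 1 - a, names = FALSE),
      rhat = gelman_rubin(t(m)),
      ess = effective_size(t(m))
    )
  })
  out <- do.call(rbind, rows)
  out$flag <- significance_flags(samples, params)
  rownames(out) <- NULL
  out
}
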