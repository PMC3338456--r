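#' ROC curve and AUC by rank statistic
#'
#' The area under the receiver operating characteristic curve is computed
#' as the Mann-Whitney probability `P(score+ > score-) + 0.5 * P(tie)`
#' using midranks; the curve itself is a threshold sweep with tied scores
#' grouped, running from (0, 0) to (1, 1). AUC 0.5 is chance-level
#' ranking, 1 is perfect.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return Object of class `roc_result`: `points` (data frame of `fpr`,
#'   `tpr`, monotone nondecreasing), `auc`, `n_positive`, `n_negative`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  assert_that(length(scores) == length(labels) && length(scores) >= 2,
              "scores and labels must be equal-length (>= 2)")
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  assert_that(n_pos > 0 && n_neg > 0,
              "both classes must be present to compute a ROC curve")
  r <- rank(scores)   # midranks handle ties
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(c(diff(s) != 0, TRUE))   # last index of each tie group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(points = points, auc = auc,
                 n_positive = n_pos, n_negative = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' Leave-one-out cross-validated occupancy probabilities
#'
#' For each meadow-year unit, predicts the posterior-predictive probability
#' of breeding occupancy with that unit held out. Two routes:
#' `"importance"` (default) fits the full posterior once and reweights each
#' draw by the inverse of the held-out unit's likelihood (leave-one-out
#' importance sampling); `"refit"` re-runs the sampler without the unit
#' (at the supplied, typically reduced, MCMC settings). In both routes the
#' held-out unit's meadow intercept is integrated out by drawing from its
#' population distribution `Normal(0, sd_meadow)` per posterior draw;
#' allotment and year intercepts are shared with retained units and kept
#' at their sampled values.
#'
#' @param spec A [sem_spec()] with the occupancy node.
#' @param data A [prepare_sem_data()] object with both occupancy classes.
#' @param method `"importance"` or `"refit"`.
#' @param n_chains,n_iter,burn_in MCMC settings for the underlying fit(s).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param samples Optional pre-computed `posterior_samples` for the
#'   importance route (must match `spec`/`data`).
#' @return Data frame with one row per unit: `meadow`, `year`, `prob`
#'   (held-out predictive probability), `occupancy` (observed label).
#' @export
loo_cv_occupancy <- function(spec, data, method = c("importance", "refit"),
                             n_chains = 2, n_iter = 2000, burn_in = 800,
                             seed = 1, samples = NULL) {
  method <- match.arg(method)
  assert_that(inherits(spec, "sem_spec") && spec$include_occupancy,
              "spec must include the occupancy node")
  assert_that(inherits(data, "sem_data"), "data must come from prepare_sem_data()")
  assert_that(sum(data$O == 1L) > 0 && sum(data$O == 0L) > 0,
              "both occupied and unoccupied units are required (AUC undefined otherwise)")

  if (method == "importance") {
    if (is.null(samples))
      samples <- sample_posterior(spec, data, n_chains = n_chains,
                                  n_iter = n_iter, burn_in = burn_in,
                                  seed = seed)
    prob <- loo_importance_probs(samples, data, seed)
  } else {
    prob <- vapply(seq_len(data$n), function(i) {
      sub <- sem_data_subset(data, setdiff(seq_len(data$n), i))
      fit <- sample_posterior(spec, sub, n_chains = n_chains,
                              n_iter = n_iter, burn_in = burn_in,
                              seed = seed + i)
      predict_unit_prob(fit, data, i, seed + i)
    }, numeric(1))
  }
  data.frame(meadow = data$meadow_ids[data$mi],
             year = data$year_ids[data$ti],
             prob = prob, occupancy = data$O)
}

# pooled draw matrix (draws x K) for a possibly vector-valued parameter
pool_mat <- function(samples, name) {
  d <- samples$draws[[name]]
  if (length(dim(d)) == 3L) {
    out <- do.call(rbind, lapply(seq_len(dim(d)[1]), function(ch) d[ch, , ]))
    if (dim(d)[3] == 1L) out <- matrix(out, ncol = 1L)
    out
  } else matrix(as.numeric(t(d)), ncol = 1L)[, 1L]
}

# importance-reweighted held-out probabilities, vectorized over draws
loo_importance_probs <- function(samples, data, seed) {
  alpha <- pool_mat(samples, "alpha")
  bwo <- pool_mat(samples, "beta_wo")
  buo <- pool_mat(samples, "beta_uo")
  sdm <- pool_mat(samples, "sd_meadow")
  mO <- pool_mat(samples, "re_o_meadow")
  aO <- pool_mat(samples, "re_o_allotment")
  tO <- pool_mat(samples, "re_o_year")
  nd <- length(alpha)
  base <- outer(alpha, rep(1, data$n)) +
    outer(bwo, data$W) + outer(buo, data$U) +
    aO[, data$ai, drop = FALSE] + tO[, data$ti, drop = FALSE]
  eta_fit <- base + mO[, data$mi, drop = FALSE]
  p_fit <- plogis(eta_fit)
  lik <- sweep(p_fit, 2, data$O, function(p, o) ifelse(o == 1L, p, 1 - p))
  w <- 1 / pmax(lik, 1e-12)
  set.seed(as.integer(seed) + 271828L)
  Z <- matrix(rnorm(nd * data$n), nd, data$n)
  p_pred <- plogis(base + Z * sdm)
  colSums(w * p_pred) / colSums(w)
}

# posterior-predictive probability for one held-out unit from a refit
predict_unit_prob <- function(fit, data, i, seed) {
  alpha <- pool_mat(fit, "alpha")
  bwo <- pool_mat(fit, "beta_wo")
  buo <- pool_mat(fit, "beta_uo")
  sdm <- pool_mat(fit, "sd_meadow")
  aO <- pool_mat(fit, "re_o_allotment")
  tO <- pool_mat(fit, "re_o_year")
  nd <- length(alpha)
  set.seed(as.integer(seed) + 314159L)
  eta <- alpha + bwo * data$W[i] + buo * data$U[i] +
    aO[, data$ai[i]] + tO[, data$ti[i]] + sdm * rnorm(nd)
  mean(plogis(eta))
}
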