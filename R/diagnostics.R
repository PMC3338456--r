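#' Gelman-Rubin potential scale reduction factor (R-hat)
#'
#' Computes the modified (Brooks-Gelman) potential scale reduction factor
#' from parallel chains: with within-chain variance W, between-chain
#' variance B (per iteration), chain length n and m chains, the pooled
#' variance estimate is `V = (n-1)/n * W + (1 + 1/m) * B / n` and
#' `R-hat = sqrt(V / W)` (the sampling-variability-inflated BUGS-era
#' estimator). Values near 1 indicate mixing; identical duplicated chains
#' give `sqrt((n-1)/n)`, i.e. 1 up to the small-sample correction.
#'
#' @param chains Either a numeric matrix (iterations x chains) or a list
#'   of equal-length numeric vectors, one per chain.
#' @return A single R-hat value (`Inf` when chains are separated constants;
#'   1 when all draws are identical).
#' @export
gelman_rubin <- function(chains) {
  ch <- as_chain_matrix(chains)
  n <- nrow(ch); m <- ncol(ch)
  assert_that(m >= 2, "at least 2 chains required")
  assert_that(n >= 10, "chains must have length >= 10")
  W <- mean(apply(ch, 2, var))
  B_over_n <- var(colMeans(ch))            # = B / n
  if (W < 1e-300) return(if (B_over_n > 0) Inf else 1)
  V <- (n - 1) / n * W + (1 + 1 / m) * B_over_n
  sqrt(V / W)
}

as_chain_matrix <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    assert_that(length(len) == 1L, "chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  assert_that(is.matrix(chains) && is.numeric(chains),
              "chains must be a numeric matrix or list of vectors")
  chains
}

#' Effective sample size from parallel chains
#'
#' Crude between/within estimate `m * n * V / B`, capped at the total
#' number of draws (used for reporting alongside R-hat).
#'
#' @inheritParams gelman_rubin
#' @return Effective sample size estimate.
#' @export
effective_size <- function(chains) {
  ch <- as_chain_matrix(chains)
  n <- nrow(ch); m <- ncol(ch)
  W <- mean(apply(ch, 2, var))
  B <- n * var(colMeans(ch))
  if (B < 1e-300) return(m * n)
  V <- (n - 1) / n * W + (1 + 1 / m) * B / n
  min(m * n, m * n * V / B)
}

#' Convergence report for a fitted SEM posterior
#'
#' Per-parameter R-hat and effective sample size with a pass flag at a
#' configurable threshold.
#'
#' @param samples A `posterior_samples` object.
#' @param params Parameters to assess (default: all scalar parameters).
#' @param threshold R-hat pass threshold (default 1.1).
#' @return Data frame: parameter, rhat, ess, pass; attribute `all_pass`.
#' @export
convergence_report <- function(samples, params = NULL, threshold = 1.1) {
  assert_that(inherits(samples, "posterior_samples"),
              "samples must come from sample_posterior()")
  if (is.null(params)) params <- samples$scalars
  rows <- lapply(params, function(p) {
    m <- t(samples$draws[[p]])     # iterations x chains
    data.frame(parameter = p, rhat = gelman_rubin(m),
               ess = effective_size(m))
  })
  out <- do.call(rbind, rows)
  out$pass <- out$rhat < threshold
  attr(out, "all_pass") <- all(out$pass)
  attr(out, "threshold") <- threshold
  out
}

#' Deviance Information Criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance, `pD = Dbar -
#' D(theta_bar)` the effective number of parameters, and `D(theta_bar)`
#' the deviance at the posterior mean of the parameters (SDs averaged on
#' the log scale; see [posterior_mean_params()]). Lower DIC is preferred
#' in model comparisons.
#'
#' @param samples Either a `posterior_samples` object (draws are then
#'   reconstructed via [draw_params()], optionally thinned by
#'   `eval_thin`), or a list of parameter states, in which case
#'   `at_mean` must supply the plug-in state.
#' @param deviance_fn Function mapping a parameter state to its deviance.
#' @param eval_thin Evaluate the deviance on every `eval_thin`-th kept
#'   draw (default 10) to bound cost; `Dbar` is their mean.
#' @param at_mean Optional explicit plug-in parameter state.
#' @return Object of class `dic_report`: list with `Dbar`, `D_at_mean`,
#'   `pD`, `DIC`.
#' @export
dic <- function(samples, deviance_fn, eval_thin = 10, at_mean = NULL) {
  if (inherits(samples, "posterior_samples")) {
    iters <- seq(1, samples$n_keep, by = eval_thin)
    devs <- unlist(lapply(seq_len(samples$n_chains), function(ch)
      vapply(iters, function(i) deviance_fn(draw_params(samples, ch, i)),
             numeric(1))))
    if (is.null(at_mean)) at_mean <- posterior_mean_params(samples)
  } else {
    assert_that(is.list(samples) && length(samples) > 0,
                "samples must be a posterior_samples object or list of states")
    assert_that(!is.null(at_mean), "at_mean required for raw draw lists")
    devs <- vapply(samples, deviance_fn, numeric(1))
  }
  bad <- which(!is.finite(devs))
  assert_that(length(bad) == 0L,
              paste0("non-finite deviance at draw(s): ",
                     paste(utils::head(bad, 10), collapse = ", ")))
  Dbar <- mean(devs)
  D_at_mean <- deviance_fn(at_mean)
  assert_that(is.finite(D_at_mean), "non-finite deviance at posterior mean")
  pD <- Dbar - D_at_mean
  structure(list(Dbar = Dbar, D_at_mean = D_at_mean, pD = pD,
                 DIC = Dbar + pD), class = "dic_report")
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("DIC = %.3f (Dbar = %.3f, pD = %.3f)\n", x$DIC, x$Dbar, x$pD))
  invisible(x)
}
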