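# Internal helpers shared across modules.

# stop() wrapper with a consistent condition class so callers/tests can
# distinguish user/input errors from R-level failures.
msem_error <- function(msg, class = "meadowsem_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "meadowsem_error", "error")))
}

assert_that <- function(ok, msg, class = "meadowsem_validation_error") {
  if (!isTRUE(ok)) msem_error(msg, class = class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# Round half away from zero (so 3.5 -> 4), unlike base round()'s
# round-half-even. Inputs here are non-negative mean scores.
round_half_up <- function(x) floor(x + 0.5)

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

# log(1 + exp(x)) without overflow
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Bernoulli-logit log likelihood for 0/1 y with linear predictor eta
bern_loglik <- function(y, eta) sum(y * eta - log1pexp(eta))

# Group sums for vectors indexed by an integer factor 1..K
group_sum <- function(x, idx, K) {
  as.numeric(rowsum(x, idx, reorder = FALSE)[as.character(seq_len(K)), 1L][
    order(seq_len(K))])
}

# rowsum() keyed simply; faster, stable ordering
gsum <- function(x, idx, K) {
  out <- numeric(K)
  tab <- rowsum(x, idx)
  out[as.integer(rownames(tab))] <- tab[, 1L]
  out
}

gcount <- function(idx, K) tabulate(idx, nbins = K)

sample_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sd(x)
  z <- (x - m) / s
  list(mean = m, sd = s,
       skewness = mean(z^3),
       kurtosis_excess = mean(z^4) - 3)
}
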