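# hand-applied modified (Brooks-Gelman) formula for reference
rhat_hand <- function(ch) {
  n <- nrow(ch); m <- ncol(ch)
  W <- mean(apply(ch, 2, var))
  B_over_n <- var(colMeans(ch))
  sqrt(((n - 1) / n * W + (1 + 1 / m) * B_over_n) / W)
}

test_that("R-hat is near 1 for same-distribution chains", {
  set.seed(42)
  ch <- matrix(rnorm(4000), ncol = 2)
  expect_lt(abs(gelman_rubin(ch) - 1), 0.02)
  # list-of-vectors input works too
  expect_equal(gelman_rubin(list(ch[, 1], ch[, 2])), gelman_rubin(ch))
})

test_that("separated constant chains give a huge (guarded) R-hat", {
  ch <- cbind(rep(0, 100), rep(10, 100))
  # within-chain variance is zero: the ratio diverges
  expect_equal(gelman_rubin(ch), Inf)
  # small within-chain noise: value matches the hand-applied formula
  set.seed(1)
  ch2 <- cbind(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1))
  expect_equal(gelman_rubin(ch2), rhat_hand(ch2), tolerance = 1e-12)
  expect_gt(gelman_rubin(ch2), 10)
})

test_that("a duplicated identical chain gives 1 up to the small-sample correction", {
  set.seed(2)
  x <- rnorm(200)
  ch <- cbind(x, x)
  n <- length(x)
  expect_equal(gelman_rubin(ch), sqrt((n - 1) / n), tolerance = 1e-12)
})

test_that("R-hat requires at least two chains and is affine invariant", {
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
  set.seed(3)
  ch <- matrix(rnorm(600), ncol = 3)
  expect_equal(gelman_rubin(3 - 5 * ch), gelman_rubin(ch), tolerance = 1e-12)
})

test_that("DIC identity and degenerate posterior", {
  dev <- function(p) (p$mu - 3)^2 + 7
  draws <- replicate(20, list(mu = 1.5), simplify = FALSE)
  rep <- dic(draws, dev, at_mean = list(mu = 1.5))
  expect_equal(rep$pD, 0)
  expect_equal(rep$DIC, dev(list(mu = 1.5)))
  expect_equal(rep$DIC, rep$Dbar + rep$pD)
})

test_that("DIC matches the conjugate normal-mean closed form", {
  # y_i ~ N(mu, sigma^2) with sigma known, mu ~ N(0, tau0^2):
  # posterior mu ~ N(mn, vn); E[D] = D(mn) + n * vn / sigma^2, so
  # DIC = D(mn) + 2 * n * vn / sigma^2. A symmetric two-point draw set
  # {mn - s, mn + s} has mean deviance D(mn) + n s^2 / sigma^2 exactly,
  # so dic() must reproduce the closed form with vn = s^2 to 1e-6.
  set.seed(10)
  sigma <- 1.3; tau0 <- 10
  y <- rnorm(12, 2, sigma)
  n <- length(y)
  prec <- n / sigma^2 + 1 / tau0^2
  mn <- sum(y) / sigma^2 / prec
  dev <- function(p) sum((y - p$mu)^2) / sigma^2 + n * log(2 * pi * sigma^2)
  s <- sqrt(1 / prec)
  draws <- list(list(mu = mn - s), list(mu = mn + s))
  rep <- dic(draws, dev, at_mean = list(mu = mn))
  closed_form <- dev(list(mu = mn)) + 2 * n * (1 / prec) / sigma^2
  expect_lt(abs(rep$DIC - closed_form), 1e-6)
  expect_equal(rep$pD, n * (1 / prec) / sigma^2, tolerance = 1e-10)

  # and with genuine Monte-Carlo draws from the conjugate posterior the
  # estimate agrees within sampling error
  set.seed(11)
  mus <- rnorm(20000, mn, s)
  rep2 <- dic(lapply(mus, function(m) list(mu = m)), dev,
              at_mean = list(mu = mn))
  expect_lt(abs(rep2$DIC - closed_form), 0.2)
})

test_that("an irrelevant covariate increases DIC in most replicates", {
  # conjugate normal regression: y = b x1 + e vs y = b x1 + c x2 + e with
  # x2 pure noise; exact conjugate posterior draws, conditional deviance
  worse <- 0
  for (r in 1:10) {
    set.seed(600 + r)
    n <- 40
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 0.8 * x1 + rnorm(n)
    dic_for <- function(X) {
      XtX <- crossprod(X) + diag(1e-4, ncol(X))
      bh <- solve(XtX, crossprod(X, y))
      Sig <- solve(XtX)
      set.seed(700 + r)
      draws <- lapply(1:400, function(i)
        list(b = as.numeric(bh + t(chol(Sig)) %*% rnorm(ncol(X)))))
      dev <- function(p) sum((y - X %*% p$b)^2) + n * log(2 * pi)
      dic(draws, dev, at_mean = list(b = as.numeric(bh)))$DIC
    }
    worse <- worse + (dic_for(cbind(x1, x2)) > dic_for(cbind(x1)))
  }
  expect_gte(worse, 6)
})

test_that("dic rejects non-finite deviances, naming the draws", {
  dev <- function(p) if (p$mu > 1) Inf else 1
  draws <- list(list(mu = 0), list(mu = 2))
  expect_error(dic(draws, dev, at_mean = list(mu = 0)), "draw")
})

test_that("convergence_report flags parameters against the threshold", {
  fit <- default_fit()
  conv <- convergence_report(fit, c("gamma_wq", "beta_wo", "sd_q"))
  expect_equal(nrow(conv), 3L)
  expect_true(all(is.finite(conv$rhat)))
  expect_type(attr(conv, "all_pass"), "logical")
})
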