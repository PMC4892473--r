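test_that("intercept-only null fits return the class prevalence", {
  y <- rep(c(1, 0), each = 25)
  fit <- fit_null_logistic(y)
  expect_equal(unname(fit$fitted_means), rep(0.5, 50))
  expect_equal(sum(fit$residuals), 0)

  y2 <- rep(c(1, 0), c(15, 35))
  fit2 <- fit_null_logistic(y2)
  expect_equal(unname(fit2$fitted_means), rep(0.3, 50))
})

test_that("null fits with covariates match an independent Newton oracle", {
  set.seed(8)
  x <- rep(c(0, 1), each = 3)
  y <- c(0, 1, 0, 1, 1, 0)
  fit <- fit_null_logistic(y, matrix(x))
  orc <- oracle_logistic(cbind(1, x), y)
  expect_equal(unname(fit$fitted_means), unname(orc$mu), tolerance = 1e-8)
  expect_equal(fit$log_likelihood, orc$loglik, tolerance = 1e-8)

  set.seed(9)
  X <- cbind(rnorm(80), rbinom(80, 1, 0.4))
  yy <- rbinom(80, 1, plogis(0.2 + 0.5 * X[, 1]))
  f2 <- fit_null_logistic(yy, X)
  o2 <- oracle_logistic(cbind(1, X), yy)
  expect_equal(unname(f2$fitted_means), unname(o2$mu), tolerance = 1e-8)
})

test_that("degenerate phenotypes and designs are rejected", {
  expect_error(fit_null_logistic(rep(1, 10)), "single class")
  expect_error(fit_null_logistic(c(0, 1, 2, 1)), "0/1")
  expect_error(fit_null_logistic(rep(c(0, 1), 5), matrix(1, 10, 1)),
               "rank-deficient")
})

test_that("likelihood ratio test matches a direct two-group computation", {
  # binary Z splits samples into two groups; the logistic MLE fits the
  # group prevalences, so the LRT has a closed form in the four counts
  y <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  z <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  n11 <- sum(y == 1 & z == 1); n01 <- sum(y == 0 & z == 1)
  n10 <- sum(y == 1 & z == 0); n00 <- sum(y == 0 & z == 0)
  ll_groups <- function(k, n) if (k == 0 || k == n) 0 else
    k * log(k / n) + (n - k) * log(1 - k / n)
  ll_full <- ll_groups(n11, n11 + n01) + ll_groups(n10, n10 + n00)
  ll_null <- ll_groups(sum(y), length(y))
  expected <- 2 * (ll_full - ll_null)

  res <- logistic_lrt(y, matrix(z))
  expect_equal(res$statistic, expected, tolerance = 1e-7)
  expect_equal(res$df, 1L)
  expect_equal(res$p.value, pchisq(expected, 1, lower.tail = FALSE),
               tolerance = 1e-7)
})

test_that("score columns collinear with the design contribute nothing", {
  y <- rep(c(1, 0), 10)
  expect_warning(res <- logistic_lrt(y, matrix(1, 20, 1)), "collinear")
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 0L)
  expect_equal(res$p.value, 1)

  set.seed(2)
  Z <- cbind(rnorm(20))
  expect_warning(res2 <- logistic_lrt(y, cbind(Z, Z)), "collinear")
  expect_equal(res2$df, 1L)
})

test_that("null LRT p-values are approximately uniform", {
  set.seed(31)
  n <- 150
  pvals <- replicate(400, {
    y <- rbinom(n, 1, 0.5)
    Z <- matrix(rnorm(n * 2), n)
    logistic_lrt(y, Z)$p.value
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
  rej <- mean(pvals <= 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)
})

test_that("the lean IRLS solver agrees with glm", {
  set.seed(4)
  s <- rnorm(200)
  y <- rbinom(200, 1, plogis(0.4 + 0.8 * s))
  f <- cpgset:::fast_logistic(cbind(1, s), y)
  g <- glm(y ~ s, family = binomial)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(f$log_likelihood, as.numeric(logLik(g)), tolerance = 1e-7)
  fs <- cpgset:::fast_logistic_slope(s, y)
  expect_equal(fs$T, coef(summary(g))[2, 3], tolerance = 1e-6)
})
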