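test_that("the toy score statistic matches direct matrix arithmetic", {
  y <- c(1, 0, 1, 0)
  G <- rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0))
  null <- fit_null_logistic(y)
  expect_equal(unname(null$fitted_means), rep(0.5, 4))
  expect_equal(skat_statistic(y, null, G, c(1, 1)), 1.0)
})

test_that("zero residuals and constant columns give a zero statistic", {
  y <- rep(c(1, 0), each = 10)
  null <- fit_null_logistic(y)
  # y == mu exactly is impossible with binary y, but constant columns make
  # G'(y - mu) proportional to the residual sum, which is zero
  G <- matrix(0.7, 20, 3)
  expect_equal(skat_statistic(y, null, G, rep(1, 3)), 0)
})

test_that("doubling the weights scales Q and the spectrum but not the p-value", {
  d <- toy_dataset(n = 100, p = 4, effect = 0.5, seed = 15)
  null <- fit_null_logistic(d$y)
  w1 <- rep(1, 4); w2 <- rep(2, 4)
  Q1 <- skat_statistic(d$y, null, d$G, w1)
  Q2 <- skat_statistic(d$y, null, d$G, w2)
  expect_equal(Q2, 4 * Q1, tolerance = 1e-10)
  l1 <- cpgset:::skat_null_eigenvalues(null, d$G, w1)
  l2 <- cpgset:::skat_null_eigenvalues(null, d$G, w2)
  expect_equal(l2, 4 * l1, tolerance = 1e-10)
  p1 <- skat_test(d$G, d$y, weights = w1)$p.value
  p2 <- skat_test(d$G, d$y, weights = w2)$p.value
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("a single CpG reduces SKAT to the squared logistic score test", {
  d <- toy_dataset(n = 120, p = 1, effect = 0.7, seed = 22)
  null <- fit_null_logistic(d$y)
  Q <- skat_statistic(d$y, null, d$G, 1)
  lam <- cpgset:::skat_null_eigenvalues(null, d$G, 1)
  expect_length(lam, 1)
  # Q / lambda is the squared standardized score statistic; the SKAT
  # p-value is its chi-square(1) tail
  g <- d$G[, 1]
  u <- sum(g * (d$y - mean(d$y)))
  v <- mean(d$y) * (1 - mean(d$y)) * sum((g - mean(g))^2)
  expect_equal(Q / lam, u^2 / v, tolerance = 1e-8)
  res <- skat_test(d$G, d$y)
  expect_equal(res$p.value, pchisq(u^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-4)
})

test_that("SKAT accepts covariates through the null design", {
  set.seed(33)
  n <- 150
  X <- cbind(rnorm(n))
  G <- matrix(rbeta(n * 3, 4, 4), n, 3)
  y <- rbinom(n, 1, plogis(0.5 * X[, 1]))
  res <- skat_test(G, y, X = X)
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  # the projected spectrum differs from the unadjusted one
  l_adj <- cpgset:::skat_null_eigenvalues(fit_null_logistic(y, X), G, rep(1, 3))
  l_raw <- cpgset:::skat_null_eigenvalues(fit_null_logistic(y), G, rep(1, 3))
  expect_false(isTRUE(all.equal(l_adj, l_raw)))
})

test_that("malformed inputs are rejected", {
  d <- toy_dataset(n = 30, p = 2)
  expect_error(skat_test(d$G, d$y, weights = c(1, -1)), "nonnegative")
  expect_error(skat_test(d$G * 2, d$y), "0, 1")
  expect_error(skat_test(d$G, rep(1, 30)), "single class")
})
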