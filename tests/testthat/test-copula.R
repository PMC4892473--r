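test_that("independence and comonotonicity map through the copula unchanged", {
  m <- same_marginals(3)
  sp0 <- calibrate_copula(m, exchangeable_correlation(3, 0))
  expect_equal(sp0$latent_correlation, diag(3))

  sp1 <- calibrate_copula(same_marginals(2), exchangeable_correlation(2, 1))
  expect_equal(sp1$latent_correlation[1, 2], 1)
})

test_that("calibrated copulas reproduce target correlations on resampling", {
  m <- same_marginals(3, mean = 0.6, precision = 10)
  sp <- calibrate_copula(m, exchangeable_correlation(3, 0.8))
  G <- sample_correlated_beta(sp, 1e5, seed = 7)
  r <- cor(G)[upper.tri(diag(3))]
  expect_true(all(r > 0.78 & r < 0.82))
})

test_that("the exchangeable correlation grid is tracked within 0.02", {
  m <- same_marginals(4, mean = 0.4)
  set.seed(11)
  for (r in c(0.2, 0.4, 0.6, 0.8)) {
    sp <- calibrate_copula(m, exchangeable_correlation(4, r))
    G <- sample_correlated_beta(sp, 1e5)
    obs <- cor(G)[upper.tri(diag(4))]
    expect_true(all(abs(obs - r) < 0.02),
                info = sprintf("r = %g: observed %s", r,
                               paste(round(obs, 3), collapse = ", ")))
  }
})

test_that("heterogeneous marginals calibrate pairwise", {
  m <- list(beta_marginal(0.2), beta_marginal(0.5), beta_marginal(0.8))
  sp <- calibrate_copula(m, exchangeable_correlation(3, 0.6))
  G <- sample_correlated_beta(sp, 1e5, seed = 3)
  obs <- cor(G)[upper.tri(diag(3))]
  expect_true(all(abs(obs - 0.6) < 0.02))
  # latent correlations must exceed the induced Pearson correlations for
  # these skewed non-identical marginals
  expect_true(all(sp$latent_correlation[upper.tri(diag(3))] >= 0.6))
})

test_that("unattainable targets raise a Fréchet-bound error naming the pair", {
  # two identically right-skewed marginals cannot reach correlation -0.98
  # (the antimonotone bound for a Beta(2, 8) pair is about -0.905)
  m <- list(beta_marginal(0.2, 10), beta_marginal(0.2, 10))
  R <- exchangeable_correlation(2, -0.98)
  expect_error(calibrate_copula(m, R), "Fréchet")
  # mirror-image marginals, by contrast, attain -1 exactly
  m2 <- list(beta_marginal(0.2, 10), beta_marginal(0.8, 10))
  sp <- calibrate_copula(m2, exchangeable_correlation(2, -0.999))
  expect_lt(sp$latent_correlation[1, 2], -0.99)
})

test_that("single-marginal sampling passes a goodness-of-fit check", {
  sp <- calibrate_copula(same_marginals(1, 0.3, 10), diag(1))
  x <- sample_correlated_beta(sp, 1e5, seed = 6)[, 1]
  ks <- suppressWarnings(ks.test(x, "pbeta", 3, 7))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(x > 0 & x < 1))
})

test_that("sampling is deterministic in the seed and restores the RNG state", {
  sp <- calibrate_copula(same_marginals(3), exchangeable_correlation(3, 0.4))
  set.seed(999); before <- runif(1)
  set.seed(999)
  G1 <- sample_correlated_beta(sp, 50, seed = 123)
  after <- runif(1)
  expect_identical(before, after)   # caller's stream untouched
  G2 <- sample_correlated_beta(sp, 50, seed = 123)
  expect_identical(G1, G2)
  G3 <- sample_correlated_beta(sp, 50, seed = 124)
  expect_false(identical(G1, G3))
})

test_that("indefinite pairwise solutions are PSD-repaired", {
  # force indefiniteness: three pairs with correlations that cannot jointly
  # hold (r12 = r13 = 0.9, r23 = -0.9)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9
  m <- same_marginals(3, 0.5, 10)
  sp <- calibrate_copula(m, R)
  expect_true(sp$repaired)
  ev <- eigen(sp$latent_correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= 0)
  expect_equal(unname(diag(sp$latent_correlation)), rep(1, 3))
})

test_that("malformed correlation targets are rejected", {
  m <- same_marginals(2)
  bad <- matrix(c(1, 0.5, 0.4, 1), 2)
  expect_error(calibrate_copula(m, bad), "symmetric")
  bad2 <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_error(calibrate_copula(m, bad2), "unit diagonal")
  expect_error(calibrate_copula(m, exchangeable_correlation(3, 0.2)), "dimension")
})
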