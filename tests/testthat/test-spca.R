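test_that("a strongly associated CpG is always at the top of the screen", {
  set.seed(41)
  n <- 80
  y <- rep(c(1, 0), each = n / 2)
  G <- matrix(rbeta(n * 5, 5, 5), n, 5)
  G[, 3] <- 0.25 + 0.5 * y + rnorm(n, 0, 0.01)   # near-separating CpG
  res <- spca_test(G, y, n_permutations = 99, seed = 1)
  expect_true(3 %in% res$detail$selected)
  ctx <- cpgset:::spca_context(G, y, NULL)
  u <- abs(drop(crossprod(ctx$Gn, y)))
  expect_equal(which.max(u), 3L)
})

test_that("the permutation p-value has the correct floor", {
  set.seed(52)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  G <- matrix(rbeta(n * 4, 5, 5), n, 4)
  G[, 1] <- pmin(G[, 1] + y * 0.25, 0.999)   # strong, non-separating signal
  res <- spca_test(G, y, n_permutations = 999, seed = 3)
  expect_equal(res$p.value, 1 / 1000)
})

test_that("the Wald statistic matches glm on the selected component", {
  d <- toy_dataset(n = 100, p = 5, effect = 0.6, seed = 7)
  res <- spca_test(d$G, d$y, n_permutations = 99, seed = 2)
  sel <- res$detail$selected
  Gc <- scale(d$G, scale = FALSE)
  s <- if (length(sel) == 1) Gc[, sel] else {
    drop(Gc[, sel] %*% eigen(crossprod(Gc[, sel]), symmetric = TRUE)$vectors[, 1])
  }
  g <- glm(d$y ~ s, family = binomial)
  expect_equal(abs(res$statistic), abs(coef(summary(g))[2, 3]), tolerance = 1e-6)
})

test_that("selection rules agree on which subset carries the signal", {
  d <- toy_dataset(n = 120, p = 6, effect = 0.9, seed = 19)
  r_score <- spca_test(d$G, d$y, n_permutations = 99, seed = 5, selection = "score")
  r_lrt <- spca_test(d$G, d$y, n_permutations = 99, seed = 5, selection = "lrt")
  expect_true(1 %in% r_score$detail$selected)
  expect_true(1 %in% r_lrt$detail$selected)
  r_cv <- spca_test(d$G, d$y, n_permutations = 99, seed = 5, selection = "cv")
  expect_true(r_cv$p.value >= 0 && r_cv$p.value <= 1)
})

test_that("the permutation null keeps the nominal level", {
  set.seed(61)
  n <- 60; p <- 4
  rej <- 0; reps <- 250
  for (i in seq_len(reps)) {
    G <- matrix(rbeta(n * p, 5, 5), n, p)
    y <- sample(rep(c(1L, 0L), each = n / 2))
    pv <- spca_test(G, y, n_permutations = 99)$p.value
    rej <- rej + (pv <= 0.05)
  }
  rate <- rej / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("the compiled permutation engine matches the interpreted procedure", {
  for (seed in c(3, 17, 91)) {
    d <- toy_dataset(n = 70, p = 5, effect = 0.4, seed = seed)
    ctx <- cpgset:::spca_context(d$G, d$y, NULL)
    sizes <- 1:5
    # observed statistic: same |T| from both implementations
    r_obs <- cpgset:::spca_single(ctx, d$y, sizes, "score")
    cpp_obs <- cpgset:::spca_perm_stats_cpp(ctx$Gc, ctx$Gn, ctx$CGG, sizes,
                                            matrix(d$y))
    expect_equal(abs(cpp_obs[1]), abs(r_obs$T), tolerance = 1e-8)
    # and for a batch of permuted label vectors
    set.seed(seed + 100)
    Y <- replicate(25, d$y[sample.int(70)])
    cppT <- cpgset:::spca_perm_stats_cpp(ctx$Gc, ctx$Gn, ctx$CGG, sizes, Y)
    rT <- apply(Y, 2, function(yb)
      cpgset:::spca_single(ctx, yb, sizes, "score")$T)
    expect_equal(abs(cppT), abs(rT), tolerance = 1e-8)
  }
})

test_that("input contracts are enforced", {
  d <- toy_dataset(n = 40, p = 3)
  expect_error(spca_test(d$G, d$y, n_permutations = 50), "at least 99")
  expect_error(spca_test(d$G, d$y, screen_fractions = c(0, 0.5)), "0, 1")
})
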