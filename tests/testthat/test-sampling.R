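test_that("case/control quotas are met exactly", {
  sc <- cpg_scenario("PTPRD", effect = 4, mean = 0.5)
  dat <- sample_case_control(sc, seed = 21)
  expect_equal(sum(dat$y == 1), 50)
  expect_equal(sum(dat$y == 0), 50)
  expect_equal(dim(dat$G), c(100, 6))
  expect_true(all(dat$G > 0 & dat$G < 1))
  expect_equal(colnames(dat$G)[1], "cg08719869")
})

test_that("sampling is reproducible from (scenario, seed)", {
  sc <- cpg_scenario("1.2", r = 0.4, effect = 0.7)
  d1 <- sample_case_control(sc, seed = 5)
  d2 <- sample_case_control(sc, seed = 5)
  expect_identical(d1$G, d2$G)
  expect_identical(d1$y, d2$y)
  d3 <- sample_case_control(sc, seed = 6)
  expect_false(identical(d1$G, d3$G))
})

test_that("under the null the phenotype is independent of methylation", {
  sc <- cpg_scenario("1.1", r = 0.2)
  dat <- sample_case_control(sc, seed = 77)
  r <- abs(cor(dat$y, dat$G))
  expect_true(all(r < 0.08))   # 3 s.e. band at n = 2000
})

test_that("per-CpG null t statistics are standard-normal-like across replications", {
  marg <- same_marginals(3, 0.5)
  sc <- scenario_spec(marg, exchangeable_correlation(3, 0.4),
                      n_cases = 100, n_controls = 100, label = "nullcheck")
  tstats <- matrix(NA_real_, 400, 3)
  for (t in seq_len(nrow(tstats))) {
    dat <- sample_case_control(sc, seed = 1000 + t)
    g1 <- dat$G[dat$y == 1, ]; g0 <- dat$G[dat$y == 0, ]
    sp <- (99 * apply(g1, 2, var) + 99 * apply(g0, 2, var)) / 198
    tstats[t, ] <- (colMeans(g1) - colMeans(g0)) / sqrt(sp * (2 / 100))
  }
  z <- as.vector(tstats)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(var(z) - 1), 0.15)
})

test_that("causal sampling shifts cases at the causal CpG only", {
  sc <- cpg_scenario("2.3", r = 0.2, effect = 1.0)  # causal CpG at position 5
  expect_equal(sc$disease$causal_indices, 5L)
  dat <- sample_case_control(sc, seed = 13)
  d <- colMeans(dat$G[dat$y == 1, ]) - colMeans(dat$G[dat$y == 0, ])
  expect_gt(d[5], max(abs(d[-5])) * 0.9)
  expect_gt(d[5], 0.01)
})

test_that("an unattainable quota reports the acceptance rate", {
  marg <- same_marginals(2, 0.5)
  dis <- disease_model(intercept = -40, causal_indices = 1, effects = 0.1)
  sc <- scenario_spec(marg, diag(2), dis, n_cases = 5, n_controls = 5,
                      label = "degenerate")
  expect_error(sample_case_control(sc, seed = 1, draw_budget = 10),
               "acceptance rate")
})

test_that("built-in scenario library matches the published design grid", {
  tab <- list_scenarios()
  expect_setequal(tab$label, c("1.1", "1.2", "1.3", "2.1", "2.2", "2.3",
                               "2.4", "2.5", "2.6", "2.7", "PTPRD", "MLH1"))
  expect_equal(tab$causal[tab$label == "1.3"], "1,2")
  expect_equal(tab$causal[tab$label == "2.6"], "1,10")
  expect_equal(tab$causal[tab$label == "2.7"], "5,10")
  expect_equal(tab$effect_grid[tab$label == "2.2"], "0.5/0.6/0.7/0.8/0.9/1.0")
  expect_equal(tab$effect_grid[tab$label == "1.3"], "0.1/0.2/0.3/0.4/0.5")
  expect_equal(tab$n_cases[tab$label == "PTPRD"], 50L)
  expect_equal(tab$n_cases[tab$label == "2.1"], 1000L)

  sc2 <- cpg_scenario("2.1", r = 0.2)
  means <- vapply(sc2$marginals, function(m) m$mean, 0)
  expect_equal(means, c(0.2, 0.2, 0.3, 0.4, 0.5, 0.5, 0.6, 0.7, 0.8, 0.8))

  # printed template correlation matrices: symmetric, unit diagonal, PSD
  for (lab in c("PTPRD", "MLH1")) {
    sc <- cpg_scenario(lab, mean = 0.5)
    R <- sc$correlation
    expect_equal(R, t(R))
    expect_equal(unname(diag(R)), rep(1, nrow(R)))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_equal(cpg_scenario("PTPRD", mean = 0.5)$correlation["cg08719869",
                                                             "cg14080967"],
               0.890)
  expect_equal(cpg_scenario("MLH1", mean = 0.5)$correlation[9, 5], 0.710)
})

test_that("scenario files round-trip through YAML and JSON", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c(
    "label: filetest",
    "marginals:",
    "  - {mean: 0.3, precision: 10}",
    "  - {mean: 0.6, precision: 10}",
    "correlation: {exchangeable: 0.5, p: 2}",
    "disease: {causal_indices: [1], effects: [0.8]}",
    "n_cases: 40",
    "n_controls: 60"), tmp)
  sc <- read_scenario(tmp)
  expect_equal(sc$label, "filetest")
  expect_equal(sc$n_cases, 40L)
  expect_equal(sc$correlation[1, 2], 0.5)
  expect_equal(sc$disease$effects, 0.8)

  tmpj <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    label = "jsontest",
    marginals = list(list(mean = 0.4, precision = 8),
                     list(mean = 0.5, precision = 8)),
    correlation = matrix(c(1, 0.3, 0.3, 1), 2),
    disease = list(),
    n_cases = 10, n_controls = 10), auto_unbox = TRUE), tmpj)
  scj <- read_scenario(tmpj)
  expect_equal(scj$marginals[[1]]$precision, 8)
  expect_equal(scj$correlation[2, 1], 0.3)
})
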