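# Distribution fitting, PSA sampling, CEAC.

test_that("moment fits reproduce the closed-form gamma and beta parameters", {
  g <- fit_distribution(pspec(100, 25, dist = "gamma"))
  expect_equal(g$shape, 16)         # (m/s)^2 under the 25% SD rule
  expect_equal(g$scale, 6.25)
  b <- fit_distribution(pspec(0.2, 0.05, dist = "beta"))
  k <- 0.2 * 0.8 / 0.05^2 - 1
  expect_equal(b$alpha, 0.2 * k)
  expect_equal(b$beta, 0.8 * k)
})

test_that("samplers recover their specified means within Monte-Carlo error", {
  set.seed(2024)
  n <- 50000
  specs <- list(
    pspec(100, 25, dist = "gamma"),
    pspec(-0.45, 0.1125, dist = "gamma"),       # negative mean, sign restored
    pspec(0.154, 0.025, dist = "beta"),
    pspec(1.6, range = c(1.2, 2.0), dist = "uniform_range")
  )
  for (spec in specs) {
    fd <- fit_distribution(spec)
    x <- fd$sample(n)
    se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - spec$mean), 3 * se)
    if (spec$dist == "gamma") expect_true(all(sign(x) == sign(spec$mean)))
    if (spec$dist == "beta") expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("infeasible beta moments fall back to a uniform on the range with a warning", {
  spec <- pspec(0.5, 0.6, range = c(0.3, 0.7), dist = "beta")
  expect_warning(fd <- fit_distribution(spec), "infeasible")
  x <- fd$sample(1000)
  expect_true(all(x >= 0.3 & x <= 0.7))
})

test_that("Dirichlet response draws live on the simplex and respect zero categories", {
  set.seed(7)
  r <- acr_response(0.62, 0.38, 0.07, sds = c(0.04, 0.04, 0.021))
  ess <- dirichlet_ess(r)
  expect_gt(ess, 1)
  p <- acr_cumulative_to_categories(r)
  draws <- raCEA:::rdirichlet(5000, p * ess)
  expect_equal(rowSums(draws), rep(1, 5000), tolerance = 1e-12)
  expect_true(all(draws >= 0))
  for (k in 1:4) {
    se <- sd(draws[, k]) / sqrt(5000)
    expect_lt(abs(mean(draws[, k]) - p[k]), 4 * se)
  }
  # fitted size reproduces the printed cumulative SDs to the right order
  sd20 <- sqrt(0.62 * 0.38 / (ess + 1))
  expect_lt(abs(sd20 - 0.04), 0.02)

  # a certain-response category stays degenerate under sampling
  r1 <- acr_response(1, 1, 1, sds = c(0.01, 0.01, 0.01))
  reg <- raCEA:::fit_registry(
    list(first_line = list(x = list(acr = r1))),
    list(list(id = "x", kind = "acr", path = c("first_line", "x", "acr"))))
  d <- reg[[1]]$sample(100)
  expect_true(all(d[, 4] == 1))
})

test_that("the PSA is reproducible, respects support, and collapses to the base case when degenerate", {
  cfg <- tiny_config(horizon_years = 5)
  p1 <- run_psa(cfg, n_iter = 15, seed = 11)
  p2 <- run_psa(cfg, n_iter = 15, seed = 11)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$qaly, p2$qaly)
  expect_identical(p1$params, p2$params)
  p3 <- run_psa(cfg, n_iter = 15, seed = 12)
  expect_false(identical(p1$cost, p3$cost))
  expect_error(run_psa(cfg, n_iter = 5), "seed")

  # sampled probabilities in [0,1], costs nonnegative
  pr <- p1$params[, grepl("discontinuation|ae_probs|cum", colnames(p1$params))]
  expect_true(all(pr >= 0 & pr <= 1))
  co <- p1$params[, grepl("cost", colnames(p1$params))]
  expect_true(all(co >= 0))

  # all-degenerate sampling reproduces the base case in every draw
  base <- run_model(cfg)
  p0 <- run_psa(cfg, n_iter = 4, seed = 5, sd_scale = 0)
  for (s in seq_along(cfg$strategies)) {
    expect_equal(unname(p0$cost[, s]), rep(base$results$cost[s], 4),
                 tolerance = 1e-9)
    expect_equal(unname(p0$qaly[, s]), rep(base$results$qaly[s], 4),
                 tolerance = 1e-9)
  }
})

test_that("PSA means converge to the base case as sampling SDs shrink", {
  cfg <- tiny_config(horizon_years = 10)
  base <- run_model(cfg)
  psa <- run_psa(cfg, n_iter = 60, seed = 3, sd_scale = 0.01)
  sm <- summary(psa)
  expect_equal(sm$mean_cost, base$results$cost, tolerance = 1e-3)
  expect_equal(sm$mean_qaly, base$results$qaly, tolerance = 1e-3)
})

test_that("CEAC probabilities partition, reward cheapness at WTP 0, and split ties", {
  mock <- structure(list(
    cost = cbind(a = c(100, 200, 300), b = c(150, 150, 250)),
    qaly = cbind(a = c(1, 1, 1), b = c(2, 2, 2)),
    strategies = c("a", "b")), class = "cea_psa")
  cc <- ceac(mock, wtp_grid = c(0, 1000))
  probs <- attr(cc, "probs")
  expect_equal(rowSums(probs), c(1, 1))
  # at WTP 0 the cheaper strategy wins each draw: a, b, b
  expect_equal(unname(probs[1, ]), c(1 / 3, 2 / 3))
  # at WTP 1000, b dominates on QALYs in every draw
  expect_equal(unname(probs[2, ]), c(0, 1))

  tie <- structure(list(
    cost = cbind(a = c(100, 100), b = c(100, 100)),
    qaly = cbind(a = c(1, 1), b = c(1, 1)),
    strategies = c("a", "b")), class = "cea_psa")
  pt <- attr(ceac(tie, wtp_grid = 48555), "probs")
  expect_equal(unname(pt[1, ]), c(0.5, 0.5))

  single <- structure(list(cost = cbind(a = c(1, 2)), qaly = cbind(a = c(1, 2)),
                           strategies = "a"), class = "cea_psa")
  ps <- attr(ceac(single, wtp_grid = c(0, 50000)), "probs")
  expect_true(all(ps == 1))

  expect_error(ceac(structure(list(cost = NULL, strategies = "a"),
                              class = "cea_psa")), "no successful")
})

test_that("at very high WTP the CEAC approaches the QALY-win fraction", {
  cfg <- tiny_config(horizon_years = 5)
  psa <- run_psa(cfg, n_iter = 40, seed = 21)
  cc <- attr(ceac(psa, wtp_grid = 1e9), "probs")
  qwin <- table(factor(psa$strategies[max.col(psa$qaly)],
                       levels = psa$strategies)) / nrow(psa$qaly)
  expect_equal(unname(cc[1, ]), as.numeric(qwin), tolerance = 1e-9)
})
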