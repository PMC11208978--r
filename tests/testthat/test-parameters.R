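# Parameter containers, ACR conversion, pooling, config I/O.

test_that("cumulative ACR rates convert to category probabilities by forced differences", {
  cases <- list(
    list(cum = c(0.734, 0.427, 0.202), cats = c(0.266, 0.307, 0.225, 0.202)),
    list(cum = c(1, 1, 1),             cats = c(0, 0, 0, 1)),
    list(cum = c(0.620, 0.380, 0.070), cats = c(0.380, 0.240, 0.310, 0.070))
  )
  for (cs in cases) {
    p <- acr_cumulative_to_categories(
      acr_response(cs$cum[1], cs$cum[2], cs$cum[3]))
    expect_equal(unname(p), cs$cats, tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("non-monotone cumulative rates are rejected", {
  expect_error(acr_response(0.4, 0.6, 0.1), "monotonicity")
  expect_error(acr_response(0.5, 0.4, 0.45), "monotonicity")
  expect_error(acr_response(1.2, 0.4, 0.1), "\\[0, 1\\]")
})

test_that("category conversion is a simplex map for any monotone triple", {
  set.seed(401)
  for (i in 1:100) {
    cum <- sort(runif(3), decreasing = TRUE)
    p <- acr_cumulative_to_categories(acr_response(cum[1], cum[2], cum[3]))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("market-share pooling takes weighted means and is identity on one-hot shares", {
  a <- list(drug_cost = pspec(100, 25, dist = "gamma"),
            discontinuation = pspec(0.2, 0.05, dist = "beta"))
  b <- list(drug_cost = pspec(300, 75, dist = "gamma"),
            discontinuation = pspec(0.4, 0.10, dist = "beta"))
  pooled <- pool_by_market_share(list(a, b), c(0.5, 0.5))
  expect_equal(pooled$drug_cost$mean, 200)
  expect_equal(pooled$discontinuation$mean, 0.3)
  expect_equal(pooled$drug_cost$sd, 50)  # 25% of pooled mean

  onehot <- pool_by_market_share(list(a, b), c(0, 1))
  expect_equal(onehot$drug_cost$mean, b$drug_cost$mean)
  expect_equal(onehot$discontinuation$mean, b$discontinuation$mean)
})

test_that("pooling renormalizes bad shares with a warning and rejects empty input", {
  a <- list(cost = pspec(110, dist = "gamma"))
  b <- list(cost = pspec(220, dist = "gamma"))
  expect_warning(pooled <- pool_by_market_share(list(a, b), c(0.6, 0.5)),
                 "renormalizing")
  expect_equal(pooled$cost$mean, 110 * 6 / 11 + 220 * 5 / 11)
  expect_error(pool_by_market_share(list(), numeric(0)), "empty")
  expect_error(pool_by_market_share(list(a), -1), "nonnegative")
})

test_that("the bundled fixture loads with exactly the three published strategies", {
  cfg <- base_case_config()
  expect_s3_class(cfg, "cea_config")
  expect_equal(cfg$strategies, c("leflunomide", "infliximab", "adalimumab"))
  expect_equal(vapply(cfg$first_line, function(d) d$label, character(1)),
               c(leflunomide = "Leflunomide",
                 infliximab = "Biosimilar infliximab",
                 adalimumab = "Biosimilar adalimumab"))
})

test_that("config serialization round-trips losslessly", {
  cfg <- fixture_base_case()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- load_config(path, quiet = TRUE)
  # identical model behaviour, not just similar numbers
  expect_equal(run_model(cfg2)$results, run_model(cfg)$results,
               tolerance = 1e-12)
  expect_equal(fixture_manifest(cfg2), fixture_manifest(cfg),
               tolerance = 1e-12)
})

test_that("invalid configs fail validation with named-field errors", {
  cfg <- fixture_base_case()
  bad <- cfg
  bad$first_line$leflunomide$discontinuation$mean <- 1.4
  expect_error(validate_config(bad), "leflunomide.discontinuation")
  bad <- cfg
  bad$ae_costs$pneumonia$mean <- -10
  expect_error(validate_config(bad), "ae_costs.pneumonia")
  bad <- cfg
  bad$settings$annual_discount_rate <- 1.5
  expect_error(validate_config(bad), "annual_discount_rate")

  # monotonicity violation caught at load time
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  txt <- readLines(path)
  txt <- sub("cum50: 0.38", "cum50: 0.7", txt)  # leflunomide: cum50 > cum20
  writeLines(txt, path)
  expect_error(load_config(path, quiet = TRUE), "monotonicity")
})

test_that("a missing SD defaults to 25% of the mean and is logged", {
  cfg <- fixture_base_case()
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg$ae_costs$pneumonia$sd <- NULL
  write_config(cfg, path)
  expect_message(cfg2 <- load_config(path), "25% of mean")
  expect_equal(cfg2$ae_costs$pneumonia$sd, 0.25 * 4983)
})
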