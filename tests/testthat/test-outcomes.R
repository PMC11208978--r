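# Utilities, discounting, accrual, ICERs, NMB, price reduction.

test_that("the linear HAQ-to-utility mapping reproduces its anchor points", {
  expect_equal(utility_from_haq(0), 0.74)
  expect_equal(utility_from_haq(1.6), 0.468)
  expect_equal(utility_from_haq(3), 0.23)
  expect_equal(utility_from_haq(1, list(intercept = 0.8, slope = -0.2)), 0.6)
})

test_that("discounting is annual at the configured rate on half-year cycles", {
  st <- list(annual_discount_rate = 0.035, cycle_length_years = 0.5)
  expect_equal(discount_factor(0, st), 1)
  expect_equal(discount_factor(2, st), 1 / 1.035)
  st0 <- list(annual_discount_rate = 0, cycle_length_years = 0.5)
  expect_equal(discount_factor(0:20, st0), rep(1, 21))
})

test_that("per-cycle accrual combines drug, adverse-event and nonpharma components", {
  cfg <- tiny_config()
  st <- build_strategy_states(cfg, "infliximab")$states
  entry <- st$line == 1 & st$phase == "entry"
  maint <- st$line == 1 & st$phase == "maint"
  expect_true(all(st$drug_cost[entry] == 2792))  # loading-dose cycle
  expect_true(all(st$drug_cost[maint] == 1654))

  # expected adverse-event cost is the sum of probability x episode cost
  probs <- vapply(cfg$first_line$infliximab$ae_probs, pval, numeric(1))
  costs <- vapply(cfg$ae_costs, pval, numeric(1))
  expect_equal(unique(st$ae_cost[st$line == 1]),
               sum(probs * costs[names(probs)]))
  # single-event contribution: pneumonia alone
  expect_equal(0.0074 * 4983, 36.8742)

  # a full-occupancy state at utility 0.468 accrues 0.234 QALYs undiscounted
  row <- data.frame(drug_cost = 0, ae_cost = 0, nonpharma_cost = 0,
                    utility = 0.468)
  inc <- accrue_cycle(1, row, disc = 1, settings = cfg$settings)
  expect_equal(inc$qaly, 0.234)
  expect_equal(inc$cost, 0)
})

test_that("ICERs report deltas, raw ratio and dominance, and are antisymmetric", {
  a <- list(label = "A", cost = 100, qaly = 2)
  b <- list(label = "B", cost = 150, qaly = 1.5)
  ic <- icer(a, b, list(wtp_threshold = 48555))
  expect_equal(ic$delta_cost, -50)
  expect_equal(ic$delta_qaly, 0.5)
  expect_equal(ic$icer, -100)
  expect_equal(ic$dominance, "dominant")
  rev <- icer(b, a, list(wtp_threshold = 48555))
  expect_equal(rev$delta_cost, -ic$delta_cost)
  expect_equal(rev$delta_qaly, -ic$delta_qaly)
  expect_equal(rev$dominance, "dominated")

  same <- icer(a, a, list(wtp_threshold = 48555))
  expect_true(same$icer_undefined)
  expect_true(is.na(same$icer))
  expect_equal(same$delta_cost, 0)
})

test_that("net monetary benefit is wtp x QALY minus cost and ranks the printed strategies", {
  res <- list(cost = 145419, qaly = 15.55)
  expect_equal(nmb(res, 0), -145419)
  expect_equal(nmb(res, 48555), 48555 * 15.55 - 145419)
  expect_equal(nmb(res, 48555), 609611.25)
  lef <- list(cost = 154632, qaly = 14.82)
  ifx <- list(cost = 152326, qaly = 15.35)
  ada <- list(cost = 145419, qaly = 15.55)
  expect_true(nmb(ada, 48555) > nmb(ifx, 48555))
  expect_true(nmb(ifx, 48555) > nmb(lef, 48555))
})

test_that("price reduction is the rounded percent saving vs the originator", {
  expect_equal(price_reduction(500, 500), 0)
  expect_equal(price_reduction(250, 1000), 75)
  expect_error(price_reduction(100, 0), "> 0")
})

test_that("lifetime totals decompose exactly and equal the per-cycle sums", {
  cfg <- tiny_config()
  tr <- run_cohort(cfg, "adalimumab")
  res <- strategy_result(tr)
  expect_equal(res$cost, res$cost_drug + res$cost_ae + res$cost_nonpharma,
               tolerance = 1e-12)
  expect_equal(res$cost, sum(tr$cost), tolerance = 1e-9)
  expect_equal(res$qaly, sum(tr$qaly), tolerance = 1e-9)
})

test_that("discounted totals decrease monotonically in the discount rate", {
  rates <- seq(0, 0.05, by = 0.01)
  cfg <- tiny_config()
  costs <- qalys <- numeric(length(rates))
  for (i in seq_along(rates)) {
    cfg$settings$annual_discount_rate <- rates[i]
    tr <- run_cohort(cfg, "leflunomide")
    costs[i] <- sum(tr$cost)
    qalys[i] <- sum(tr$qaly)
  }
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("with no mortality, no discounting and utility fixed at the intercept, QALYs are 0.74 T", {
  for (T in c(4, 10)) {
    cfg <- constant_utility_config(horizon_years = T)
    for (s in cfg$strategies) {
      tr <- run_cohort(cfg, s)
      expect_equal(sum(tr$qaly), 0.74 * T, tolerance = 1e-9)
    }
  }
})
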