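# Cohort engine: state expansion, transitions, conservation, oracle checks.

test_that("occupancy including dead is conserved at every cycle", {
  cfg <- tiny_config(horizon_years = 15)
  for (s in cfg$strategies) {
    tr <- run_cohort(cfg, s)
    sums <- rowSums(tr$occupancy)
    expect_true(all(abs(sums - 1) < 1e-10))
    expect_true(all(tr$occupancy >= -1e-15))
  }
})

test_that("zero mortality conserves the living cohort at 1 forever", {
  cfg <- zero_mortality_config(horizon_years = 20)
  cfg$settings$simplified_sequence <- TRUE
  tr <- run_cohort(cfg, "leflunomide")
  expect_true(all(abs(tr$survival - 1) < 1e-12))
})

test_that("the first cycle splits the cohort by ACR category and routes failures onward", {
  cfg <- zero_mortality_config()
  bs <- build_strategy_states(cfg, "leflunomide")
  entry <- bs$states$line == 1 & bs$states$phase == "entry"
  expect_equal(sum(bs$init[entry]), 1)
  expect_equal(bs$init[entry][1], 0.38)          # <ACR20 failures
  expect_equal(sum(bs$init[entry][2:4]), 0.62)   # responders remain

  # infliximab: 73.4% remain on treatment after the first cycle
  tr <- run_cohort(cfg, "infliximab")
  st <- build_strategy_states(cfg, "infliximab")$states
  expect_equal(sum(tr$occupancy[2, which(st$line == 1)]), 0.734)
})

test_that("first-cycle HAQ changes apply at entry and floor at zero", {
  cfg <- tiny_config()
  cfg$population$baseline_haq$mean <- 1.02
  st <- build_strategy_states(cfg, "leflunomide")$states
  ge70 <- st$line == 1 & st$phase == "entry" & st$stratum == 4
  expect_equal(st$haq[ge70], 0)  # 1.02 - 1.02, floored at 0
  expect_true(all(st$entry_haq[st$phase == "entry"] == 1.02))
})

test_that("maintenance transitions move the discontinuation fraction and rebound HAQ", {
  cfg <- tiny_config()
  bs <- build_strategy_states(cfg, "infliximab")
  st <- bs$states
  m2 <- which(st$line == 1 & st$phase == "maint" & st$stratum == 2)
  next_entry <- which(st$line == 2 & st$phase == "entry")
  expect_equal(bs$M[m2, next_entry], 0.154)
  expect_equal(bs$M[m2, m2], 0.846)
  # leflunomide: 36.5% move on per cycle
  bsl <- build_strategy_states(cfg, "leflunomide")
  stl <- bsl$states
  ml <- which(stl$line == 1 & stl$phase == "maint" & stl$stratum == 3)
  expect_equal(bsl$M[ml, which(stl$line == 2 & stl$phase == "entry")], 0.365)

  # rebound: every line is entered at the HAQ held at the abandoned line's
  # entry, which by induction is the baseline score
  expect_true(all(st$entry_haq == pval(cfg$population$baseline_haq)))

  # zero discontinuation is the identity on maintenance occupancy
  cfg0 <- tiny_config()
  cfg0$first_line$infliximab$discontinuation$mean <- 0
  bs0 <- build_strategy_states(cfg0, "infliximab")
  m <- which(bs0$states$line == 1 & bs0$states$phase == "maint" &
               bs0$states$stratum == 2)
  expect_equal(bs0$M[m, m], 1)
})

test_that("supportive-care HAQ trajectory follows -0.04, +0.2, then +0.28 with an absorbing ceiling", {
  expect_equal(supportive_haq_delta(1), -0.04)
  expect_equal(supportive_haq_delta(2), 0.2)
  expect_equal(supportive_haq_delta(c(3, 4, 10)), c(0.28, 0.28, 0.28))
  cfg <- tiny_config()
  st <- build_strategy_states(cfg, "leflunomide")$states
  sc <- st[st$phase %in% c("sc_tunnel", "sc_terminal"), ]
  h0 <- 1.6
  expect_equal(sc$haq[1], h0 - 0.04)
  expect_equal(sc$haq[2], h0 - 0.04 + 0.2)
  expect_equal(sc$haq[3], h0 - 0.04 + 0.2 + 0.28)
  expect_true(all(sc$haq <= 3))
  expect_equal(sc$haq[nrow(sc)], 3)  # ceiling reached and absorbing
  # clamping, not overshoot: 2.9 + 0.28 ends at exactly 3
  i29 <- which(abs(sc$haq - 2.88) < 1e-9)
  expect_equal(sc$haq[i29 + 1], 3)
})

test_that("certain failure and discontinuation drive the whole cohort to supportive care", {
  cfg <- zero_mortality_config()
  cfg$settings$simplified_sequence <- TRUE
  cfg$first_line$leflunomide$acr <- acr_response(0, 0, 0)  # all <ACR20
  cfg$first_line$leflunomide$discontinuation$mean <- 1
  tr <- run_cohort(cfg, "leflunomide")
  st <- tr$states
  sc_states <- which(st$phase %in% c("sc_tunnel", "sc_terminal"))
  expect_equal(sum(tr$occupancy[2, sc_states]), 1)  # everyone in SC by cycle 2
})

test_that("survival is non-increasing and worse disability lowers it pointwise", {
  cfg <- tiny_config(horizon_years = 20)
  tr <- run_cohort(cfg, "adalimumab")
  expect_true(all(diff(tr$survival) <= 1e-12))

  lo <- tiny_config(horizon_years = 20); lo$population$baseline_haq$mean <- 1.0
  hi <- tiny_config(horizon_years = 20); hi$population$baseline_haq$mean <- 2.0
  s_lo <- run_cohort(lo, "leflunomide")$survival
  s_hi <- run_cohort(hi, "leflunomide")$survival
  expect_true(all(s_hi <= s_lo + 1e-12))
})

test_that("the cohort engine matches the individual-level microsimulation oracle", {
  cfg <- random_small_config(7)
  tr <- run_cohort(cfg, "infliximab")
  ms <- microsimulate(cfg, "infliximab", n = 4e4, seed = 123)
  expect_lt(abs(sum(tr$cost) - ms$mean_cost), 3 * ms$se_cost)
  expect_lt(abs(sum(tr$qaly) - ms$mean_qaly), 3 * ms$se_qaly)
})

test_that("non-finite parameters trigger a hard engine failure", {
  cfg <- tiny_config()
  cfg$first_line$leflunomide$drug_cost$first$mean <- NaN
  expect_error(run_cohort(cfg, "leflunomide"))
})
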