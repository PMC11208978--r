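# Shared test configurations, built in code.

# Base-case fixture with a shortened horizon for fast tests.
tiny_config <- function(horizon_years = 10) {
  cfg <- raCEA::fixture_base_case()
  cfg$settings$horizon_years <- horizon_years
  cfg
}

# Life table with zero mortality at every age.
zero_mortality_lt <- function() {
  raCEA::generate_life_table(male = list(makeham = 0, level = 0, slope = 0),
                             female = list(makeham = 0, level = 0, slope = 0))
}

zero_mortality_config <- function(horizon_years = 10) {
  cfg <- tiny_config(horizon_years)
  cfg$life_table <- zero_mortality_lt()
  cfg
}

# Degenerate configuration whose utility is constant at the mapping
# intercept: zero mortality, zero discounting, baseline HAQ 0 and every
# HAQ change zero, so lifetime QALYs have the closed form intercept * T.
constant_utility_config <- function(horizon_years = 10) {
  cfg <- zero_mortality_config(horizon_years)
  cfg$settings$annual_discount_rate <- 0
  cfg$population$baseline_haq$mean <- 0
  for (nm in names(cfg$first_line_haq_change)) {
    cfg$first_line_haq_change[[nm]]$mean <- 0
  }
  for (ln in names(cfg$subsequent_lines)) {
    hc <- cfg$subsequent_lines[[ln]]$haq_change
    if (!is.null(hc$mean)) {
      cfg$subsequent_lines[[ln]]$haq_change$mean <- 0
    } else {
      cfg$subsequent_lines[[ln]]$haq_change$naive$mean <- 0
      cfg$subsequent_lines[[ln]]$haq_change$experienced$mean <- 0
    }
  }
  cfg$supportive_care$haq_deltas <- c(0, 0, 0)
  cfg
}

# Random small configuration for oracle comparisons: random monotone ACR
# triples, discontinuation and cost levels on a 10-year horizon.
random_small_config <- function(seed) {
  set.seed(seed)
  cfg <- tiny_config(horizon_years = 10)
  for (d in names(cfg$first_line)) {
    cum <- sort(stats::runif(3, 0.05, 0.95), decreasing = TRUE)
    cfg$first_line[[d]]$acr <- raCEA::acr_response(cum[1], cum[2], cum[3],
                                                   sds = rep(0.05, 3))
    cfg$first_line[[d]]$discontinuation$mean <- stats::runif(1, 0.05, 0.45)
    base_cost <- stats::runif(1, 100, 3000)
    cfg$first_line[[d]]$drug_cost$first$mean <- base_cost * stats::runif(1, 1, 1.8)
    cfg$first_line[[d]]$drug_cost$subsequent$mean <- base_cost
  }
  for (ln in names(cfg$subsequent_lines)) {
    cfg$subsequent_lines[[ln]]$discontinuation$mean <- stats::runif(1, 0.05, 0.45)
    cfg$subsequent_lines[[ln]]$drug_cost$mean <- stats::runif(1, 124, 1654)
  }
  cfg$population$baseline_haq$mean <- stats::runif(1, 1.2, 2.0)
  cfg
}
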