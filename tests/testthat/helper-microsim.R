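# Brute-force individual-level microsimulation oracle.
#
# Re-implements the treatment-sequence rules patient by patient, directly
# from the configuration fields and independently of the cohort engine's
# state-space expansion: each simulee carries (line, cycles-in-line, HAQ),
# deaths and switches are sampled, adverse events are sampled per cycle,
# and discounted cost/QALY are accumulated per patient. Engine totals are
# the expectations of these per-patient sums.

`%||%` <- function(a, b) if (is.null(a)) b else a

microsimulate <- function(config, strategy, n = 1e5, seed = 1) {
  set.seed(seed)
  pv <- raCEA::pval
  st <- config$settings
  pop <- config$population
  lt <- raCEA:::resolve_life_table(config)
  cl <- st$cycle_length_years
  disc_rate <- st$annual_discount_rate
  um <- st$utility_mapping
  baseline <- pv(pop$baseline_haq)
  hr <- pv(pop$mortality_hr_per_haq)
  ff <- pop$female_fraction
  age0 <- pop$baseline_age
  horizon <- if (is.null(st$horizon_years)) 100 - age0 else st$horizon_years
  n_cycles <- max(1L, round(min(horizon, 100 - age0) / cl))
  simplified <- isTRUE(st$simplified_sequence)

  fl <- config$first_line[[strategy]]
  cat_delta <- vapply(config$first_line_haq_change, pv, numeric(1))
  cat_p <- raCEA::acr_cumulative_to_categories(fl$acr)
  ae_cost_vec <- vapply(config$ae_costs, pv, numeric(1))

  line_list <- list(list(
    cost0 = pv(fl$drug_cost$first), cost1 = pv(fl$drug_cost$subsequent),
    disc = pv(fl$discontinuation), haq_delta = NA_real_,
    ae_p = vapply(names(fl$ae_probs), function(a) pv(fl$ae_probs[[a]]), numeric(1)),
    ae_c = ae_cost_vec[names(fl$ae_probs)]
  ))
  if (!simplified) {
    for (ln in names(config$subsequent_lines)) {
      l <- config$subsequent_lines[[ln]]
      hc <- l$haq_change
      d <- if (!is.null(hc$mean)) pv(hc)
           else if (isTRUE(fl$tnfi)) pv(hc$experienced) else pv(hc$naive)
      line_list[[length(line_list) + 1L]] <- list(
        cost0 = pv(l$drug_cost), cost1 = pv(l$drug_cost),
        disc = pv(l$discontinuation), haq_delta = d,
        ae_p = vapply(names(l$ae_probs %||% list()),
                      function(a) pv(l$ae_probs[[a]]), numeric(1)),
        ae_c = ae_cost_vec[names(l$ae_probs %||% list())]
      )
    }
  }
  K <- length(line_list)           # supportive care is line K + 1
  sc <- config$supportive_care
  sc_drug <- pv(sc$drug_cost_per_cycle)
  nonpharma_on <- !isFALSE(sc$include_nonpharma)
  sc_steroid <- if (nonpharma_on) pv(sc$steroid_injection_cost) else 0
  sc_physio <- if (nonpharma_on) pv(sc$physiotherapy_cost_per_cycle) else 0
  deltas <- sc$haq_deltas
  clamp <- function(h) pmin(pmax(h, 0), 3)
  next_haq <- function(k) {  # entry HAQ for line k (> 1) or SC (k = K + 1)
    if (k <= K) clamp(baseline + line_list[[k]]$haq_delta)
    else clamp(baseline + deltas[1])
  }

  line <- rep(1L, n)
  cil <- rep(0L, n)
  stratum <- sample.int(4L, n, replace = TRUE, prob = cat_p)
  haq <- clamp(baseline + cat_delta[stratum])
  alive <- rep(TRUE, n)
  cost <- numeric(n)
  qaly <- numeric(n)

  for (t in seq_len(n_cycles) - 1L) {
    if (!any(alive)) break
    age <- age0 + t * cl
    qb <- raCEA::cycle_death_prob(lt, age, ff, cl)
    die <- alive & (stats::runif(n) < pmin(qb * hr^haq, 1))
    alive[die] <- FALSE
    idx <- which(alive)
    if (!length(idx)) break
    disc <- (1 + disc_rate)^(-t * cl)

    # accrual at start-of-cycle HAQ
    cyc_cost <- numeric(length(idx))
    for (k in seq_len(K)) {
      on <- line[idx] == k
      if (!any(on)) next
      l <- line_list[[k]]
      cyc_cost[on] <- cyc_cost[on] + ifelse(cil[idx][on] == 0L, l$cost0, l$cost1)
      for (j in seq_along(l$ae_p)) {
        cyc_cost[on] <- cyc_cost[on] +
          stats::rbinom(sum(on), 1L, l$ae_p[j]) * l$ae_c[j]
      }
    }
    in_sc <- line[idx] == K + 1L
    if (any(in_sc)) {
      cyc_cost[in_sc] <- cyc_cost[in_sc] + sc_drug + sc_physio +
        ifelse(cil[idx][in_sc] < 2L, sc_steroid, 0)
    }
    cost[idx] <- cost[idx] + cyc_cost * disc
    qaly[idx] <- qaly[idx] + (um$intercept + um$slope * haq[idx]) * cl * disc

    # end-of-cycle transitions (from the pre-transition line)
    line_before <- line
    for (k in seq_len(K)) {
      on <- which(alive & line_before == k)
      if (!length(on)) next
      first_cycle <- cil[on] == 0L
      fail <- if (k == 1L) first_cycle & stratum[on] == 1L else rep(FALSE, length(on))
      quit <- !first_cycle & (stats::runif(length(on)) < line_list[[k]]$disc)
      move <- fail | quit
      mv <- on[move]
      if (length(mv)) {
        line[mv] <- k + 1L
        cil[mv] <- 0L
        haq[mv] <- next_haq(k + 1L)
      }
      keep <- on[!move]
      cil[keep] <- cil[keep] + 1L
    }
    adv <- which(alive & line_before == K + 1L)  # SC tunnel advance
    if (length(adv)) {
      cil[adv] <- cil[adv] + 1L
      haq[adv] <- clamp(haq[adv] + ifelse(cil[adv] == 1L, deltas[2], deltas[3]))
    }
  }
  list(cost = cost, qaly = qaly, alive = alive,
       mean_cost = mean(cost), mean_qaly = mean(qaly),
       se_cost = stats::sd(cost) / sqrt(n), se_qaly = stats::sd(qaly) / sqrt(n))
}
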