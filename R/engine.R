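# Cohort state-transition engine.
#
# The treatment sequence is expanded into a finite state table. Within a
# line the HAQ-DI score is constant, and on abandoning a line it rebounds to
# the score at that line's entry, so (by induction) every line is entered at
# the baseline HAQ-DI and the state space stays small:
#   first line:        4 entry states (one per ACR category, first cycle on
#                      the line) + 3 maintenance states (responders),
#   each later line:   1 entry + 1 maintenance state,
#   supportive care:   a tunnel tracking time-in-state until the HAQ-DI
#                      ceiling (3.0) is reached, then one absorbing state,
#   dead:              tracked as a separate accumulator.
# A line's first-cycle HAQ change is applied at line entry, so the entry
# state's HAQ (used for that cycle's mortality and accrual) already includes
# it; non-responders therefore carry their category change for the single
# cycle they spend on the line before rebounding.

clamp_haq <- function(h) pmin(pmax(h, 0), 3)

#' Supportive-care HAQ-DI increment
#'
#' Progressive deterioration under supportive care: a small initial
#' improvement in the first cycle, then worsening in every later cycle
#' (applied subject to the HAQ-DI ceiling of 3).
#'
#' @param cycle_in_sc 1-based cycle count within supportive care.
#' @param deltas the trajectory constants (first cycle, second cycle,
#'   every later cycle); base case `c(-0.04, 0.2, 0.28)`.
#' @return the HAQ-DI increment for that cycle (vectorized).
#' @export
supportive_haq_delta <- function(cycle_in_sc, deltas = c(-0.04, 0.2, 0.28)) {
  stopifnot(all(cycle_in_sc >= 1))
  ifelse(cycle_in_sc == 1, deltas[1],
         ifelse(cycle_in_sc == 2, deltas[2], deltas[3]))
}

# Assemble the ordered treatment lines for one strategy. Returns a list of
# line descriptors; the supportive-care terminal state is handled separately.
strategy_lines <- function(config, strategy) {
  fl <- config$first_line[[strategy]]
  if (is.null(fl)) stop("unknown strategy: ", strategy)
  simplified <- isTRUE(config$settings$simplified_sequence)
  lines <- list(list(
    name = strategy, label = fl$label %||% strategy, kind = "first",
    acr = fl$acr,
    haq_change = vapply(config$first_line_haq_change, pval, numeric(1)),
    discontinuation = pval(fl$discontinuation),
    drug_cost_first = pval(fl$drug_cost$first),
    drug_cost_subsequent = pval(fl$drug_cost$subsequent),
    ae_cost = ae_cycle_cost(fl$ae_probs, config$ae_costs)
  ))
  if (!simplified) {
    tnfi_experienced <- isTRUE(fl$tnfi)
    for (ln in names(config$subsequent_lines %||% list())) {
      l <- config$subsequent_lines[[ln]]
      hc <- l$haq_change
      h <- if (is_pspec(hc)) {
        pval(hc)
      } else if (tnfi_experienced) {
        pval(hc$experienced)
      } else {
        pval(hc$naive)
      }
      lines[[length(lines) + 1L]] <- list(
        name = ln, label = l$label %||% ln, kind = "subsequent",
        haq_change = h,
        discontinuation = pval(l$discontinuation),
        drug_cost_first = pval(l$drug_cost),
        drug_cost_subsequent = pval(l$drug_cost),
        ae_cost = ae_cycle_cost(l$ae_probs %||% list(), config$ae_costs)
      )
    }
  }
  lines
}

# Expected adverse-event cost per cycle: sum of per-cycle event probability
# times per-episode cost.
ae_cycle_cost <- function(ae_probs, ae_costs) {
  if (length(ae_probs) == 0L) return(0)
  sum(vapply(names(ae_probs), function(nm) {
    pval(ae_probs[[nm]]) * pval(ae_costs[[nm]])
  }, numeric(1)))
}

#' Build the expanded state space for one strategy
#'
#' Expands the treatment sequence into the state table, the static
#' end-of-cycle switch matrix, and the initial occupancy vector. Exposed
#' mainly for inspection and testing; [run_cohort()] calls it internally.
#'
#' @param config a `"cea_config"`.
#' @param strategy name of a first-line drug listed in `config$strategies`.
#' @return list with `states` (data frame: line, phase, stratum, tun, haq,
#'   entry_haq, drug_cost, ae_cost, nonpharma_cost, utility),
#'   `M` (row-stochastic end-of-cycle switch matrix over alive states) and
#'   `init` (initial occupancy).
#' @export
build_strategy_states <- function(config, strategy) {
  lines <- strategy_lines(config, strategy)
  sc <- config$supportive_care
  um <- config$settings$utility_mapping
  baseline <- pval(config$population$baseline_haq)
  nonpharma_on <- !isFALSE(sc$include_nonpharma)

  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- list(...)

  # treatment lines
  for (k in seq_along(lines)) {
    l <- lines[[k]]
    if (l$kind == "first") {
      for (s in 1:4) {
        add(line = k, phase = "entry", stratum = s, tun = 0L,
            haq = clamp_haq(baseline + l$haq_change[[s]]), entry_haq = baseline,
            drug_cost = l$drug_cost_first, ae_cost = l$ae_cost,
            nonpharma_cost = 0)
      }
      for (s in 2:4) {
        add(line = k, phase = "maint", stratum = s, tun = 1L,
            haq = clamp_haq(baseline + l$haq_change[[s]]), entry_haq = baseline,
            drug_cost = l$drug_cost_subsequent, ae_cost = l$ae_cost,
            nonpharma_cost = 0)
      }
    } else {
      add(line = k, phase = "entry", stratum = NA_integer_, tun = 0L,
          haq = clamp_haq(baseline + l$haq_change), entry_haq = baseline,
          drug_cost = l$drug_cost_first, ae_cost = l$ae_cost,
          nonpharma_cost = 0)
      add(line = k, phase = "maint", stratum = NA_integer_, tun = 1L,
          haq = clamp_haq(baseline + l$haq_change), entry_haq = baseline,
          drug_cost = l$drug_cost_subsequent, ae_cost = l$ae_cost,
          nonpharma_cost = 0)
    }
  }

  # supportive-care tunnel: advance until the HAQ ceiling is reached
  sc_line <- length(lines) + 1L
  deltas <- sc$haq_deltas
  h <- clamp_haq(baseline + supportive_haq_delta(1, deltas))
  t <- 0L
  sc_first <- length(rows) + 1L
  repeat {
    steroid <- if (nonpharma_on && t < 2L) pval(sc$steroid_injection_cost) else 0
    physio <- if (nonpharma_on) pval(sc$physiotherapy_cost_per_cycle) else 0
    add(line = sc_line, phase = if (h >= 3) "sc_terminal" else "sc_tunnel",
        stratum = NA_integer_, tun = t,
        haq = h, entry_haq = baseline,
        drug_cost = pval(sc$drug_cost_per_cycle), ae_cost = 0,
        nonpharma_cost = steroid + physio)
    if (h >= 3 && t >= 2L) break
    t <- t + 1L
    h <- clamp_haq(h + supportive_haq_delta(t + 1L, deltas))
    if (t > 60L) break  # guard against non-deteriorating trajectories
  }
  n_sc <- length(rows) - sc_first + 1L

  states <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  states$utility <- utility_from_haq(states$haq, um)
  n <- nrow(states)

  idx <- function(line, phase, stratum = NA_integer_, tun = NA_integer_) {
    hit <- states$line == line & states$phase == phase &
      (is.na(stratum) | (!is.na(states$stratum) & states$stratum == stratum)) &
      (is.na(tun) | states$tun == tun)
    which(hit)[1]
  }
  next_entry <- function(k) {
    if (k < length(lines)) idx(k + 1L, "entry") else sc_first
  }

  M <- matrix(0, n, n)
  for (k in seq_along(lines)) {
    l <- lines[[k]]
    if (l$kind == "first") {
      M[idx(k, "entry", 1L), next_entry(k)] <- 1
      for (s in 2:4) {
        M[idx(k, "entry", s), idx(k, "maint", s)] <- 1
        m <- idx(k, "maint", s)
        M[m, next_entry(k)] <- l$discontinuation
        M[m, m] <- 1 - l$discontinuation
      }
    } else {
      M[idx(k, "entry"), idx(k, "maint")] <- 1
      m <- idx(k, "maint")
      M[m, next_entry(k)] <- l$discontinuation
      M[m, m] <- 1 - l$discontinuation
    }
  }
  for (j in seq_len(n_sc)) {
    i <- sc_first + j - 1L
    M[i, min(i + 1L, sc_first + n_sc - 1L)] <- 1
  }

  stopifnot(all(abs(rowSums(M) - 1) < 1e-12))

  init <- numeric(n)
  p <- acr_cumulative_to_categories(lines[[1]]$acr)
  for (s in 1:4) init[idx(1L, "entry", s)] <- p[[s]]

  list(states = states, M = M, init = init,
       strategy = strategy, label = lines[[1]]$label)
}

#' Per-cycle cost and QALY accrual
#'
#' Given the surviving occupancy of each state, accrues that cycle's
#' discounted cost components (drug acquisition, expected adverse-event
#' cost, supportive-care nonpharmacological cost) and QALYs (state utility
#' times the cycle length in years).
#'
#' @param occ_surv occupancy of each alive state after that cycle's deaths.
#' @param states state table from [build_strategy_states()].
#' @param disc discount factor for the cycle.
#' @param settings the `settings` section of a config.
#' @param weight accrual weight (used for the optional half-cycle
#'   correction; 1 otherwise).
#' @return list with `cost_drug`, `cost_ae`, `cost_nonpharma`, `cost`,
#'   `qaly` (all discounted).
#' @export
accrue_cycle <- function(occ_surv, states, disc, settings, weight = 1) {
  cl <- settings$cycle_length_years
  cd <- sum(occ_surv * states$drug_cost) * disc * weight
  ca <- sum(occ_surv * states$ae_cost) * disc * weight
  cn <- sum(occ_surv * states$nonpharma_cost) * disc * weight
  q <- sum(occ_surv * states$utility) * cl * disc * weight
  if (cd < 0 || ca < 0 || cn < 0) stop("accrue_cycle: negative cost increment")
  list(cost_drug = cd, cost_ae = ca, cost_nonpharma = cn,
       cost = cd + ca + cn, qaly = q)
}

#' Propagate the cohort through one strategy
#'
#' Runs the deterministic cohort simulation: each cycle applies, in order,
#' (1) mortality at the state's current HAQ-DI (the general-population
#' per-cycle probability from the life table times `hr^HAQ`), (2) cost and
#' QALY accrual for survivors at the start-of-cycle HAQ, and (3) the
#' end-of-cycle switch transitions (ACR-based routing in the first cycle of
#' the first line, discontinuation afterwards, supportive-care tunnel
#' advance). The cohort ages half a year per cycle and the run stops at the
#' horizon or age 100, whichever is first.
#'
#' @param config a `"cea_config"`.
#' @param strategy a first-line drug named in `config$strategies`.
#' @param life_table optional pre-resolved `"life_table"` (resolved from the
#'   config otherwise).
#' @return A `"cohort_trace"`: per-cycle occupancy (including dead), cost
#'   and QALY increments (discounted), cohort age, survival, and mean
#'   HAQ-DI among survivors.
#' @export
run_cohort <- function(config, strategy, life_table = NULL) {
  lt <- life_table %||% resolve_life_table(config)
  st <- config$settings
  pop <- config$population
  bs <- build_strategy_states(config, strategy)
  states <- bs$states
  M <- bs$M
  n <- nrow(states)

  age0 <- pop$baseline_age
  cl <- st$cycle_length_years
  horizon <- st$horizon_years %||% (100 - age0)
  n_cycles <- max(1L, round(min(horizon, 100 - age0) / cl))
  hr <- pval(pop$mortality_hr_per_haq)
  ff <- pop$female_fraction
  hcc <- isTRUE(st$half_cycle_correction)

  o <- bs$init
  dead <- 0
  occ <- matrix(0, n_cycles, n + 1L)
  cost_drug <- cost_ae <- cost_nonpharma <- qaly <- disc_f <-
    survival <- mean_haq <- numeric(n_cycles)

  for (t in seq_len(n_cycles)) {
    age <- age0 + (t - 1L) * cl
    qb <- cycle_death_prob(lt, age, ff, cl)
    q <- adjusted_mortality(qb, states$haq, hr)
    d <- o * q
    dead <- dead + sum(d)
    os <- o - d
    if (any(!is.finite(os))) stop("run_cohort: non-finite occupancy at cycle ", t)

    w <- if (hcc && (t == 1L || t == n_cycles)) 0.5 else 1
    disc <- discount_factor(t - 1L, st)
    inc <- accrue_cycle(os, states, disc, st, weight = w)

    occ[t, ] <- c(os, dead)
    cost_drug[t] <- inc$cost_drug
    cost_ae[t] <- inc$cost_ae
    cost_nonpharma[t] <- inc$cost_nonpharma
    qaly[t] <- inc$qaly
    disc_f[t] <- disc
    survival[t] <- sum(os)
    mean_haq[t] <- if (sum(os) > 0) sum(os * states$haq) / sum(os) else NA_real_

    if (abs(sum(os) + dead - 1) > 1e-10) {
      stop("run_cohort: occupancy not conserved at cycle ", t)
    }
    o <- as.vector(crossprod(M, os))
  }

  structure(list(
    strategy = strategy, label = bs$label, states = states,
    n_cycles = n_cycles, age = age0 + (seq_len(n_cycles) - 1L) * cl,
    occupancy = occ, discount = disc_f,
    cost_drug = cost_drug, cost_ae = cost_ae, cost_nonpharma = cost_nonpharma,
    cost = cost_drug + cost_ae + cost_nonpharma, qaly = qaly,
    survival = survival, mean_haq = mean_haq,
    settings = st
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace: %s, %d cycles (age %.1f-%.1f)\n",
              x$label, x$n_cycles, x$age[1], x$age[x$n_cycles] + 0.5))
  cat(sprintf("  discounted cost %.0f, QALY %.3f, final survival %.3f\n",
              sum(x$cost), sum(x$qaly), x$survival[x$n_cycles]))
  invisible(x)
}

#' Export a cohort trace as a long data frame
#'
#' One row per cycle and state (plus the dead accumulator), suitable for
#' CSV export.
#' @param trace a `"cohort_trace"`.
#' @return data frame with cycle, age, state descriptors and occupancy.
#' @export
trace_to_df <- function(trace) {
  s <- trace$states
  n <- nrow(s)
  state_lab <- c(sprintf("L%d_%s%s", s$line, s$phase,
                         ifelse(is.na(s$stratum), paste0("_t", s$tun),
                                paste0("_s", s$stratum))), "dead")
  do.call(rbind, lapply(seq_len(trace$n_cycles), function(t) {
    data.frame(cycle = t - 1L, age = trace$age[t], state = state_lab,
               line = c(s$line, NA), haq = c(s$haq, NA),
               occupancy = trace$occupancy[t, ])
  }))
}
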