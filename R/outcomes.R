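# Lifetime outcomes: utilities, discounting, ICERs, dominance, NMB.

#' Map a HAQ-DI score to utility
#'
#' Linear mapping `utility = intercept + slope * HAQ-DI` (base case
#' 0.74 - 0.17 x HAQ-DI), so full function (HAQ 0) is worth 0.74 and the
#' worst disability (HAQ 3) 0.23.
#'
#' @param haq HAQ-DI score(s) in `[0, 3]`.
#' @param mapping list with `intercept` and `slope` (a utility mapping from
#'   the config settings).
#' @return utility value(s).
#' @export
utility_from_haq <- function(haq, mapping = list(intercept = 0.74, slope = -0.17)) {
  mapping$intercept + mapping$slope * haq
}

#' Per-cycle discount factor
#'
#' `(1 + annual_rate)^(-cycle_index * cycle_length_years)`; cycle 0 is
#' undiscounted.
#'
#' @param cycle_index 0-based cycle index (vectorized).
#' @param settings config `settings` (uses `annual_discount_rate` and
#'   `cycle_length_years`).
#' @return discount factor(s).
#' @export
discount_factor <- function(cycle_index, settings) {
  (1 + settings$annual_discount_rate)^(-cycle_index * settings$cycle_length_years)
}

#' Summarize a cohort trace into lifetime totals
#'
#' @param trace a `"cohort_trace"` from [run_cohort()].
#' @return A `"strategy_result"`: label, total discounted cost and QALYs,
#'   and the cost decomposition (drug, adverse-event, nonpharmacological).
#' @export
strategy_result <- function(trace) {
  structure(list(
    strategy = trace$strategy, label = trace$label,
    cost = sum(trace$cost), qaly = sum(trace$qaly),
    cost_drug = sum(trace$cost_drug), cost_ae = sum(trace$cost_ae),
    cost_nonpharma = sum(trace$cost_nonpharma),
    life_years = sum(trace$survival) * trace$settings$cycle_length_years
  ), class = "strategy_result")
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' Computes deltas (comparator minus reference), the ICER, a dominance
#' classification, and whether the comparator is cost-effective at the
#' willingness-to-pay threshold by net-monetary-benefit comparison. The raw
#' (possibly negative) ratio is reported even under dominance, alongside the
#' dominance label.
#'
#' @param a comparator: a `"strategy_result"` or list with `cost` and `qaly`.
#' @param b reference: same form.
#' @param settings config `settings` (uses `wtp_threshold`).
#' @return An `"icer_result"` with `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` and flagged undefined when `|delta_qaly| < 1e-12`), `dominance`
#'   (`"dominant"`, `"dominated"` or `"trade-off"`), and
#'   `cost_effective_at_wtp`.
#' @export
icer <- function(a, b, settings = list(wtp_threshold = 48555)) {
  dc <- a$cost - b$cost
  dq <- a$qaly - b$qaly
  undefined <- abs(dq) < 1e-12
  ratio <- if (undefined) NA_real_ else dc / dq
  dominance <- if (dc < 0 && dq > 0) {
    "dominant"
  } else if (dc > 0 && dq < 0) {
    "dominated"
  } else {
    "trade-off"
  }
  wtp <- settings$wtp_threshold
  ce <- nmb(a, wtp) >= nmb(b, wtp)
  structure(list(
    comparator = a$label %||% "A", reference = b$label %||% "B",
    delta_cost = dc, delta_qaly = dq, icer = ratio,
    icer_undefined = undefined, dominance = dominance,
    cost_effective_at_wtp = ce, wtp = wtp
  ), class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost %.0f, dQALY %.2f, ICER %s (%s)%s\n",
              x$comparator, x$reference, x$delta_cost, x$delta_qaly,
              if (x$icer_undefined) "undefined" else sprintf("%.0f", x$icer),
              x$dominance,
              if (x$cost_effective_at_wtp) sprintf(", cost-effective at WTP %.0f", x$wtp) else ""))
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * QALY - cost`: positive increments favour the strategy at the
#' given willingness-to-pay.
#'
#' @param result a `"strategy_result"` or list with `cost` and `qaly`.
#' @param wtp willingness-to-pay per QALY (>= 0).
#' @return net monetary benefit in the cost currency.
#' @export
nmb <- function(result, wtp) {
  stopifnot(wtp >= 0)
  wtp * result$qaly - result$cost
}

#' Biosimilar price reduction
#'
#' Percent reduction of a biosimilar's acquisition cost relative to the
#' originator, rounded to a whole percent.
#'
#' @param biosimilar_cost,originator_cost per-cycle acquisition costs;
#'   `originator_cost` must be positive.
#' @return integer percent reduction.
#' @examples
#' price_reduction(940, 7073)   # 87
#' price_reduction(1654, 3609)  # 54
#' @export
price_reduction <- function(biosimilar_cost, originator_cost) {
  if (originator_cost <= 0) stop("price_reduction: originator cost must be > 0")
  round(100 * (1 - biosimilar_cost / originator_cost))
}

#' Run the base-case model
#'
#' Evaluates every strategy in the configuration through the cohort engine
#' and assembles lifetime discounted costs and QALYs plus incremental
#' comparisons against the reference strategy (the first one listed).
#'
#' @param config a `"cea_config"` (see [base_case_config()],
#'   [load_config()]).
#' @param keep_traces keep the per-cycle traces in the returned object.
#' @return A `"cea"` object: `results` (one row per strategy: cost, qaly and
#'   cost components), `comparisons` (one row per non-reference strategy:
#'   deltas, ICER, dominance), `icers` (list of `"icer_result"`), and
#'   optionally `traces`.
#' @export
run_model <- function(config, keep_traces = FALSE) {
  config <- validate_config(config)
  lt <- resolve_life_table(config)
  traces <- lapply(config$strategies, function(s) run_cohort(config, s, lt))
  names(traces) <- config$strategies
  res <- lapply(traces, strategy_result)

  results <- do.call(rbind, lapply(res, function(r) {
    data.frame(strategy = r$strategy, label = r$label, cost = r$cost,
               qaly = r$qaly, cost_drug = r$cost_drug, cost_ae = r$cost_ae,
               cost_nonpharma = r$cost_nonpharma, life_years = r$life_years,
               stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL

  ref <- config$strategies[1]
  ics <- lapply(config$strategies[-1], function(s) icer(res[[s]], res[[ref]], config$settings))
  names(ics) <- config$strategies[-1]
  comparisons <- do.call(rbind, lapply(ics, function(ic) {
    data.frame(comparator = ic$comparator, reference = ic$reference,
               delta_cost = ic$delta_cost, delta_qaly = ic$delta_qaly,
               icer = ic$icer, dominance = ic$dominance,
               cost_effective_at_wtp = ic$cost_effective_at_wtp,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(comparisons)) rownames(comparisons) <- NULL

  structure(list(
    results = results, comparisons = comparisons, icers = ics,
    reference = ref, settings = config$settings,
    traces = if (keep_traces) traces else NULL,
    config = config
  ), class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat("Cost-effectiveness model:", nrow(x$results), "strategies, reference =",
      x$results$label[x$results$strategy == x$reference], "\n\n")
  print(summary(x))
  invisible(x)
}

#' Base-case results table
#'
#' Formats net and incremental costs/QALYs and ICERs at reporting precision
#' (costs to whole dollars, QALYs to 2 decimals, ICERs to whole
#' dollars/QALY).
#'
#' @param object a `"cea"`.
#' @param ... unused.
#' @return data frame, one row per strategy.
#' @export
summary.cea <- function(object, ...) {
  r <- object$results
  ref <- object$reference
  inc_cost <- inc_qaly <- icer_c <- character(nrow(r))
  for (i in seq_len(nrow(r))) {
    if (r$strategy[i] == ref) {
      inc_cost[i] <- inc_qaly[i] <- icer_c[i] <- "Reference"
    } else {
      ic <- object$icers[[r$strategy[i]]]
      inc_cost[i] <- format(round(ic$delta_cost), big.mark = " ")
      inc_qaly[i] <- sprintf("%.2f", ic$delta_qaly)
      icer_c[i] <- if (ic$icer_undefined) "undefined" else
        format(round(ic$icer), big.mark = " ")
    }
  }
  data.frame(
    strategy = r$label,
    cost = round(r$cost), incremental_cost = inc_cost,
    qaly = round(r$qaly, 2), incremental_qaly = inc_qaly,
    icer = icer_c, stringsAsFactors = FALSE
  )
}
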