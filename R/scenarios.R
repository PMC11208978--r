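# Scenario analysis: structural and setting overrides on a base config.

#' Define a scenario
#'
#' A scenario is a labelled set of overrides on the base configuration.
#' Only the declared override fields may be touched; anything else is a
#' named error.
#'
#' @param label scenario label.
#' @param utility_mapping alternative HAQ-to-utility mapping: a list with
#'   `intercept`/`slope` (and optionally `label`), or the index of one of
#'   the config's bundled alternative mappings.
#' @param horizon_years model duration override in years.
#' @param discount annual discount rate override.
#' @param baseline_age cohort starting age override.
#' @param simplified if `TRUE`, first-line failures move directly to
#'   supportive care (no later-line biologics).
#' @param include_nonpharma if `FALSE`, supportive-care nonpharmacological
#'   costs (steroid injections, physiotherapy) are removed.
#' @return A `"scenario_spec"`.
#' @export
scenario_spec <- function(label, utility_mapping = NULL, horizon_years = NULL,
                          discount = NULL, baseline_age = NULL,
                          simplified = NULL, include_nonpharma = NULL) {
  structure(list(label = label, utility_mapping = utility_mapping,
                 horizon_years = horizon_years, discount = discount,
                 baseline_age = baseline_age, simplified = simplified,
                 include_nonpharma = include_nonpharma),
            class = "scenario_spec")
}

apply_scenario <- function(config, spec) {
  extra <- setdiff(names(spec), c("label", "utility_mapping", "horizon_years",
                                  "discount", "baseline_age", "simplified",
                                  "include_nonpharma"))
  if (length(extra)) {
    stop("scenario '", spec$label, "': undeclared override(s): ",
         paste(extra, collapse = ", "))
  }
  if (!is.null(spec$utility_mapping)) {
    um <- spec$utility_mapping
    if (is.numeric(um) && length(um) == 1L) {
      alts <- config$settings$alt_utility_mappings
      if (um < 1 || um > length(alts)) {
        stop("scenario '", spec$label, "': utility_mapping index out of range")
      }
      um <- alts[[um]]
    }
    config$settings$utility_mapping <- um
  }
  if (!is.null(spec$horizon_years)) config$settings$horizon_years <- spec$horizon_years
  if (!is.null(spec$discount)) config$settings$annual_discount_rate <- spec$discount
  if (!is.null(spec$baseline_age)) config$population$baseline_age <- spec$baseline_age
  if (!is.null(spec$simplified)) config$settings$simplified_sequence <- spec$simplified
  if (!is.null(spec$include_nonpharma)) {
    config$supportive_care$include_nonpharma <- spec$include_nonpharma
  }
  validate_config(config)
}

#' The published scenario grid
#'
#' Base case plus: the two bundled alternative HAQ-to-utility mappings,
#' model durations of 5-40 years, discount rates of 0% and 5%, cohort
#' starting ages of 51 and 61, the simplified sequence (first line followed
#' directly by supportive care), and removal of supportive-care
#' nonpharmacological costs.
#'
#' @param config a `"cea_config"` (used only to count bundled alternative
#'   mappings).
#' @return list of [scenario_spec()]s, base case first.
#' @export
published_scenarios <- function(config) {
  specs <- list(scenario_spec("base_case"))
  for (i in seq_along(config$settings$alt_utility_mappings %||% list())) {
    specs[[length(specs) + 1L]] <-
      scenario_spec(paste0("utility_mapping_alt_", i), utility_mapping = i)
  }
  for (h in c(5, 10, 20, 30, 40)) {
    specs[[length(specs) + 1L]] <-
      scenario_spec(paste0("horizon_", h, "y"), horizon_years = h)
  }
  for (r in c(0, 0.05)) {
    specs[[length(specs) + 1L]] <-
      scenario_spec(paste0("discount_", r * 100, "pct"), discount = r)
  }
  for (a in c(51, 61)) {
    specs[[length(specs) + 1L]] <-
      scenario_spec(paste0("age_", a), baseline_age = a)
  }
  specs[[length(specs) + 1L]] <- scenario_spec("simplified_sequence",
                                               simplified = TRUE)
  specs[[length(specs) + 1L]] <- scenario_spec("no_nonpharma_costs",
                                               include_nonpharma = FALSE)
  specs
}

#' Run a scenario grid
#'
#' Evaluates the full model under each scenario's overrides. An invalid
#' override fails that scenario with a named error message; the remaining
#' scenarios still run.
#'
#' @param config the base `"cea_config"`.
#' @param specs list of [scenario_spec()]s; defaults to
#'   [published_scenarios()].
#' @return A `"cea_scenarios"` object with `results` (scenario x strategy
#'   net cost/QALY), `comparisons` (scenario x pair deltas and ICER) and
#'   `errors` (named character vector of failed scenarios).
#' @export
run_scenarios <- function(config, specs = published_scenarios(config)) {
  config <- validate_config(config)
  res_rows <- list()
  cmp_rows <- list()
  errors <- character(0)
  for (spec in specs) {
    fit <- tryCatch(run_model(apply_scenario(config, spec)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      errors[spec$label] <- conditionMessage(fit)
      next
    }
    r <- fit$results
    r <- cbind(scenario = spec$label, r)
    res_rows[[spec$label]] <- r
    if (!is.null(fit$comparisons)) {
      cmp_rows[[spec$label]] <- cbind(scenario = spec$label, fit$comparisons)
    }
  }
  structure(list(
    results = do.call(rbind, c(res_rows, list(make.row.names = FALSE))),
    comparisons = do.call(rbind, c(cmp_rows, list(make.row.names = FALSE))),
    errors = errors
  ), class = "cea_scenarios")
}

#' @export
print.cea_scenarios <- function(x, ...) {
  cat("Scenario grid:", length(unique(x$results$scenario)), "scenarios run")
  if (length(x$errors)) cat(",", length(x$errors), "failed")
  cat("\n")
  print(x$comparisons[, c("scenario", "comparator", "reference",
                          "delta_cost", "delta_qaly", "icer", "dominance")],
        digits = 4)
  invisible(x)
}
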