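# Parameter containers, validation, and config I/O.
#
# A model configuration is one nested list (class "cea_config") holding
# strategies, shared parameter tables, economic settings, the population
# profile and a life-table specification. Every uncertain scalar is stored
# as a "pspec" (point value + sampling description) so the base-case engine,
# the PSA sampler and the tornado DSA all read from a single source.

#' Describe one uncertain parameter
#'
#' Bundles the base-case value of a parameter with the information needed to
#' sample it (distribution family, SD, plausible range) and a provenance tag
#' distinguishing published values from synthetic stand-ins.
#'
#' @param mean base-case (point) value.
#' @param sd standard deviation; when `NULL` it is later defaulted to
#'   25% of the absolute mean (the convention used for all costs and
#'   HAQ changes without a reported SD).
#' @param range length-2 numeric giving a low/high range used by the
#'   deterministic sensitivity analysis; optional.
#' @param dist sampling family: `"beta"` (probabilities), `"gamma"`
#'   (costs and HAQ-change magnitudes), `"uniform_range"`, or `"fixed"`.
#' @param provenance `"paper"` for published values, `"synthetic"` for
#'   generated stand-ins.
#' @return An object of class `"pspec"`.
#' @export
pspec <- function(mean, sd = NULL, range = NULL, dist = "gamma",
                  provenance = "paper") {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (!is.null(range)) {
    range <- as.numeric(range)
    if (length(range) != 2L || any(!is.finite(range)) || range[1] > range[2]) {
      stop("pspec: 'range' must be a finite length-2 numeric with low <= high")
    }
  }
  if (!dist %in% c("beta", "gamma", "dirichlet", "uniform_range", "fixed")) {
    stop("pspec: unknown distribution family '", dist, "'")
  }
  structure(list(mean = mean, sd = sd, range = range, dist = dist,
                 provenance = provenance),
            class = "pspec")
}

#' Point value of a parameter
#'
#' Extracts the base-case value from a [pspec()] (or passes a bare numeric
#' through unchanged).
#' @param x a `pspec` or numeric scalar.
#' @return numeric scalar.
#' @export
pval <- function(x) {
  if (inherits(x, "pspec") || (is.list(x) && !is.null(x$mean))) x$mean else x
}

is_pspec <- function(x) inherits(x, "pspec") || (is.list(x) && !is.null(x$mean) && !is.null(x$dist))

#' Cumulative ACR response triple
#'
#' First-cycle efficacy of a first-line drug as the cumulative fractions of
#' patients achieving at least ACR20, ACR50 and ACR70.
#'
#' @param cum20,cum50,cum70 cumulative response proportions in `[0, 1]`,
#'   with `cum20 >= cum50 >= cum70`.
#' @param sds per-component standard deviations (same order), used to fit
#'   the Dirichlet sampling distribution.
#' @param provenance provenance tag.
#' @return An object of class `"acr_response"`.
#' @export
acr_response <- function(cum20, cum50, cum70, sds = NULL, provenance = "paper") {
  v <- c(cum20 = cum20, cum50 = cum50, cum70 = cum70)
  if (any(v < 0) || any(v > 1)) {
    stop("acr_response: cumulative rates must lie in [0, 1]")
  }
  if (!(cum20 >= cum50 && cum50 >= cum70)) {
    stop("acr_response: cumulative monotonicity violated (need cum20 >= cum50 >= cum70)")
  }
  if (!is.null(sds)) {
    sds <- as.numeric(sds)
    if (length(sds) != 3L || any(sds < 0)) {
      stop("acr_response: 'sds' must be 3 nonnegative values")
    }
  }
  structure(list(cum20 = cum20, cum50 = cum50, cum70 = cum70, sds = sds,
                 provenance = provenance),
            class = "acr_response")
}

#' Convert cumulative ACR rates to response-category probabilities
#'
#' The model's canonical internal representation splits the cohort into four
#' mutually exclusive response categories: below ACR20 (treatment failure),
#' ACR20-50, ACR50-70, and at or above ACR70. Published trials report the
#' cumulative triple; the categories are its forced differences.
#'
#' @param r an [acr_response()].
#' @return Named numeric vector `c(p_lt20, p_20_50, p_50_70, p_ge70)`
#'   summing to 1.
#' @examples
#' acr_cumulative_to_categories(acr_response(0.734, 0.427, 0.202))
#' @export
acr_cumulative_to_categories <- function(r) {
  if (!inherits(r, "acr_response")) {
    r <- acr_response(r[[1]], r[[2]], r[[3]])
  }
  p <- c(p_lt20  = 1 - r$cum20,
         p_20_50 = r$cum20 - r$cum50,
         p_50_70 = r$cum50 - r$cum70,
         p_ge70  = r$cum70)
  stopifnot(abs(sum(p) - 1) < 1e-12, all(p >= 0))
  p
}

#' Pool treatment-line parameters by market share
#'
#' Collapses several drugs of the same class into one pooled pseudo-drug,
#' taking share-weighted means of every numeric parameter (costs,
#' discontinuation, adverse-event probabilities, HAQ changes). Sampling
#' descriptions propagate the weighted mean with the 25%-of-mean SD rule;
#' ranges are rebuilt as mean +/- 1.96 SD.
#'
#' @param drug_params non-empty list of same-structured parameter lists
#'   (numeric and [pspec()] leaves).
#' @param shares nonnegative market-share weights, one per drug; renormalized
#'   with a warning if they do not sum to 1 (tolerance 1e-9).
#' @return A pooled parameter list with the structure of the inputs.
#' @export
pool_by_market_share <- function(drug_params, shares) {
  if (length(drug_params) == 0L) stop("pool_by_market_share: empty drug list")
  shares <- as.numeric(shares)
  if (length(shares) != length(drug_params)) {
    stop("pool_by_market_share: one share per drug required")
  }
  if (any(shares < 0)) stop("pool_by_market_share: shares must be nonnegative")
  s <- sum(shares)
  if (s <= 0) stop("pool_by_market_share: shares sum to zero")
  if (abs(s - 1) > 1e-9) {
    warning(sprintf("market shares sum to %.6g; renormalizing", s))
    shares <- shares / s
  }
  pool_rec(drug_params, shares)
}

pool_rec <- function(items, w) {
  x1 <- items[[1]]
  if (is_pspec(x1)) {
    m <- sum(w * vapply(items, function(x) x$mean, numeric(1)))
    prov <- unique(vapply(items, function(x) x$provenance %||% "synthetic",
                          character(1)))
    sdp <- 0.25 * abs(m)
    rng <- if (m != 0) sort(c(m - 1.96 * sdp, m + 1.96 * sdp)) else NULL
    pspec(m, sd = sdp, range = rng, dist = x1$dist,
          provenance = if (length(prov) == 1L) prov else "synthetic")
  } else if (is.numeric(x1)) {
    Reduce(`+`, Map(function(x, wi) wi * x, items, w))
  } else if (is.list(x1)) {
    out <- lapply(seq_along(x1), function(i) {
      pool_rec(lapply(items, `[[`, i), w)
    })
    names(out) <- names(x1)
    out
  } else {
    x1  # labels/flags: keep the first drug's value
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ae_names <- c("pneumonia", "herpes_zoster", "tuberculosis", "hepatitis_b")
acr_cat_names <- c("lt20", "acr20_50", "acr50_70", "ge70")

# ---- validation --------------------------------------------------------

check_prob <- function(x, what) {
  v <- pval(x)
  if (!is.finite(v) || v < 0 || v > 1) {
    stop(sprintf("config field '%s': probability %g outside [0, 1]", what, v))
  }
  invisible(v)
}

check_cost <- function(x, what) {
  v <- pval(x)
  if (!is.finite(v) || v < 0) {
    stop(sprintf("config field '%s': cost %g must be >= 0", what, v))
  }
  invisible(v)
}

check_haq_change <- function(x, what) {
  v <- pval(x)
  if (!is.finite(v) || v < -3 || v > 3) {
    stop(sprintf("config field '%s': HAQ change %g outside [-3, 3]", what, v))
  }
  invisible(v)
}

# Apply the 25%-of-mean default SD to every pspec missing one; messages each
# defaulted field so the run log records applied defaults.
apply_sd_defaults <- function(x, path = character(), quiet = FALSE) {
  if (is_pspec(x)) {
    if (is.null(x$sd) && !x$dist %in% c("fixed", "uniform_range")) {
      x$sd <- 0.25 * abs(x$mean)
      if (!quiet) {
        message(sprintf("SD for '%s' not given; defaulting to 25%% of mean (%g)",
                        paste(path, collapse = "."), x$sd))
      }
    }
    class(x) <- "pspec"
    x
  } else if (is.list(x)) {
    for (nm in names(x)) x[[nm]] <- apply_sd_defaults(x[[nm]], c(path, nm), quiet)
    x
  } else {
    x
  }
}

#' Validate a model configuration
#'
#' Checks probabilities against `[0, 1]`, costs against nonnegativity, HAQ
#' changes against `[-3, 3]`, cumulative ACR monotonicity, and structural
#' completeness (strategy references, supportive care terminal). Errors name
#' the offending field.
#'
#' @param config a configuration list (see [load_config()]).
#' @return The configuration, invisibly, with class `"cea_config"`.
#' @export
validate_config <- function(config) {
  req <- c("settings", "population", "ae_costs", "first_line",
           "first_line_haq_change", "supportive_care", "life_table",
           "strategies")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config: missing section(s): ", paste(miss, collapse = ", "))

  st <- config$settings
  if (st$annual_discount_rate < 0 || st$annual_discount_rate > 1) {
    stop("config field 'settings.annual_discount_rate': must lie in [0, 1]")
  }
  if (st$cycle_length_years <= 0) stop("config field 'settings.cycle_length_years': must be > 0")
  if (!is.null(st$horizon_years) && st$horizon_years <= 0) {
    stop("config field 'settings.horizon_years': must be > 0")
  }
  um <- st$utility_mapping
  if (!all(c("intercept", "slope") %in% names(um))) {
    stop("config field 'settings.utility_mapping': needs intercept and slope")
  }

  pop <- config$population
  check_prob(pop$female_fraction, "population.female_fraction")
  bh <- pval(pop$baseline_haq)
  if (bh < 0 || bh > 3) stop("config field 'population.baseline_haq': outside [0, 3]")
  if (pop$baseline_age < 0 || pop$baseline_age >= 100) {
    stop("config field 'population.baseline_age': must lie in [0, 100)")
  }
  if (pval(pop$mortality_hr_per_haq) < 0) {
    stop("config field 'population.mortality_hr_per_haq': must be >= 0")
  }

  for (nm in names(config$ae_costs)) {
    check_cost(config$ae_costs[[nm]], paste0("ae_costs.", nm))
  }
  for (nm in names(config$first_line_haq_change)) {
    check_haq_change(config$first_line_haq_change[[nm]],
                     paste0("first_line_haq_change.", nm))
  }

  for (dn in names(config$first_line)) {
    d <- config$first_line[[dn]]
    a <- d$acr
    if (!inherits(a, "acr_response")) {
      a <- acr_response(a$cum20, a$cum50, a$cum70, a$sds,
                        a$provenance %||% "paper")
      config$first_line[[dn]]$acr <- a
    }
    check_prob(d$discontinuation, paste0("first_line.", dn, ".discontinuation"))
    check_cost(d$drug_cost$first, paste0("first_line.", dn, ".drug_cost.first"))
    check_cost(d$drug_cost$subsequent, paste0("first_line.", dn, ".drug_cost.subsequent"))
    for (ae in names(d$ae_probs)) {
      check_prob(d$ae_probs[[ae]], paste0("first_line.", dn, ".ae_probs.", ae))
    }
  }

  for (ln in names(config$subsequent_lines %||% list())) {
    l <- config$subsequent_lines[[ln]]
    check_prob(l$discontinuation, paste0("subsequent_lines.", ln, ".discontinuation"))
    check_cost(l$drug_cost, paste0("subsequent_lines.", ln, ".drug_cost"))
    hc <- l$haq_change
    if (is_pspec(hc)) {
      check_haq_change(hc, paste0("subsequent_lines.", ln, ".haq_change"))
    } else {
      for (g in names(hc)) {
        check_haq_change(hc[[g]], paste0("subsequent_lines.", ln, ".haq_change.", g))
      }
    }
    for (ae in names(l$ae_probs %||% list())) {
      check_prob(l$ae_probs[[ae]], paste0("subsequent_lines.", ln, ".ae_probs.", ae))
    }
  }

  sc <- config$supportive_care
  check_cost(sc$drug_cost_per_cycle, "supportive_care.drug_cost_per_cycle")
  check_cost(sc$steroid_injection_cost, "supportive_care.steroid_injection_cost")
  check_cost(sc$physiotherapy_cost_per_cycle, "supportive_care.physiotherapy_cost_per_cycle")
  if (length(sc$haq_deltas) != 3L) {
    stop("config field 'supportive_care.haq_deltas': need 3 values (cycle 1, cycle 2, later)")
  }

  bad <- setdiff(config$strategies, names(config$first_line))
  if (length(bad)) {
    stop("config field 'strategies': unknown first-line drug(s): ",
         paste(bad, collapse = ", "))
  }

  class(config) <- "cea_config"
  invisible(config)
}

# ---- serialization -----------------------------------------------------

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attr(x, "class") <- NULL
  }
  x
}

restore_classes <- function(config) {
  config <- rapply(config, f = identity, how = "replace")
  tag <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, tag)
      if (!is.null(x$mean) && !is.null(x$dist)) class(x) <- "pspec"
      if (!is.null(x$cum20) && !is.null(x$cum50)) {
        x <- acr_response(x$cum20, x$cum50, x$cum70,
                          if (length(x$sds)) unlist(x$sds) else NULL,
                          x$provenance %||% "paper")
      }
    }
    x
  }
  tag(config)
}

#' Load and validate a model configuration
#'
#' Reads a YAML (or JSON) configuration document defining strategies,
#' population, economic settings and sampling distributions, applies the
#' 25%-of-mean default SD rule to any uncertain parameter lacking an SD
#' (logging each application), and validates every field.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @param quiet suppress messages about applied defaults.
#' @return A validated object of class `"cea_config"`.
#' @seealso [base_case_config()] for the bundled base-case fixture,
#'   [write_config()] for the inverse.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config <- restore_classes(raw)
  config <- apply_sd_defaults(config, quiet = quiet)
  validate_config(config)
}

#' Write a model configuration to YAML
#'
#' Serializes a configuration so that [load_config()] round-trips it
#' losslessly.
#'
#' @param config a `"cea_config"`.
#' @param path output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(strip_classes(unclass(config)), path,
                   precision = 15L)
  invisible(path)
}
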