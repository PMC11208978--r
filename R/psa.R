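# Probabilistic sensitivity analysis: distribution fitting, the sampling
# registry, the Monte-Carlo loop, and the acceptability curve.

#' Fit a sampling distribution to a parameter description
#'
#' Method-of-moments fits: beta via `alpha = m * ((m (1 - m) / s^2) - 1)`
#' (and `beta` scaled accordingly), gamma via `shape = (m / s)^2`,
#' `scale = s^2 / m`. Negative-mean quantities (HAQ changes) are sampled as
#' gamma on the magnitude with the sign restored. When beta moments are
#' infeasible (`s^2 >= m (1 - m)`) the sampler falls back to a uniform on
#' the parameter's range with a warning. A zero SD (or family `"fixed"`)
#' gives a degenerate sampler.
#'
#' @param spec a [pspec()].
#' @return list with `family`, `mean`, `sd`, and `sample(n)`, plus fitted
#'   `shape`/`scale` (gamma) or `alpha`/`beta` (beta) where applicable.
#' @examples
#' fit_distribution(pspec(100, 25, dist = "gamma"))$shape  # 16
#' @export
fit_distribution <- function(spec) {
  m <- spec$mean
  s <- spec$sd %||% (0.25 * abs(m))
  fam <- spec$dist
  out <- list(family = fam, mean = m, sd = s)
  if (fam == "fixed" || s == 0 || m == 0 && fam != "uniform_range") {
    out$family <- "fixed"
    out$sample <- function(n) rep(m, n)
    return(out)
  }
  if (fam == "beta") {
    if (m < 0 || m > 1) stop("fit_distribution: beta mean outside [0, 1]")
    if (s^2 >= m * (1 - m)) {
      rng <- spec$range %||% c(max(0, m - 1.96 * s), min(1, m + 1.96 * s))
      warning(sprintf(
        "beta moments infeasible for mean %g, sd %g; using uniform on [%g, %g]",
        m, s, rng[1], rng[2]))
      out$family <- "uniform_range"
      out$sample <- function(n) stats::runif(n, rng[1], rng[2])
      return(out)
    }
    k <- m * (1 - m) / s^2 - 1
    out$alpha <- m * k
    out$beta <- (1 - m) * k
    out$sample <- function(n) stats::rbeta(n, out$alpha, out$beta)
    return(out)
  }
  if (fam == "gamma") {
    am <- abs(m)
    out$shape <- (am / s)^2
    out$scale <- s^2 / am
    sgn <- sign(m)
    out$sample <- function(n) sgn * stats::rgamma(n, shape = out$shape, scale = out$scale)
    return(out)
  }
  if (fam == "uniform_range") {
    rng <- spec$range
    if (is.null(rng)) stop("fit_distribution: uniform_range needs a range")
    out$sample <- function(n) stats::runif(n, rng[1], rng[2])
    return(out)
  }
  stop("fit_distribution: unsupported family '", fam, "'")
}

#' Fit a Dirichlet effective sample size to printed cumulative SDs
#'
#' Under a Dirichlet with category means `p` and effective sample size `N`,
#' any partial sum of categories is Beta-distributed with SD
#' `sqrt(m (1 - m) / (N + 1))`. The single `N` minimizing the squared error
#' to the printed per-component (cumulative) SDs is fitted.
#'
#' @param r an [acr_response()] with `sds`.
#' @return fitted effective sample size (a large value when no SDs exist).
#' @export
dirichlet_ess <- function(r) {
  if (is.null(r$sds) || all(r$sds == 0)) return(1e8)
  m <- c(r$cum20, r$cum50, r$cum70)
  v <- m * (1 - m)
  sds <- r$sds
  obj <- function(logN) {
    N <- exp(logN)
    sum((sds - sqrt(v / (N + 1)))^2)
  }
  opt <- stats::optimize(obj, interval = log(c(1, 1e7)))
  exp(opt$minimum)
}

# Dirichlet draws by gamma normalization.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

# ---- sampling registry -------------------------------------------------
#
# Every uncertain parameter is one registry entry carrying the path to its
# pspec node in the config. Parameters printed once (category HAQ changes,
# AE episode costs, baseline HAQ, later-line tables) are shared: a single
# draw applies to every strategy.

scalar_entry <- function(id, path, mirror = list()) {
  list(id = id, kind = "scalar", path = path, mirror = mirror)
}

#' Registry of uncertain parameters
#'
#' Enumerates every sampled parameter of a configuration: scalar entries
#' (costs, probabilities, HAQ changes) pointing at their [pspec()] nodes,
#' and one Dirichlet entry per first-line drug for the ACR response split.
#'
#' @param config a `"cea_config"`.
#' @return list of registry entries (each with `id`, `kind`, `path`).
#' @export
psa_parameters <- function(config) {
  reg <- list()
  add <- function(e) reg[[length(reg) + 1L]] <<- e
  node <- function(path) config[[path]]

  add(scalar_entry("population.baseline_haq", c("population", "baseline_haq")))
  for (nm in names(config$ae_costs)) {
    add(scalar_entry(paste0("ae_costs.", nm), c("ae_costs", nm)))
  }
  for (nm in names(config$first_line_haq_change)) {
    add(scalar_entry(paste0("haq_change_first_cycle.", nm),
                     c("first_line_haq_change", nm)))
  }
  for (d in names(config$first_line)) {
    fl <- config$first_line[[d]]
    add(list(id = paste0("first_line.", d, ".acr"), kind = "acr",
             path = c("first_line", d, "acr")))
    add(scalar_entry(paste0("first_line.", d, ".discontinuation"),
                     c("first_line", d, "discontinuation")))
    if (identical(pval(fl$drug_cost$first), pval(fl$drug_cost$subsequent))) {
      add(scalar_entry(paste0("first_line.", d, ".drug_cost"),
                       c("first_line", d, "drug_cost", "first"),
                       mirror = list(c("first_line", d, "drug_cost", "subsequent"))))
    } else {
      add(scalar_entry(paste0("first_line.", d, ".drug_cost.first"),
                       c("first_line", d, "drug_cost", "first")))
      add(scalar_entry(paste0("first_line.", d, ".drug_cost.subsequent"),
                       c("first_line", d, "drug_cost", "subsequent")))
    }
    for (ae in names(fl$ae_probs)) {
      p <- fl$ae_probs[[ae]]
      if (pval(p) > 0 && p$dist != "fixed") {
        add(scalar_entry(paste0("first_line.", d, ".ae_probs.", ae),
                         c("first_line", d, "ae_probs", ae)))
      }
    }
  }
  for (ln in names(config$subsequent_lines %||% list())) {
    l <- config$subsequent_lines[[ln]]
    add(scalar_entry(paste0("subsequent_lines.", ln, ".drug_cost"),
                     c("subsequent_lines", ln, "drug_cost")))
    add(scalar_entry(paste0("subsequent_lines.", ln, ".discontinuation"),
                     c("subsequent_lines", ln, "discontinuation")))
    if (is_pspec(l$haq_change)) {
      add(scalar_entry(paste0("subsequent_lines.", ln, ".haq_change"),
                       c("subsequent_lines", ln, "haq_change")))
    } else {
      for (g in names(l$haq_change)) {
        add(scalar_entry(paste0("subsequent_lines.", ln, ".haq_change.", g),
                         c("subsequent_lines", ln, "haq_change", g)))
      }
    }
    for (ae in names(l$ae_probs %||% list())) {
      if (pval(l$ae_probs[[ae]]) > 0) {
        add(scalar_entry(paste0("subsequent_lines.", ln, ".ae_probs.", ae),
                         c("subsequent_lines", ln, "ae_probs", ae)))
      }
    }
  }
  for (nm in c("drug_cost_per_cycle", "steroid_injection_cost",
               "physiotherapy_cost_per_cycle")) {
    add(scalar_entry(paste0("supportive_care.", nm), c("supportive_care", nm)))
  }
  reg
}

# Pre-fit all samplers once; sd_scale multiplies every SD (Dirichlet: the
# effective sample size is divided by sd_scale^2).
fit_registry <- function(config, reg, sd_scale = 1) {
  lapply(reg, function(e) {
    if (e$kind == "scalar") {
      spec <- config[[e$path]]
      if (spec$dist == "uniform_range") {
        m <- spec$mean
        half <- max(spec$range[2] - m, m - spec$range[1]) * sd_scale
        e$sample <- function(n) stats::runif(n, m - half, m + half)
      } else {
        spec2 <- spec
        spec2$sd <- (spec$sd %||% (0.25 * abs(spec$mean))) * sd_scale
        fd <- fit_distribution(spec2)
        e$sample <- fd$sample
      }
    } else {  # acr
      r <- config[[e$path]]
      p <- acr_cumulative_to_categories(r)
      ess <- dirichlet_ess(r) / max(sd_scale^2, 1e-12)
      if (sd_scale == 0 || !is.finite(ess)) {
        e$sample <- function(n) matrix(rep(p, each = n), n, 4L)
      } else {
        alpha <- p * ess
        # zero-probability categories stay at zero (degenerate component)
        pos <- alpha > 0
        e$sample <- function(n) {
          out <- matrix(0, n, 4L)
          out[, pos] <- rdirichlet(n, alpha[pos])
          out
        }
      }
    }
    e
  })
}

# One joint draw: returns the modified config and a named vector of sampled
# values (categories flattened for ACR entries).
sample_config <- function(config, fitted_reg) {
  vals <- list()
  for (e in fitted_reg) {
    if (e$kind == "scalar") {
      v <- e$sample(1L)
      config[[c(e$path, "mean")]] <- v
      for (mp in e$mirror) config[[c(mp, "mean")]] <- v
      vals[[e$id]] <- v
    } else {
      p <- as.vector(e$sample(1L))
      r <- config[[e$path]]
      r$cum20 <- p[2] + p[3] + p[4]
      r$cum50 <- p[3] + p[4]
      r$cum70 <- p[4]
      config[[e$path]] <- r
      vals[[paste0(e$id, ".cum20")]] <- r$cum20
      vals[[paste0(e$id, ".cum50")]] <- r$cum50
      vals[[paste0(e$id, ".cum70")]] <- r$cum70
    }
  }
  list(config = config, values = unlist(vals))
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter jointly and independently from its
#' fitted distribution, evaluates all strategies on the same draw through
#' the cohort engine, and repeats for `n_iter` iterations. Reproducible:
#' iteration i uses a substream seed derived from `seed` and i, so results
#' do not depend on execution order. Iterations producing non-finite
#' results are recorded as failed, excluded, and warned about.
#'
#' @param config a `"cea_config"`.
#' @param n_iter number of Monte-Carlo iterations (>= 1).
#' @param seed integer seed; mandatory, never auto-generated.
#' @param sd_scale multiplier applied to every sampling SD (0 collapses all
#'   distributions to the base case); default 1.
#' @return A `"cea_psa"`: `draws` (data frame iteration x strategy with
#'   cost and qaly), `params` (matrix of sampled parameter values),
#'   `n_failed`, `seed`, and the base-case `cea` fit.
#' @export
run_psa <- function(config, n_iter = 1000, seed, sd_scale = 1) {
  if (missing(seed) || is.null(seed)) {
    stop("run_psa: an explicit seed is required")
  }
  stopifnot(n_iter >= 1)
  config <- validate_config(config)
  lt <- resolve_life_table(config)
  reg <- psa_parameters(config)
  fitted <- fit_registry(config, reg, sd_scale)
  strategies <- config$strategies
  S <- length(strategies)

  cost <- qaly <- matrix(NA_real_, n_iter, S, dimnames = list(NULL, strategies))
  params <- NULL
  failed <- integer(0)
  sub_seeds <- (as.numeric(seed) + seq_len(n_iter) * 1000003) %% 2147483647

  for (i in seq_len(n_iter)) {
    set.seed(sub_seeds[i])
    draw <- sample_config(config, fitted)
    if (is.null(params)) {
      params <- matrix(NA_real_, n_iter, length(draw$values),
                       dimnames = list(NULL, names(draw$values)))
    }
    params[i, ] <- draw$values
    ok <- TRUE
    for (s in seq_len(S)) {
      r <- tryCatch({
        tr <- run_cohort(draw$config, strategies[s], lt)
        c(sum(tr$cost), sum(tr$qaly))
      }, error = function(e) c(NA_real_, NA_real_))
      if (any(!is.finite(r))) { ok <- FALSE; break }
      cost[i, s] <- r[1]
      qaly[i, s] <- r[2]
    }
    if (!ok) failed <- c(failed, i)
  }
  if (length(failed)) {
    warning(length(failed), " PSA iteration(s) failed and were excluded")
    cost <- cost[-failed, , drop = FALSE]
    qaly <- qaly[-failed, , drop = FALSE]
    params <- params[-failed, , drop = FALSE]
  }
  kept <- setdiff(seq_len(n_iter), failed)
  draws <- data.frame(
    iteration = rep(kept, times = S),
    strategy = rep(strategies, each = length(kept)),
    cost = as.vector(cost), qaly = as.vector(qaly),
    stringsAsFactors = FALSE
  )
  structure(list(
    draws = draws, cost = cost, qaly = qaly, params = params,
    strategies = strategies, n_iter = n_iter, n_failed = length(failed),
    seed = seed, sd_scale = sd_scale, settings = config$settings
  ), class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (%d failed), %d strategies, seed %s\n",
              x$n_iter, x$n_failed, length(x$strategies), format(x$seed)))
  print(summary(x))
  invisible(x)
}

#' Mean PSA costs and QALYs per strategy
#' @param object a `"cea_psa"`.
#' @param ... unused.
#' @return data frame of Monte-Carlo means.
#' @export
summary.cea_psa <- function(object, ...) {
  data.frame(strategy = object$strategies,
             mean_cost = colMeans(object$cost),
             mean_qaly = colMeans(object$qaly),
             row.names = NULL)
}

#' Cost-effectiveness plane scatter
#' @param x a `"cea_psa"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cea_psa <- function(x, ...) {
  cols <- seq_along(x$strategies) + 1L
  graphics::plot(range(x$qaly), range(x$cost), type = "n",
                 xlab = "QALYs", ylab = "Cost (US$)",
                 main = "Cost-effectiveness plane", ...)
  for (s in seq_along(x$strategies)) {
    graphics::points(x$qaly[, s], x$cost[, s], col = cols[s], pch = 16,
                     cex = 0.4)
  }
  graphics::legend("topleft", legend = x$strategies, col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that a strategy is
#' cost-effective is the fraction of PSA draws in which it attains the
#' strictly highest net monetary benefit; exact ties share the credit
#' equally, so probabilities sum to one at every grid point.
#'
#' @param psa a `"cea_psa"` with at least one successful draw.
#' @param wtp_grid willingness-to-pay grid (default US$0 to 80,000 in
#'   1,000 steps).
#' @return A `"cea_ceac"` data frame with columns `wtp`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 80000, by = 1000)) {
  n <- nrow(psa$cost)
  if (is.null(n) || n == 0) stop("ceac: no successful PSA draws")
  S <- length(psa$strategies)
  probs <- matrix(0, length(wtp_grid), S,
                  dimnames = list(NULL, psa$strategies))
  for (w in seq_along(wtp_grid)) {
    nmb <- wtp_grid[w] * psa$qaly - psa$cost
    best <- nmb == matrixStats_rowMaxs(nmb)
    credit <- best / rowSums(best)
    probs[w, ] <- colMeans(credit)
  }
  out <- data.frame(
    wtp = rep(wtp_grid, times = S),
    strategy = rep(psa$strategies, each = length(wtp_grid)),
    probability = as.vector(probs),
    stringsAsFactors = FALSE
  )
  structure(out, probs = probs, wtp_grid = wtp_grid,
            class = c("cea_ceac", "data.frame"))
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' @export
plot.cea_ceac <- function(x, ...) {
  probs <- attr(x, "probs")
  grid <- attr(x, "wtp_grid")
  graphics::matplot(grid, probs, type = "l", lty = 1, lwd = 2,
                    xlab = "Willingness to pay (US$/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1),
                    main = "Cost-effectiveness acceptability curve", ...)
  graphics::legend("right", legend = colnames(probs),
                   col = seq_len(ncol(probs)), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
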