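# One-way deterministic sensitivity analysis (tornado).

# Low/high excursion for one scalar pspec: the printed range when one is
# available, otherwise mean +/- 1.96 SD clipped to the parameter's support.
dsa_bounds <- function(spec) {
  if (!is.null(spec$range) && spec$range[1] <= spec$range[2]) {
    return(spec$range)
  }
  m <- spec$mean
  s <- spec$sd %||% (0.25 * abs(m))
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  if (spec$dist == "beta") {
    lo <- max(0, lo); hi <- min(1, hi)
  } else if (spec$dist == "gamma") {
    if (m >= 0) lo <- max(0, lo) else hi <- min(0, hi)
  }
  c(lo, hi)
}

# DSA-varied parameters: every scalar registry entry plus the three
# cumulative ACR rates of each first-line drug (varied individually with
# monotonicity clamping).
dsa_parameters <- function(config) {
  reg <- Filter(function(e) e$kind == "scalar", psa_parameters(config))
  entries <- lapply(reg, function(e) {
    spec <- config[[e$path]]
    if (spec$dist == "fixed" || (spec$sd %||% 0) == 0 && is.null(spec$range)) {
      return(NULL)
    }
    b <- dsa_bounds(spec)
    list(id = e$id, kind = "scalar", path = e$path, mirror = e$mirror,
         low = b[1], high = b[2], base = spec$mean)
  })
  entries <- Filter(Negate(is.null), entries)
  for (d in names(config$first_line)) {
    r <- config$first_line[[d]]$acr
    sds <- r$sds %||% rep(0, 3)
    for (k in 1:3) {
      nm <- c("cum20", "cum50", "cum70")[k]
      m <- r[[nm]]
      b <- c(max(0, m - 1.96 * sds[k]), min(1, m + 1.96 * sds[k]))
      entries[[length(entries) + 1L]] <- list(
        id = paste0("first_line.", d, ".acr.", nm), kind = "acr_cum",
        path = c("first_line", d, "acr"), component = nm,
        low = b[1], high = b[2], base = m)
    }
  }
  entries
}

set_dsa_value <- function(config, entry, value) {
  if (entry$kind == "scalar") {
    config[[c(entry$path, "mean")]] <- value
    for (mp in entry$mirror) config[[c(mp, "mean")]] <- value
  } else {
    r <- config[[entry$path]]
    r[[entry$component]] <- value
    # clamp to keep cumulative monotonicity
    r$cum50 <- min(r$cum50, r$cum20)
    r$cum70 <- min(r$cum70, r$cum50)
    config[[entry$path]] <- r
  }
  config
}

#' One-way deterministic sensitivity analysis
#'
#' Varies each uncertain parameter alone to the ends of its 95% interval
#' (printed range where available, mean +/- 1.96 SD otherwise), re-runs the
#' model, and records the resulting ICER excursion for every strategy
#' comparison. Entries are sorted by bar width (|ICER high - ICER low|) in
#' descending order; an entry whose base-case ICER falls outside the
#' excursion interval is flagged non-monotone.
#'
#' @param config a `"cea_config"`.
#' @param pairs list of `c(comparator, reference)` strategy pairs; defaults
#'   to all ordered pairs of configured strategies against earlier-listed
#'   ones.
#' @param top number of entries flagged as the leading parameters per pair.
#' @return A `"cea_tornado"` data frame: one row per parameter and pair
#'   with low/high parameter values, ICERs at both ends, `width`, `rank`
#'   (within pair), `top` flag and `non_monotone` flag.
#' @export
tornado <- function(config, pairs = NULL, top = 10) {
  config <- validate_config(config)
  strategies <- config$strategies
  if (is.null(pairs)) {
    pairs <- list()
    for (i in seq_along(strategies)) {
      for (j in seq_len(i - 1L)) {
        pairs[[length(pairs) + 1L]] <- c(strategies[i], strategies[j])
      }
    }
  }
  lt <- resolve_life_table(config)
  eval_config <- function(cfg) {
    res <- lapply(strategies, function(s) strategy_result(run_cohort(cfg, s, lt)))
    names(res) <- strategies
    res
  }
  base <- eval_config(config)
  pair_icer <- function(res, pr) {
    ic <- icer(res[[pr[1]]], res[[pr[2]]], config$settings)
    ic$icer
  }
  entries <- dsa_parameters(config)

  rows <- list()
  for (e in entries) {
    res_lo <- eval_config(set_dsa_value(config, e, e$low))
    res_hi <- eval_config(set_dsa_value(config, e, e$high))
    for (pr in pairs) {
      i_lo <- pair_icer(res_lo, pr)
      i_hi <- pair_icer(res_hi, pr)
      i_base <- pair_icer(base, pr)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = e$id, comparator = pr[1], reference = pr[2],
        low = e$low, high = e$high, base = e$base,
        icer_low = i_lo, icer_high = i_hi, icer_base = i_base,
        width = abs(i_hi - i_lo),
        non_monotone = !is.na(i_lo) && !is.na(i_hi) &&
          (i_base < min(i_lo, i_hi) - 1e-9 | i_base > max(i_lo, i_hi) + 1e-9),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$comparator, out$reference, -out$width), ]
  out$rank <- stats::ave(-out$width, out$comparator, out$reference,
                         FUN = function(x) rank(x, ties.method = "first"))
  out$top <- out$rank <= top
  rownames(out) <- NULL
  structure(out, class = c("cea_tornado", "data.frame"))
}

#' Tornado diagram for one comparison
#' @param x a `"cea_tornado"`.
#' @param comparator,reference the strategy pair to plot (defaults to the
#'   first pair present).
#' @param top number of bars.
#' @param ... unused.
#' @export
plot.cea_tornado <- function(x, comparator = NULL, reference = NULL,
                             top = 10, ...) {
  d <- as.data.frame(x)
  comparator <- comparator %||% d$comparator[1]
  reference <- reference %||% d$reference[d$comparator == comparator][1]
  d <- d[d$comparator == comparator & d$reference == reference, ]
  d <- utils::head(d[order(-d$width), ], top)
  d <- d[order(d$width), ]
  lo <- pmin(d$icer_low, d$icer_high)
  hi <- pmax(d$icer_low, d$icer_high)
  op <- graphics::par(mar = c(5, 16, 3, 2)); on.exit(graphics::par(op))
  graphics::plot(range(c(lo, hi, d$icer_base)), c(0.5, nrow(d) + 0.5),
                 type = "n", yaxt = "n", xlab = "ICER (US$/QALY)", ylab = "",
                 main = paste("Tornado:", comparator, "vs", reference))
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "steelblue")
  graphics::abline(v = d$icer_base[1], lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}
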