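# Life-table handling and HAQ-adjusted mortality.

#' Construct a life table
#'
#' @param df data frame with columns `age` (integer), `sex`
#'   (`"male"`/`"female"`) and `annual_qx` (annual death probability).
#' @return A `"life_table"` data frame.
#' @export
life_table <- function(df) {
  stopifnot(all(c("age", "sex", "annual_qx") %in% names(df)))
  if (any(df$annual_qx < 0 | df$annual_qx > 1)) {
    stop("life_table: annual_qx outside [0, 1]")
  }
  if (!all(df$sex %in% c("male", "female"))) {
    stop("life_table: sex must be 'male' or 'female'")
  }
  df <- df[order(df$sex, df$age), c("age", "sex", "annual_qx")]
  rownames(df) <- NULL
  class(df) <- c("life_table", "data.frame")
  df
}

#' Read / write a life table CSV
#'
#' Plain CSV with columns `age,sex,annual_qx`.
#' @param path file path.
#' @return [read_life_table()] returns a `"life_table"`;
#'   [write_life_table()] returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param lt a `"life_table"`.
#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Stand-in for a national life table: the annual hazard at age x is
#' `makeham + level * exp(slope * x)` per sex, integrated over the year of
#' age to give `annual_qx`. Defaults are calibrated to a long-lived
#' high-income population (blended life expectancy at age 56 of about
#' 26 years); the table is synthetic and deterministic.
#'
#' @param male,female length-3 named lists/vectors with elements `makeham`
#'   (background hazard), `level` (Gompertz level) and `slope` (log-hazard
#'   slope per year of age).
#' @param ages integer ages covered.
#' @return A `"life_table"`.
#' @export
generate_life_table <- function(male = list(makeham = 2.0e-4, level = 2.0e-5, slope = 0.102),
                                female = list(makeham = 1.2e-4, level = 0.9e-5, slope = 0.107),
                                ages = 0:100) {
  qx <- function(p) {
    A <- p$makeham; B <- p$level; th <- p$slope
    if (any(c(A, B, th) < 0)) stop("generate_life_table: parameters must be >= 0")
    cum <- if (th > 0) B / th * (exp(th * (ages + 1)) - exp(th * ages)) else rep(B, length(ages))
    q <- 1 - exp(-(A + cum))
    if (any(q > 1 | q < 0)) stop("generate_life_table: qx outside [0, 1] before age ", max(ages))
    q
  }
  life_table(data.frame(
    age = rep(ages, 2L),
    sex = rep(c("male", "female"), each = length(ages)),
    annual_qx = c(qx(male), qx(female))
  ))
}

#' Sex-blended per-cycle death probability
#'
#' Looks up the annual death probabilities at `floor(age)` (capped at the
#' table's oldest age), blends male and female by the cohort's female
#' fraction, and converts to the model's cycle length assuming a constant
#' hazard within the year: `1 - (1 - q_annual)^cycle_length`.
#'
#' @param lt a `"life_table"`.
#' @param age cohort age in years (vectorized).
#' @param female_fraction proportion of women in the cohort.
#' @param cycle_length_years cycle length (default 0.5).
#' @return per-cycle death probability (same length as `age`).
#' @export
cycle_death_prob <- function(lt, age, female_fraction,
                             cycle_length_years = 0.5) {
  amax <- max(lt$age)
  a <- pmin(pmax(floor(age), min(lt$age)), amax)
  qm <- lt$annual_qx[lt$sex == "male"][match(a, lt$age[lt$sex == "male"])]
  qf <- lt$annual_qx[lt$sex == "female"][match(a, lt$age[lt$sex == "female"])]
  q <- female_fraction * qf + (1 - female_fraction) * qm
  1 - (1 - q)^cycle_length_years
}

#' HAQ-adjusted death probability
#'
#' Scales the general-population per-cycle death probability by a hazard
#' ratio raised to the HAQ-DI score (`base_q * hr^haq`), capped at 1: worse
#' disability carries excess mortality.
#'
#' @param base_q per-cycle general-population death probability.
#' @param haq HAQ-DI score in `[0, 3]`.
#' @param hr hazard ratio per HAQ-DI unit (base case 1.33).
#' @return adjusted probability (vectorized, capped at 1).
#' @examples
#' adjusted_mortality(0.01, 1, 1.33)  # 0.0133
#' @export
adjusted_mortality <- function(base_q, haq, hr) {
  pmin(base_q * hr^haq, 1)
}

#' Remaining life expectancy from a life table
#'
#' Blended (or single-sex) expectation of remaining years at a given age,
#' computed from cumulative annual survival with a half-year continuity
#' correction. Used to sanity-check synthetic tables.
#'
#' @param lt a `"life_table"`.
#' @param age starting age.
#' @param female_fraction blend weight (1 = female table, 0 = male).
#' @return remaining life expectancy in years.
#' @export
life_expectancy <- function(lt, age, female_fraction = 0.5) {
  ages <- sort(unique(lt$age))
  ages <- ages[ages >= age]
  q <- cycle_death_prob(lt, ages, female_fraction, cycle_length_years = 1)
  sum(cumprod(1 - q)) + 0.5
}

# Resolve the config's life-table section (either a Gompertz-Makeham spec or
# an inline/CSV table) into a life_table object.
resolve_life_table <- function(config) {
  ltc <- config$life_table
  if (inherits(ltc, "life_table")) return(ltc)
  if (!is.null(ltc$csv)) return(read_life_table(ltc$csv))
  if (identical(ltc$family, "gompertz_makeham")) {
    return(generate_life_table(male = ltc$male, female = ltc$female))
  }
  if (is.data.frame(ltc)) return(life_table(ltc))
  if (is.list(ltc) && !is.null(ltc$age)) {
    return(life_table(as.data.frame(lapply(ltc, unlist))))
  }
  stop("config: unrecognized life_table section")
}
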