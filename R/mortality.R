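#' Synthesize a calibrated background life table
#'
#' Builds the sex-weighted (55 % female) background mortality schedule used by
#' the model as a parametric Gompertz-Makeham life table calibrated so that
#' remaining life expectancy at `start_age` equals
#' `target_le_total - start_age`. The annual hazard at exact age x is
#' `makeham + level * exp(slope * (x - start_age))`; only `level` is fitted
#' (one-dimensional root finding), since model results depend on background
#' mortality only through life expectancy at the cohort start age. A real
#' life table in the same two-column format (age, annual death probability)
#' can replace the synthetic one via [read_lifetable()].
#'
#' @param start_age Cohort start age in years (default 47).
#' @param target_le_total Target total life expectancy of the non-diabetic
#'   population in years (default 84.2).
#' @param max_age Last open age; the table is closed with q = 1 there.
#' @param makeham Age-independent hazard component (per year).
#' @param slope Gompertz log-hazard slope (per year).
#' @return An object of class `islet_lifetable`: list with `ages`, `q_annual`,
#'   `start_age`, and a `calibration` record (target, achieved LE, fitted
#'   coefficients).
#' @export
#' @examples
#' lt <- build_background_lifetable()
#' lt$calibration$achieved_le_total
build_background_lifetable <- function(start_age = 47, target_le_total = 84.2,
                                       max_age = 110, makeham = 5e-4,
                                       slope = 0.10) {
  if (start_age >= target_le_total)
    stop("start_age must be below target_le_total")
  ages <- seq(floor(start_age), max_age)
  q_from_level <- function(level) {
    h <- makeham + level * exp(slope * (ages + 0.5 - start_age))
    q <- 1 - exp(-h)
    q[length(q)] <- 1
    q
  }
  remaining_le <- function(level) lifetable_le(q_from_level(level))
  f <- function(loglevel) remaining_le(exp(loglevel)) - (target_le_total - start_age)
  sol <- tryCatch(
    uniroot(f, lower = log(1e-8), upper = log(0.5), tol = 1e-10),
    error = function(e) stop("life-table calibration did not converge: ",
                             conditionMessage(e)))
  level <- exp(sol$root)
  q <- q_from_level(level)
  achieved <- floor(start_age) + lifetable_le(q)
  if (abs(achieved - target_le_total) > 0.1)
    stop("life-table calibration off target: achieved ", round(achieved, 3))
  structure(list(
    ages = ages, q_annual = q, start_age = start_age,
    calibration = list(family = "gompertz-makeham",
                       target_le_total = target_le_total,
                       achieved_le_total = achieved,
                       makeham = makeham, slope = slope, level = level)),
    class = "islet_lifetable")
}

## Remaining life expectancy by trapezoid summation of annual survival.
lifetable_le <- function(q_annual) {
  s <- cumprod(1 - q_annual)
  sum((c(1, s[-length(s)]) + s) / 2)
}

#' Remaining life expectancy at an age of the table
#' @param lifetable An `islet_lifetable`.
#' @param age Integer age within the table (default: its start age).
#' @return Remaining life expectancy in years.
#' @export
remaining_life_expectancy <- function(lifetable, age = lifetable$start_age) {
  i <- match(floor(age), lifetable$ages)
  if (is.na(i)) stop("age outside life table")
  lifetable_le(lifetable$q_annual[i:length(lifetable$q_annual)])
}

#' Scale an annual death probability by a hazard ratio
#'
#' Probability -> cumulative hazard -> scale -> probability:
#' `1 - (1 - q)^hr`. Commutes with [annual_to_cycle()].
#'
#' @param q Probability in `[0, 1)` (1 is passed through).
#' @param hr Hazard ratio, > 0.
#' @return Scaled probability.
#' @export
#' @examples
#' apply_hazard_ratio(0.01, 2.40)  # ~0.02384
apply_hazard_ratio <- function(q, hr) {
  stopifnot(all(q >= 0), all(q <= 1), all(hr > 0))
  1 - (1 - q)^hr
}

#' Convert an annual probability to a per-cycle probability
#'
#' @param q Annual probability in `[0, 1]`.
#' @param cycles_per_year Number of model cycles per year (default 16).
#' @return Per-cycle probability `1 - (1 - q)^(1/cycles_per_year)`.
#' @export
annual_to_cycle <- function(q, cycles_per_year = 16) {
  stopifnot(all(q >= 0), all(q <= 1))
  1 - (1 - q)^(1 / cycles_per_year)
}

## Per-cycle background death probability for each model cycle, from the
## life table and the cohort start age. Ages beyond the table are fatal.
cycle_background_q <- function(lifetable, start_age, n_cycles,
                               cycles_per_year = 16) {
  age <- floor(start_age + (seq_len(n_cycles) - 1) / cycles_per_year)
  i <- match(age, lifetable$ages)
  q_ann <- rep(1, n_cycles)
  ok <- !is.na(i)
  q_ann[ok] <- lifetable$q_annual[i[ok]]
  annual_to_cycle(q_ann, cycles_per_year)
}

#' Read or write a life table as two-column CSV (age, q_annual)
#' @param path File path.
#' @param lifetable An `islet_lifetable`.
#' @param start_age Start age to attach on read.
#' @return `read_lifetable()` returns an `islet_lifetable`.
#' @export
read_lifetable <- function(path, start_age = NULL) {
  df <- read.csv(path)
  stopifnot(all(c("age", "q_annual") %in% names(df)))
  q <- df$q_annual
  if (any(q < 0 | q > 1)) stop("q_annual outside [0, 1]")
  structure(list(ages = df$age, q_annual = q,
                 start_age = if (is.null(start_age)) df$age[1] else start_age,
                 calibration = list(family = "user-supplied")),
            class = "islet_lifetable")
}

#' @rdname read_lifetable
#' @export
write_lifetable <- function(lifetable, path) {
  write.csv(data.frame(age = lifetable$ages, q_annual = lifetable$q_annual),
            path, row.names = FALSE)
  invisible(path)
}
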