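#' Run the cohort engine for one arm over a set of parameter draws
#'
#' Iterates state occupancy over the model horizon for every draw in
#' `inputs`, applying half-cycle correction (rewards valued at the average of
#' beginning- and end-of-cycle occupancy) and discounting. Per-transplantation
#' lump costs and one-time disutilities are applied to the full mass entering
#' the transplantation state.
#'
#' @param inputs Engine inputs from [build_model_inputs()].
#' @param arm `"transplant"` or `"comparator"`.
#' @param record_every If > 0, record cumulative discounted cost and QALYs
#'   every this many cycles (for net-benefit probability maps).
#' @param trace Record full per-cycle state occupancy (single draw only).
#' @return A data frame with one row per draw and columns `cost`, `qaly`,
#'   `ly`, `cost_undisc`, `qaly_undisc`, `ly_undisc`; checkpoint matrices and
#'   the occupancy trace are attached as attributes `cp_cost`, `cp_qaly`,
#'   `trace`.
#' @export
run_cohort <- function(inputs, arm = c("transplant", "comparator"),
                       record_every = 0, trace = FALSE) {
  arm <- match.arg(arm)
  res <- cohort_engine(arm == "transplant",
                       inputs$trans, inputs$costs, inputs$utils,
                       inputs$q_bg, inputs$log1q,
                       inputs$disc_mid, inputs$disc_end,
                       inputs$n_cycles, inputs$cycles_per_year,
                       inputs$first_phase, inputs$max_tx,
                       as.integer(record_every), trace)
  out <- as.data.frame(res$totals)
  if (!is.null(res$cp_cost)) {
    attr(out, "cp_cost") <- res$cp_cost
    attr(out, "cp_qaly") <- res$cp_qaly
  }
  if (!is.null(res$trace)) {
    tr <- res$trace
    colnames(tr) <- expand_states(inputs$max_tx, inputs$first_phase)$label
    attr(out, "trace") <- tr
  }
  out
}

#' Run one treatment arm under a single parameter realization
#'
#' @param arm `"transplant"` or `"comparator"`.
#' @param draw A named parameter vector ([draw()] or [mean_draw()]).
#' @param config An [model_config()].
#' @param lifetable An `islet_lifetable`.
#' @param scen An [scenario()].
#' @param trace Also return the per-cycle occupancy trace.
#' @return List of class `islet_arm_result` with expected (discounted and
#'   undiscounted) cost, QALYs and life years, and optionally `trace`.
#' @export
run_arm <- function(arm, draw, config = model_config(),
                    lifetable = build_background_lifetable(
                      start_age = config$start_age,
                      target_le_total = config$target_le_nondiabetic),
                    scen = scenario(), trace = FALSE) {
  inputs <- build_model_inputs(draw, scen, config, lifetable)
  if (inputs$n_draws != 1) stop("run_arm expects a single draw")
  res <- run_cohort(inputs, arm, trace = trace)
  structure(list(arm = arm,
                 expected_cost = res$cost[1], expected_qaly = res$qaly[1],
                 expected_ly = res$ly[1],
                 undiscounted_cost = res$cost_undisc[1],
                 undiscounted_qaly = res$qaly_undisc[1],
                 undiscounted_ly = res$ly_undisc[1],
                 trace = attr(res, "trace")),
            class = "islet_arm_result")
}

#' Incremental cost-effectiveness summary of two arm results
#'
#' @param tx,cmp `islet_arm_result` objects (or lists with `expected_cost`
#'   and the effect fields) for the transplant and comparator arm.
#' @param wtp Willingness to pay per unit of effect (CAD).
#' @param outcome `"QALY"` or `"LY"`.
#' @return List with `delta_cost`, `delta_effect`, `icer` (`NA` with
#'   `icer_defined = FALSE` when the incremental effect is <= 0), and `nmb`.
#' @export
incremental <- function(tx, cmp, wtp = 100000, outcome = c("QALY", "LY")) {
  outcome <- match.arg(outcome)
  eff <- if (outcome == "QALY") "expected_qaly" else "expected_ly"
  delta_cost <- tx$expected_cost - cmp$expected_cost
  delta_effect <- tx[[eff]] - cmp[[eff]]
  defined <- delta_effect > 0
  list(delta_cost = delta_cost, delta_effect = delta_effect,
       icer = if (defined) delta_cost / delta_effect else NA_real_,
       icer_defined = defined,
       nmb = delta_effect * wtp - delta_cost)
}

#' Five-year graft-survival check and calibration
#'
#' Runs the transplant arm at mean parameters and reports the five-year
#' (cycle `5 * cycles_per_year`) state occupancy conditional on survival:
#' the share with full graft function and the overall graft-survival share
#' (full + partial + transplantation states). If the registered transition
#' probabilities do not reproduce the target rates (50 % full, 82 % overall),
#' a common multiplier on the full-to-partial and late partial-failure
#' probabilities is calibrated by root finding on the full-function target.
#'
#' @param targets Named vector with `full_5y` and `overall_5y`.
#' @param registry,config,lifetable Model inputs.
#' @param tol Calibration tolerance on the full-function share.
#' @param printed_tol Half-width for judging the registered probabilities
#'   "already on target" without calibration.
#' @param bounds Search interval for the multiplier.
#' @return List with `multiplier`, achieved shares at the calibrated
#'   multiplier (`achieved`) and at multiplier 1 (`uncalibrated`), and
#'   logical `printed_values_ok`.
#' @export
calibrate_graft_transitions <- function(targets = c(full_5y = 0.50,
                                                    overall_5y = 0.82),
                                        registry = build_default_registry(),
                                        config = model_config(),
                                        lifetable = build_background_lifetable(
                                          start_age = config$start_age,
                                          target_le_total = config$target_le_nondiabetic),
                                        tol = 0.02, printed_tol = 0.05,
                                        bounds = c(0.25, 4)) {
  draw0 <- mean_draw(registry)
  shares <- function(mult) {
    d <- draw0
    d["p_full_to_partial"] <- min(d["p_full_to_partial"] * mult, 1)
    d["p_partial_failure_after6m"] <- min(d["p_partial_failure_after6m"] * mult, 1)
    cfg <- config
    cfg$horizon_cycles <- 5 * config$cycles_per_year
    res <- run_arm("transplant", d, cfg, lifetable, trace = TRUE)
    occ <- res$trace[nrow(res$trace), ]
    st <- expand_states(config$max_transplants, config$first_phase_cycles)
    alive <- 1 - occ[st$base == "DEAD"]
    full <- sum(occ[st$base == "FULL"]) / alive
    graft <- sum(occ[st$base %in% c("FULL", "PARTIAL", "TRANSPLANT")]) / alive
    c(full_5y = unname(full), overall_5y = unname(graft))
  }
  at1 <- shares(1)
  printed_ok <- all(abs(at1 - targets[names(at1)]) <= printed_tol)
  f <- function(m) shares(m)["full_5y"] - targets["full_5y"]
  mult <- tryCatch(uniroot(f, lower = bounds[1], upper = bounds[2],
                           tol = 1e-4)$root,
                   error = function(e) {
                     grid <- seq(bounds[1], bounds[2], length.out = 25)
                     grid[which.min(abs(vapply(grid, f, 0)))]
                   })
  list(multiplier = mult, achieved = shares(mult), uncalibrated = at1,
       targets = targets, printed_values_ok = printed_ok)
}

#' Total life expectancy of the IIT arm implied by the model
#'
#' Runs the comparator arm at mean parameters, undiscounted, and reports
#' `start_age +` undiscounted life years -- the quantity the mortality hazard
#' ratios are calibrated against (base case target: 72.2 total years, i.e. a
#' 12-year difference from the non-diabetic 84.2).
#'
#' @param lifetable An `islet_lifetable`.
#' @param config An [model_config()].
#' @param registry Parameter registry.
#' @param hr_multiplier Common multiplier applied to both mortality hazard
#'   ratios; must lie in `[0.2, 5]`.
#' @return Total life expectancy in years.
#' @export
verify_arm_life_expectancy <- function(lifetable = build_background_lifetable(),
                                       config = model_config(),
                                       registry = build_default_registry(),
                                       hr_multiplier = 1) {
  if (hr_multiplier < 0.2 || hr_multiplier > 5)
    stop("hr_multiplier outside [0.2, 5]: model misconfigured")
  cfg <- config
  cfg$discount_rate_annual <- 0
  scen0 <- scenario(discount_rate_annual = 0, hr_multiplier = hr_multiplier)
  res <- run_arm("comparator", mean_draw(registry), cfg, lifetable, scen0)
  config$start_age + res$undiscounted_ly
}

#' Calibrate the mortality HR multiplier to a life-expectancy difference
#'
#' Finds the common multiplier on both mortality hazard ratios such that the
#' IIT arm's total life expectancy equals
#' `target_le_nondiabetic - le_difference`.
#'
#' @param le_difference Target difference in years (e.g. 10, 12, 14).
#' @inheritParams verify_arm_life_expectancy
#' @return The calibrated multiplier.
#' @export
calibrate_le_difference <- function(le_difference,
                                    lifetable = build_background_lifetable(),
                                    config = model_config(),
                                    registry = build_default_registry()) {
  target <- config$target_le_nondiabetic - le_difference
  f <- function(m) verify_arm_life_expectancy(lifetable, config, registry, m) - target
  uniroot(f, lower = 0.2, upper = 5, tol = 1e-4)$root
}
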