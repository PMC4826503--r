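#' Model configuration
#'
#' Settings of the cohort engine: cycle structure, horizon, discounting and
#' cohort demographics. The defaults are the base-case analysis settings:
#' 1/16-year cycles (~23 days) over 1000 cycles (62.5 years), 5 % annual
#' discounting of costs and effects, cohort start age 47, up to four
#' transplantations, and a first post-transplant phase of 8 cycles (~6
#' months) with higher costs and early graft-failure risk.
#'
#' @param cycles_per_year Cycles per year.
#' @param horizon_cycles Number of cycles simulated.
#' @param discount_rate_annual Annual discount rate (fraction).
#' @param start_age Cohort start age, years.
#' @param max_transplants Maximum transplantations per patient.
#' @param first_phase_cycles Length of the early post-transplant phase, cycles.
#' @param wtp_grid Willingness-to-pay grid (CAD per QALY) for acceptability
#'   curves and value-of-information summaries.
#' @param outcome `"QALY"` or `"LY"`.
#' @param target_le_nondiabetic Total life expectancy of the non-diabetic
#'   reference population, years (life-table calibration anchor).
#' @return A list of class `islet_config`.
#' @export
model_config <- function(cycles_per_year = 16, horizon_cycles = 1000,
                         discount_rate_annual = 0.05, start_age = 47,
                         max_transplants = 4, first_phase_cycles = 8,
                         wtp_grid = seq(0, 250000, by = 2000),
                         outcome = c("QALY", "LY"),
                         target_le_nondiabetic = 84.2) {
  outcome <- match.arg(outcome)
  stopifnot(horizon_cycles >= 0, discount_rate_annual >= 0,
            cycles_per_year >= 1, max_transplants >= 1,
            first_phase_cycles >= 1)
  structure(list(cycles_per_year = cycles_per_year,
                 horizon_cycles = horizon_cycles,
                 discount_rate_annual = discount_rate_annual,
                 start_age = start_age,
                 max_transplants = max_transplants,
                 first_phase_cycles = first_phase_cycles,
                 wtp_grid = wtp_grid, outcome = outcome,
                 target_le_nondiabetic = target_le_nondiabetic),
            class = "islet_config")
}

#' Define an analysis scenario
#'
#' A scenario is a structured override set applied on top of the base case:
#' discount rate, generic vs branded immunosuppression pricing, the assumed
#' life-expectancy difference between IIT-treated patients and the
#' non-diabetic population (implemented through a common multiplier on both
#' mortality hazard ratios, calibrated at run time for differences other than
#' the 12-year base case), doubled IIT-state disutilities, cost multipliers
#' for the IIT/DRC states, a per-transplantation cost reduction, and the
#' outcome measure.
#'
#' @param id Scenario identifier.
#' @param description Free-text description.
#' @param discount_rate_annual Annual discount rate (fraction).
#' @param generic_immunosuppression Use generic (1/3) immunosuppression price?
#' @param le_difference Assumed life-expectancy difference (years) between
#'   IIT-treated patients and the non-diabetic population: 12 (base), 10 or 14.
#' @param double_iit_disutilities Double the IIT-state disutilities (mean
#'   utilities become 0.61 / 0.43)?
#' @param iit_cost_multiplier Multiplier on the IIT-without-complications
#'   state cost (1.10 in the increased-cost scenario).
#' @param drc_cost_multiplier Multiplier on the DRC state cost (1.25).
#' @param transplant_cost_delta Additive change in CAD per transplantation
#'   (e.g. -20000).
#' @param zero_immunosuppression_cost Hypothetical: immunosuppression free of
#'   charge.
#' @param outcome `"QALY"` or `"LY"`.
#' @param population_factor Patients represented at population level for
#'   population EVPI (default 5140).
#' @param hr_multiplier Optional explicit multiplier on both mortality hazard
#'   ratios; `NULL` means 1 for the 12-year base case and calibrated for
#'   other `le_difference` values.
#' @return A list of class `islet_scenario`.
#' @export
scenario <- function(id = "base", description = "base case",
                     discount_rate_annual = 0.05,
                     generic_immunosuppression = FALSE,
                     le_difference = 12,
                     double_iit_disutilities = FALSE,
                     iit_cost_multiplier = 1.0,
                     drc_cost_multiplier = 1.0,
                     transplant_cost_delta = 0,
                     zero_immunosuppression_cost = FALSE,
                     outcome = c("QALY", "LY"),
                     population_factor = 5140,
                     hr_multiplier = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(iit_cost_multiplier > 0, drc_cost_multiplier > 0,
            discount_rate_annual >= 0, le_difference > 0)
  structure(list(id = id, description = description,
                 discount_rate_annual = discount_rate_annual,
                 generic_immunosuppression = generic_immunosuppression,
                 le_difference = le_difference,
                 double_iit_disutilities = double_iit_disutilities,
                 iit_cost_multiplier = iit_cost_multiplier,
                 drc_cost_multiplier = drc_cost_multiplier,
                 transplant_cost_delta = transplant_cost_delta,
                 zero_immunosuppression_cost = zero_immunosuppression_cost,
                 outcome = outcome,
                 population_factor = population_factor,
                 hr_multiplier = hr_multiplier),
            class = "islet_scenario")
}

## Config with the scenario's discount rate and outcome applied.
apply_scenario_config <- function(config, scen) {
  config$discount_rate_annual <- scen$discount_rate_annual
  config$outcome <- scen$outcome
  if (scen$le_difference >= config$target_le_nondiabetic - config$start_age)
    stop("le_difference must be smaller than remaining non-diabetic life expectancy")
  config
}
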