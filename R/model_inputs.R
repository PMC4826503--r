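## Engine input builder: turns parameter realizations into the per-draw
## transition, cost and utility matrices consumed by the C++ cohort engine
## and the R reference runner. Column orders here are a contract with
## src/cohort.cpp -- keep them in sync.

TRANS_COLS <- c("p_full1", "p_full2", "p_full34", "p_f2p", "p_ffail",
                "p_pfail_early", "p_pfail_late", "p_drc_n", "p_drc_full",
                "p_drc_part", "p_major", "ratio_stop",
                "hr_mort_iit", "hr_mort_drc")
COST_COLS <- c("lump_tx1", "lump_tx2", "lump_tx3", "lump_tx4",
               "c_full_first", "c_full_after", "c_part_first", "c_part_after",
               "c_iit", "c_drc", "c_major_event")
UTIL_COLS <- c("u_tx1", "u_tx_re", "u_full", "u_part", "u_iit", "u_drc",
               "du_init_lump", "du_major_event")

## Printed per-state/per-transplant totals used as composition anchors.
TX_TOTAL_MEAN <- 94765          # all costs in the 23 days after a transplantation
FULL_FIRST6M_MEAN <- 1886       # full graft function, first 6 months, per cycle
FULL_AFTER_MEAN <- 747          # full graft function afterwards, per cycle
VGC_COURSE_DAYS <- 98           # valganciclovir: 14-week course
INSULIN_SHARE_PARTIAL <- 0.40   # share of IIT cost added in partial-graft states
INSULIN_SHARE_TX <- 0.16        # share of IIT cost added in the transplant cycle

#' Build cohort-engine inputs from parameter realizations
#'
#' Composes per-draw derived quantities from the sampled components:
#' per-cycle state costs (e.g. graft-survival cost = immunosuppression +
#' amortized annual follow-up visit, plus 40 % of the IIT cost as insulin in
#' partial-graft states), the total cost per transplantation (procedure +
#' anakinra + first-cycle immunosuppression + the in-cycle share of the
#' valganciclovir course + a fixed early follow-up residual, reconciled so
#' the mean equals the printed 94,765 CAD total), the incremental utility
#' chain (full graft 0.82; each further state subtracts its decrement), the
#' nested hazard ratios, and per-cycle background mortality with discount
#' factors. Scenario overrides (generic immunosuppression, cost multipliers,
#' transplant cost delta, doubled IIT disutilities, mortality HR multiplier)
#' are applied here.
#'
#' @param draws A named numeric vector (one realization) or an `n x p` matrix
#'   from [draw_matrix()].
#' @param scen An [scenario()] (its `hr_multiplier` must already be resolved
#'   to a number or `NULL` = 1).
#' @param config An [model_config()].
#' @param lifetable An `islet_lifetable`.
#' @return List with matrices `trans`, `costs`, `utils` (one row per draw),
#'   cycle vectors `q_bg`, `log1q`, `disc_mid`, `disc_end`, and the engine
#'   scalars.
#' @export
build_model_inputs <- function(draws, scen = scenario(),
                               config = model_config(),
                               lifetable = build_background_lifetable(
                                 start_age = config$start_age,
                                 target_le_total = config$target_le_nondiabetic)) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1,
                                           dimnames = list(NULL, names(draws)))
  g <- function(nm) {
    if (!nm %in% colnames(draws)) stop("draws missing parameter: ", nm)
    draws[, nm]
  }
  n <- nrow(draws)
  hr_mult <- if (is.null(scen$hr_multiplier)) 1 else scen$hr_multiplier
  if (hr_mult < 0.2 || hr_mult > 5)
    stop("mortality HR multiplier outside [0.2, 5]: model misconfigured")

  ## -- costs ----------------------------------------------------------------
  imm <- if (scen$zero_immunosuppression_cost) rep(0, n)
         else if (scen$generic_immunosuppression) g("cost_immunosuppression_generic_cycle")
         else g("cost_immunosuppression_cycle")
  fu_cycle <- g("cost_followup_visit") / config$cycles_per_year
  vgc <- g("cost_valganciclovir_course")
  c_full_after <- imm + fu_cycle
  c_full_first <- c_full_after +
    (FULL_FIRST6M_MEAN - FULL_AFTER_MEAN) / 5000 * vgc
  insulin_graft <- INSULIN_SHARE_PARTIAL * g("cost_iit_cycle")
  c_part_after <- c_full_after + insulin_graft
  c_part_first <- c_full_first + insulin_graft
  c_iit <- g("cost_iit_cycle") * scen$iit_cost_multiplier
  c_drc <- g("cost_drc_cycle") * scen$drc_cost_multiplier

  cycle_days <- 365.25 / config$cycles_per_year
  vgc_frac <- cycle_days / VGC_COURSE_DAYS
  early_fu_residual <- TX_TOTAL_MEAN - (91414 + 574 + 713.5 + 5000 * vgc_frac)
  lump_base <- g("cost_transplant_procedure") + g("cost_anakinra_course") +
    imm + vgc_frac * vgc + early_fu_residual + g("cost_alemtuzumab") +
    scen$transplant_cost_delta +
    g("ratio_initial_complications") * g("cost_initial_complication") +
    INSULIN_SHARE_TX * g("cost_iit_cycle")
  lump_tx1 <- lump_base + g("cost_pre_transplant_visit")
  lump_tx2 <- lump_base + 0.5 * g("cost_basiliximab")
  lump_tx3 <- lump_base
  lump_tx4 <- lump_base
  costs <- cbind(lump_tx1, lump_tx2, lump_tx3, lump_tx4,
                 c_full_first, c_full_after, c_part_first, c_part_after,
                 c_iit, c_drc, g("cost_major_complication"))
  colnames(costs) <- COST_COLS
  if (any(costs < 0))
    stop("negative state cost after scenario overrides")

  ## -- utilities (annual chain, stored per cycle) ---------------------------
  dbl <- if (scen$double_iit_disutilities) 2 else 1
  u_full_a <- g("u_full_graft")
  u_part_a <- u_full_a - g("du_partial_graft")
  u_iit_a <- u_part_a - dbl * g("du_iit")
  u_drc_a <- u_part_a - g("du_iit") - dbl * g("du_drc")
  u_ann <- cbind(u_iit_a, u_part_a, u_full_a, u_part_a, u_iit_a, u_drc_a)
  if (any(u_ann < -1 | u_ann > 1))
    stop("state utility outside [-1, 1]")
  utils <- cbind(u_ann / config$cycles_per_year,
                 g("ratio_initial_complications") * g("du_initial_complication"),
                 g("du_major_complication"))
  colnames(utils) <- UTIL_COLS

  ## -- transitions ----------------------------------------------------------
  hr_drc_part <- g("hr_drc_partial")
  hr_drc_full <- hr_drc_part * g("ratio_hr_drc_full")
  p_drc_n <- g("p_drc_base")
  trans <- cbind(g("p_full_tx1"), g("p_full_tx2"), g("p_full_tx34"),
                 g("p_full_to_partial"), g("p_full_graft_failure"),
                 g("p_partial_failure_first6m"), g("p_partial_failure_after6m"),
                 p_drc_n,
                 apply_hazard_ratio(p_drc_n, hr_drc_full),
                 apply_hazard_ratio(p_drc_n, hr_drc_part),
                 g("p_major_complication"), g("ratio_stop_immunosuppression"),
                 g("hr_mortality_hypoglycemia") * hr_mult,
                 g("hr_mortality_hypoglycemia") * g("ratio_hr_mortality_drc") * hr_mult)
  colnames(trans) <- TRANS_COLS
  probs <- trans[, 1:12, drop = FALSE]
  if (any(probs < 0 | probs > 1))
    stop("transition probability outside [0, 1]")

  ## -- per-cycle vectors ----------------------------------------------------
  n_cycles <- config$horizon_cycles
  q_bg <- cycle_background_q(lifetable, config$start_age, n_cycles,
                             config$cycles_per_year)
  r <- config$discount_rate_annual
  i <- seq_len(n_cycles)
  list(trans = trans, costs = costs, utils = utils,
       q_bg = q_bg, log1q = log(1 - q_bg),
       disc_mid = (1 + r)^(-(i - 0.5) / config$cycles_per_year),
       disc_end = (1 + r)^(-i / config$cycles_per_year),
       n_cycles = n_cycles,
       cycles_per_year = config$cycles_per_year,
       first_phase = config$first_phase_cycles,
       max_tx = config$max_transplants,
       n_draws = n)
}
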