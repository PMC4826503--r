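#' Probabilistic sensitivity analysis
#'
#' Samples `n_draws` parameter realizations, runs both arms under every
#' realization, and records paired discounted/undiscounted costs, QALYs and
#' life years together with per-draw cumulative (discounted) incremental cost
#' and effect paths at regular checkpoints (for net-benefit probability
#' maps). Draws are reproducible by seed, and scenarios sharing a seed use
#' common random numbers wherever parameter specifications coincide, so
#' scenario contrasts are low variance.
#'
#' @param n_draws Number of Monte Carlo draws (>= 2).
#' @param seed Integer root seed.
#' @param registry Parameter registry ([build_default_registry()]).
#' @param config Model configuration ([model_config()]).
#' @param scen Scenario ([scenario()]); its discount rate and outcome
#'   override the configuration, and its `le_difference` is resolved to a
#'   mortality-HR multiplier (calibrated when different from the 12-year base
#'   case).
#' @param lifetable Background life table.
#' @param record_every Checkpoint interval in cycles for the cumulative
#'   net-benefit paths (default 40 = 2.5 years); 0 disables recording.
#' @return Object of class `islet_psa`: a list with `draws` (data frame of
#'   per-draw arm results and increments), checkpoint matrices `cp_delta_cost`
#'   / `cp_delta_qaly`, `checkpoint_years`, and metadata.
#' @export
run_psa <- function(n_draws, seed, registry = build_default_registry(),
                    config = model_config(), scen = scenario(),
                    lifetable = build_background_lifetable(
                      start_age = config$start_age,
                      target_le_total = config$target_le_nondiabetic),
                    record_every = 40) {
  stopifnot(n_draws >= 2)
  scen <- resolve_scenario(scen, registry, config, lifetable)
  cfg <- apply_scenario_config(config, scen)
  draws <- draw_matrix(registry, n_draws, seed)
  inputs <- build_model_inputs(draws, scen, cfg, lifetable)
  tx <- run_cohort(inputs, "transplant", record_every = record_every)
  cmp <- run_cohort(inputs, "comparator", record_every = record_every)
  bad <- !stats::complete.cases(tx) | !stats::complete.cases(cmp)
  if (any(bad)) {
    if (mean(bad) > 0.01)
      stop("more than 1% of PSA draws produced non-finite results")
    warning(sum(bad), " non-finite PSA draw(s) skipped")
  }
  df <- data.frame(
    cost_tx = tx$cost, qaly_tx = tx$qaly, ly_tx = tx$ly,
    cost_cmp = cmp$cost, qaly_cmp = cmp$qaly, ly_cmp = cmp$ly,
    ly_tx_undisc = tx$ly_undisc, ly_cmp_undisc = cmp$ly_undisc,
    qaly_tx_undisc = tx$qaly_undisc, qaly_cmp_undisc = cmp$qaly_undisc,
    cost_tx_undisc = tx$cost_undisc, cost_cmp_undisc = cmp$cost_undisc)
  df <- df[!bad, , drop = FALSE]
  df$delta_cost <- df$cost_tx - df$cost_cmp
  df$delta_qaly <- df$qaly_tx - df$qaly_cmp
  df$delta_ly <- df$ly_tx - df$ly_cmp
  df$delta_effect <- if (cfg$outcome == "QALY") df$delta_qaly else df$delta_ly
  out <- list(draws = df, n_draws = nrow(df), seed = seed, scenario = scen,
              config = cfg)
  if (record_every > 0) {
    out$cp_delta_cost <- (attr(tx, "cp_cost") - attr(cmp, "cp_cost"))[!bad, , drop = FALSE]
    out$cp_delta_qaly <- (attr(tx, "cp_qaly") - attr(cmp, "cp_qaly"))[!bad, , drop = FALSE]
    out$checkpoint_years <- seq_len(ncol(out$cp_delta_cost)) * record_every /
      cfg$cycles_per_year
  }
  structure(out, class = "islet_psa")
}

## Memoized resolution of the scenario's mortality-HR multiplier.
.le_cache <- new.env(parent = emptyenv())
resolve_scenario <- function(scen, registry, config, lifetable) {
  if (!is.null(scen$hr_multiplier)) return(scen)
  if (scen$le_difference == 12) { scen$hr_multiplier <- 1; return(scen) }
  key <- paste0("le", scen$le_difference, "_",
                format(lifetable$calibration$achieved_le_total %||% 0, digits = 10),
                "_", config$start_age)
  if (is.null(.le_cache[[key]]))
    .le_cache[[key]] <- calibrate_le_difference(scen$le_difference, lifetable,
                                                config, registry)
  scen$hr_multiplier <- .le_cache[[key]]
  scen
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected cost-effectiveness summary of a PSA
#'
#' Expectations over the PSA draws per arm, incremental cost and effect, and
#' the ICER computed from those expectations.
#'
#' @param psa An `islet_psa`.
#' @return One-row data frame: per-arm expected cost and effect, `delta_cost`,
#'   `delta_effect`, `icer`.
#' @export
psa_summary <- function(psa) {
  df <- psa$draws
  eff_tx <- if (psa$config$outcome == "QALY") df$qaly_tx else df$ly_tx
  eff_cmp <- if (psa$config$outcome == "QALY") df$qaly_cmp else df$ly_cmp
  delta_cost <- mean(df$delta_cost)
  delta_effect <- mean(df$delta_effect)
  data.frame(scenario = psa$scenario$id,
             cost_cmp = mean(df$cost_cmp), cost_tx = mean(df$cost_tx),
             delta_cost = delta_cost,
             effect_cmp = mean(eff_cmp), effect_tx = mean(eff_tx),
             delta_effect = delta_effect,
             icer = if (delta_effect > 0) delta_cost / delta_effect else NA_real_)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws in which transplantation has positive incremental
#' net monetary benefit at each willingness-to-pay value.
#'
#' @param psa An `islet_psa`.
#' @param wtp_grid Willingness-to-pay grid (CAD per effect unit).
#' @return Data frame `wtp`, `prob_ce`.
#' @export
ceac <- function(psa, wtp_grid = psa$config$wtp_grid) {
  df <- psa$draws
  prob <- vapply(wtp_grid,
                 function(l) mean(df$delta_effect * l - df$delta_cost > 0), 0)
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' Cost-effectiveness acceptability frontier
#'
#' At each willingness-to-pay value, the probability that the option with the
#' highest *expected* net monetary benefit is the cost-effective one in a
#' random draw. For two options this follows the comparator's acceptability
#' curve below the expected-NMB crossover (the ICER from expectations) and
#' the transplant curve above it.
#'
#' @inheritParams ceac
#' @return Data frame `wtp`, `best`, `prob_frontier`.
#' @export
ceaf <- function(psa, wtp_grid = psa$config$wtp_grid) {
  df <- psa$draws
  cc <- ceac(psa, wtp_grid)
  exp_nmb_inc <- mean(df$delta_effect) * wtp_grid - mean(df$delta_cost)
  tx_best <- exp_nmb_inc > 0
  data.frame(wtp = wtp_grid,
             best = ifelse(tx_best, "transplant", "comparator"),
             prob_frontier = ifelse(tx_best, cc$prob_ce, 1 - cc$prob_ce))
}

#' Net benefit probability map
#'
#' Deciles (and mean) of the cumulative incremental net *health* benefit
#' `cum delta E - cum delta C / wtp` over model time, evaluated at the
#' recorded checkpoints.
#'
#' @param psa An `islet_psa` run with `record_every > 0`.
#' @param wtp Willingness to pay (CAD per QALY), default 100,000.
#' @return Data frame with `years`, `mean`, and decile columns `d10` ... `d90`.
#' @export
nbpm <- function(psa, wtp = 100000) {
  if (is.null(psa$cp_delta_cost))
    stop("PSA was run without checkpoint recording")
  nhb <- psa$cp_delta_qaly - psa$cp_delta_cost / wtp
  qs <- apply(nhb, 2, stats::quantile, probs = seq(0.1, 0.9, 0.1))
  out <- data.frame(years = psa$checkpoint_years, mean = colMeans(nhb))
  dec <- as.data.frame(t(qs))
  names(dec) <- paste0("d", seq(10, 90, 10))
  cbind(out, dec)
}

#' Expected value of perfect information
#'
#' Per-patient EVPI at each willingness-to-pay value,
#' `mean(max(0, NMB_draw)) - max(0, mean(NMB))` over the incremental NMB
#' draws, and the population EVPI obtained by scaling with the number of
#' patients the decision affects.
#'
#' @inheritParams ceac
#' @param population_factor Patients represented at population level
#'   (default: the scenario's, 5140 in the base case).
#' @return Data frame `wtp`, `evpi`, `evpi_population`.
#' @export
evpi <- function(psa, wtp_grid = psa$config$wtp_grid,
                 population_factor = psa$scenario$population_factor) {
  df <- psa$draws
  per_patient <- vapply(wtp_grid, function(l) {
    nmb <- df$delta_effect * l - df$delta_cost
    mean(pmax(nmb, 0)) - max(mean(nmb), 0)
  }, 0)
  data.frame(wtp = wtp_grid, evpi = per_patient,
             evpi_population = per_patient * population_factor)
}

#' Nested two-level EVPPI estimator
#'
#' Expected value of perfect information about a parameter group, by the
#' traditional nested Monte Carlo scheme: the outer loop samples the group,
#' the inner loop samples the complement conditional on it (via
#' [partial_draw_matrix()]), inner-loop NMB means are maximized over options
#' per outer iteration, averaged, and the maximum overall expected NMB is
#' subtracted. Common random numbers are used across options within an inner
#' loop (both arms run on the same draws).
#'
#' @param group `"costs"`, `"natural_history"`, `"effectiveness_safety"`, or
#'   a character vector of parameter names.
#' @param outer,inner Loop sizes (>= 2 each).
#' @param wtp_grid Willingness-to-pay grid.
#' @param seed Integer root seed.
#' @inheritParams run_psa
#' @return Data frame `wtp`, `evppi` (per patient, CAD), with attribute
#'   `outer_means` (per-outer-iteration inner-mean arm results).
#' @export
evppi_nested <- function(group, outer = 600, inner = 600,
                         wtp_grid = NULL, seed = 1,
                         registry = build_default_registry(),
                         config = model_config(), scen = scenario(),
                         lifetable = build_background_lifetable(
                           start_age = config$start_age,
                           target_le_total = config$target_le_nondiabetic)) {
  stopifnot(outer >= 2, inner >= 2)
  scen <- resolve_scenario(scen, registry, config, lifetable)
  cfg <- apply_scenario_config(config, scen)
  if (is.null(wtp_grid)) wtp_grid <- cfg$wtp_grid
  resolve_group(registry, group)   # fail early on unknown group
  outer_draws <- draw_matrix(registry, outer, substream_seed(seed, "evppi_outer"))
  eff_col <- if (cfg$outcome == "QALY") "qaly" else "ly"
  om <- matrix(NA_real_, outer, 4,
               dimnames = list(NULL, c("cost_tx", "eff_tx", "cost_cmp", "eff_cmp")))
  for (j in seq_len(outer)) {
    m <- partial_draw_matrix(registry, group, outer_draws[j, ], inner,
                             substream_seed(seed, "evppi_inner", j))
    inputs <- build_model_inputs(m, scen, cfg, lifetable)
    tx <- run_cohort(inputs, "transplant")
    cmp <- run_cohort(inputs, "comparator")
    om[j, ] <- c(mean(tx$cost), mean(tx[[eff_col]]),
                 mean(cmp$cost), mean(cmp[[eff_col]]))
  }
  per_patient <- vapply(wtp_grid, function(l) {
    nmb_tx <- l * om[, "eff_tx"] - om[, "cost_tx"]
    nmb_cmp <- l * om[, "eff_cmp"] - om[, "cost_cmp"]
    mean(pmax(nmb_tx, nmb_cmp)) - max(mean(nmb_tx), mean(nmb_cmp))
  }, 0)
  structure(data.frame(wtp = wtp_grid, evppi = per_patient),
            outer_means = om, group = group,
            loops = c(outer = outer, inner = inner))
}
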