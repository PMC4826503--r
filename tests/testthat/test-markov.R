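test_that("transition rows are proper distributions for all states and many draws", {
  reg <- default_registry()
  st <- expand_states(4, 8)
  lt <- default_lifetable()
  set.seed(1)
  draws <- draw_matrix(reg, 300, seed = 2)
  cfg <- model_config()
  inputs <- build_model_inputs(draws, scenario(), cfg, lt)
  qs <- sample(inputs$q_bg, 5)   # a few ages across the horizon
  for (i in seq_len(nrow(draws))) {
    pars <- inputs$trans[i, ]
    q <- qs[1 + (i %% length(qs))]
    rows <- vapply(st$id, function(s)
      sum(transition_row(s, pars, q, st)), 0)
    expect_true(all(abs(rows - 1) < 1e-12))
  }
})

test_that("transition structure matches the allowed state graph", {
  reg <- default_registry()
  st <- expand_states(4, 8)
  inputs <- build_model_inputs(mean_draw(reg), scenario(), model_config(),
                               default_lifetable())
  pars <- inputs$trans[1, ]
  q <- inputs$q_bg[1]

  # IIT with complications: support only on itself and dead
  r <- transition_row(isletcea:::state_index(st, "IIT_DRC"), pars, q, st)
  expect_true(all(r[setdiff(names(r), c("IIT_DRC", "DEAD"))] == 0))

  # transplantation cannot reach IIT without complications directly
  r <- transition_row(isletcea:::state_index(st, "TRANSPLANT", 1), pars, q, st)
  expect_equal(unname(r["IIT_NO_DRC"]), 0)
  expect_gt(unname(r["IIT_DRC"]), 0)

  # full graft: the registered probability enters before competing risks,
  # so the realized flow is slightly below it
  expect_equal(unname(pars["p_f2p"]), 0.0077379, tolerance = 1e-6)
  rf <- transition_row(isletcea:::state_index(st, "FULL", 1, 9), pars, q, st)
  flow <- sum(rf[grep("^P1_", names(rf))])
  expect_lt(flow, pars[["p_f2p"]])
  expect_gt(flow, pars[["p_f2p"]] * 0.99)

  # early partial graft with re-transplants left: survivors re-transplant
  rp <- transition_row(isletcea:::state_index(st, "PARTIAL", 2, 1), pars, q, st)
  expect_gt(unname(rp["T3"]), 0.9)
  # at the fourth transplant they stay partial under the late failure rate
  rp4 <- transition_row(isletcea:::state_index(st, "PARTIAL", 4, 1), pars, q, st)
  expect_equal(unname(rp4["T4"]), 0)
  expect_gt(unname(rp4["P4_c2"]), 0.9)
})

test_that("state costs compose to the printed per-cycle totals", {
  reg <- default_registry()
  lt <- default_lifetable()
  inp <- build_model_inputs(mean_draw(reg), scenario(), model_config(), lt)
  costs <- inp$costs[1, ]
  expect_equal(unname(costs["c_full_after"]), 747, tolerance = 0.005)
  expect_equal(unname(costs["c_part_after"]), 811, tolerance = 0.005)
  expect_equal(unname(costs["c_full_first"]), 1886, tolerance = 0.005)
  expect_equal(unname(costs["c_part_first"]), 1950, tolerance = 0.005)
  expect_equal(unname(costs["c_iit"]), 159)
  expect_equal(unname(costs["c_drc"]), 602, tolerance = 1e-6)
  # per-transplant total: printed 94,765 plus expected initial-complication
  # cost (0.65 x 600) and the in-cycle insulin share
  expect_equal(unname(costs["lump_tx3"]), 94765 + 0.65 * 600 + 0.16 * 159,
               tolerance = 0.002)
  expect_equal(unname(costs["lump_tx1"] - costs["lump_tx3"]), 569)
  expect_equal(unname(costs["lump_tx2"] - costs["lump_tx3"]), 1500)

  # generic immunosuppression lowers graft-state costs by the printed gap
  gen <- build_model_inputs(mean_draw(reg),
                            scenario(generic_immunosuppression = TRUE),
                            model_config(), lt)
  expect_equal(unname(costs["c_full_after"] - gen$costs[1, "c_full_after"]),
               713.5 - 238.1, tolerance = 1e-9)
})

test_that("utilities follow the incremental decrement chain", {
  reg <- default_registry()
  lt <- default_lifetable()
  inp <- build_model_inputs(mean_draw(reg), scenario(), model_config(), lt)
  u <- inp$utils[1, ] * 16
  expect_equal(unname(u["u_full"]), 0.82)
  expect_equal(inp$utils[1, "u_full"], 0.82 / 16)   # = 0.05125 per cycle
  expect_equal(unname(u["u_part"]), 0.81)
  expect_equal(unname(u["u_iit"]), 0.71)
  expect_equal(unname(u["u_drc"]), 0.57)
  expect_equal(unname(u["u_tx1"]), unname(u["u_iit"]))
  expect_equal(unname(u["u_tx_re"]), unname(u["u_part"]))

  dbl <- build_model_inputs(mean_draw(reg),
                            scenario(double_iit_disutilities = TRUE),
                            model_config(), lt)
  ud <- dbl$utils[1, ] * 16
  expect_equal(unname(ud["u_iit"]), 0.61)
  expect_equal(unname(ud["u_drc"]), 0.43)
})

test_that("cohort engine agrees with the independent R reference runner", {
  reg <- default_registry()
  lt <- default_lifetable()
  cfg <- model_config(horizon_cycles = 1000)
  for (dr in list(mean_draw(reg), draw(reg, 42))) {
    for (sc in list(scenario(),
                    scenario(generic_immunosuppression = TRUE,
                             discount_rate_annual = 0.01),
                    scenario(double_iit_disutilities = TRUE,
                             discount_rate_annual = 0,
                             iit_cost_multiplier = 1.1,
                             drc_cost_multiplier = 1.25))) {
      inp <- build_model_inputs(dr, sc, cfg, lt)
      for (arm in c("transplant", "comparator")) {
        eng <- unlist(run_cohort(inp, arm)[1, ])
        ref <- unlist(isletcea:::run_arm_reference(inp, arm))
        expect_equal(eng, ref, tolerance = 1e-9)
      }
    }
  }
})

test_that("occupancy is conserved, death is absorbing, survival dominance holds", {
  reg <- default_registry()
  lt <- default_lifetable()
  d <- draw(reg, 3)
  res <- run_arm("transplant", d, lifetable = lt, trace = TRUE)
  tr <- res$trace
  expect_true(all(abs(rowSums(tr) - 1) < 1e-9))
  expect_true(all(diff(tr[, "DEAD"]) > -1e-12))
  # transplant arm never dies faster than the comparator
  psa <- shared_psa(500, seed = 6)
  expect_true(all(psa$draws$ly_tx_undisc >= psa$draws$ly_cmp_undisc))
  expect_true(all(psa$draws$qaly_tx_undisc <= psa$draws$ly_tx_undisc))
})

test_that("undiscounted arm totals reproduce the published life-year row", {
  reg <- default_registry()
  lt <- default_lifetable()
  cfg <- model_config(discount_rate_annual = 0)
  cmp <- run_arm("comparator", mean_draw(reg), cfg, lt)
  tx <- run_arm("transplant", mean_draw(reg), cfg, lt)
  expect_equal(cmp$undiscounted_ly, 25.30, tolerance = 1.0 / 25.30)
  expect_equal(tx$undiscounted_ly, 28.63, tolerance = 1.0 / 28.63)
  expect_gt(tx$undiscounted_ly, cmp$undiscounted_ly)
})

test_that("zero horizon yields zero totals and discounting is monotone", {
  reg <- default_registry()
  lt <- default_lifetable()
  cfg0 <- model_config(horizon_cycles = 0)
  res <- run_arm("transplant", mean_draw(reg), cfg0, lt)
  expect_equal(unlist(res[2:7]), rep(0, 6), ignore_attr = TRUE)

  r3 <- run_arm("transplant", mean_draw(reg),
                model_config(discount_rate_annual = 0.03), lt)
  r5 <- run_arm("transplant", mean_draw(reg),
                model_config(discount_rate_annual = 0.05), lt)
  expect_gt(r3$expected_cost, r5$expected_cost)
  expect_gt(r3$expected_qaly, r5$expected_qaly)
  expect_gt(r3$expected_ly, r5$expected_ly)
  expect_lt(r5$expected_cost, r5$undiscounted_cost)
})

test_that("incremental summary computes ICER and net monetary benefit", {
  # direct arithmetic on the published incremental expectations
  tx <- list(expected_cost = 290816, expected_qaly = 1.9387, expected_ly = 1)
  cmp <- list(expected_cost = 0, expected_qaly = 0, expected_ly = 0)
  inc <- incremental(tx, cmp, wtp = 100000)
  expect_equal(inc$nmb, -96946, tolerance = 1e-4)
  expect_equal(inc$icer, 150006, tolerance = 1e-5)
  z <- incremental(cmp, cmp)
  expect_equal(z$delta_cost, 0)
  expect_equal(z$delta_effect, 0)
  expect_equal(z$nmb, 0)
  expect_false(z$icer_defined)
})

test_that("five-year graft survival matches the calibration targets", {
  cal <- calibrate_graft_transitions(registry = default_registry(),
                                     lifetable = default_lifetable())
  expect_lt(abs(cal$uncalibrated["full_5y"] - 0.50), 0.05)
  expect_lt(abs(cal$uncalibrated["overall_5y"] - 0.82), 0.05)
  expect_true(cal$printed_values_ok)
  expect_lt(abs(cal$achieved["full_5y"] - 0.50), 0.002)
  expect_true(cal$multiplier > 0.25 && cal$multiplier < 4)
})

test_that("zero graft-loss multiplier freezes graft survival at its peak", {
  reg <- default_registry()
  d <- mean_draw(reg)
  d["p_full_to_partial"] <- 0
  d["p_partial_failure_after6m"] <- 0
  d["p_partial_failure_first6m"] <- 0
  d["p_full_graft_failure"] <- 0
  d["p_drc_base"] <- 0
  d["p_major_complication"] <- 0
  cfg <- model_config(horizon_cycles = 80)
  res <- run_arm("transplant", d, cfg, default_lifetable(), trace = TRUE)
  st <- expand_states(4, 8)
  occ <- res$trace[nrow(res$trace), ]
  alive <- 1 - occ[st$base == "DEAD"]
  graft <- sum(occ[st$base %in% c("FULL", "PARTIAL", "TRANSPLANT")]) / alive
  expect_gt(graft, 0.999)
})

test_that("cohort expectations match an individual-level microsimulation", {
  # comparator arm with a flat life table is a 3-state chain with constant
  # per-cycle probabilities; a 200k-walker microsimulation is the oracle
  lt <- flat_lifetable(q = 0.02)
  reg <- default_registry()
  d <- mean_draw(reg)
  cfg <- model_config(discount_rate_annual = 0, horizon_cycles = 1000)
  cohort <- run_arm("comparator", d, cfg, lt)
  q_cycle <- annual_to_cycle(0.02)
  ms <- microsim_comparator_ly(
    200000, 1000, q_cycle,
    hr_iit = d[["hr_mortality_hypoglycemia"]],
    hr_drc = d[["hr_mortality_hypoglycemia"]] * d[["ratio_hr_mortality_drc"]],
    p_drc = d[["p_drc_base"]])
  expect_lt(abs(cohort$undiscounted_ly - ms["mean"]), 3 * ms["se"])
})
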