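test_that("the scenario grid has 18 rows in the published order", {
  grid <- table4_scenarios()
  expect_length(grid, 18)
  expect_identical(names(grid)[1], "base_5pct")
  ref <- read.csv(system.file("extdata", "table4_reference.csv",
                              package = "isletcea"))
  expect_identical(ref$id, unname(vapply(grid, `[[`, "", "id")))
})

test_that("a default scenario is the identity override", {
  lt <- default_lifetable()
  row <- run_scenario(scenario(id = "custom"), 300, 5,
                      registry = default_registry(), lifetable = lt)
  psa <- run_psa(300, 5, registry = default_registry(), lifetable = lt,
                 record_every = 0)
  base <- psa_summary(psa)
  expect_equal(row$icer, base$icer)
  expect_equal(row$delta_cost, base$delta_cost)
})

test_that("generic immunosuppression changes costs only, under common random numbers", {
  lt <- default_lifetable()
  reg <- default_registry()
  b <- run_psa(400, 9, registry = reg, lifetable = lt, record_every = 0)
  g <- run_psa(400, 9, registry = reg, lifetable = lt, record_every = 0,
               scen = scenario(generic_immunosuppression = TRUE))
  expect_equal(b$draws$qaly_tx, g$draws$qaly_tx)
  expect_equal(b$draws$qaly_cmp, g$draws$qaly_cmp)
  expect_equal(b$draws$ly_tx, g$draws$ly_tx)
  expect_true(all(b$draws$cost_tx > g$draws$cost_tx))
  expect_equal(b$draws$cost_cmp, g$draws$cost_cmp)
})

test_that("scenario overrides move costs in the expected directions", {
  lt <- default_lifetable()
  reg <- default_registry()
  d <- mean_draw(reg)
  base <- run_arm("transplant", d, lifetable = lt)
  cheap <- run_arm("transplant", d, lifetable = lt,
                   scen = scenario(transplant_cost_delta = -20000))
  expect_lt(cheap$expected_cost, base$expected_cost - 20000)  # >1 transplant
  dear <- run_arm("comparator", d, lifetable = lt,
                  scen = scenario(iit_cost_multiplier = 1.10,
                                  drc_cost_multiplier = 1.25))
  expect_gt(dear$expected_cost, run_arm("comparator", d, lifetable = lt)$expected_cost)
  free <- run_arm("transplant", d, lifetable = lt,
                  scen = scenario(zero_immunosuppression_cost = TRUE))
  expect_lt(free$expected_cost, base$expected_cost)
})

test_that("lower discount rates raise effects and lower the ICER; QALY gains exceed LY gains", {
  lt <- default_lifetable()
  reg <- default_registry()
  rates <- c(0, 0.01, 0.03, 0.035, 0.05)
  rows <- lapply(rates, function(r)
    run_scenario(scenario(id = paste0("r", r), discount_rate_annual = r),
                 800, 21, registry = reg, lifetable = lt))
  icers <- vapply(rows, `[[`, 0, "icer")
  effects <- vapply(rows, `[[`, 0, "delta_effect")
  expect_true(all(diff(icers) > 0))      # ICER increases with discount rate
  expect_true(all(diff(effects) < 0))

  ly_row <- run_scenario(scenario(id = "ly", outcome = "LY"), 800, 21,
                         registry = reg, lifetable = lt)
  expect_gt(rows[[5]]$delta_effect, ly_row$delta_effect)
  expect_gt(ly_row$delta_effect, 0)
})

test_that("life-expectancy scenarios recalibrate the comparator arm", {
  lt <- default_lifetable()
  reg <- default_registry()
  row <- run_scenario(scenario(id = "le10", le_difference = 10,
                               discount_rate_annual = 0, outcome = "LY"),
                      400, 31, registry = reg, lifetable = lt)
  # comparator undiscounted life years = (84.2 - 10) - 47 at mean parameters;
  # PSA expectation sits close to it
  expect_equal(row$effect_cmp, 74.2 - 47, tolerance = 0.02)
  expect_error(run_scenario(scenario(le_difference = 40), 10, 1,
                            registry = reg, lifetable = lt))
})

test_that("configurations load from YAML and JSON files", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("config:",
               "  discount_rate_annual: 0.03",
               "  horizon_cycles: 400",
               "scenario:",
               "  id: from_yaml",
               "  generic_immunosuppression: true",
               "  le_difference: 10"), yml)
  cfg <- load_analysis_config(yml)
  expect_equal(cfg$config$discount_rate_annual, 0.03)
  expect_equal(cfg$config$horizon_cycles, 400)
  expect_true(cfg$scenario$generic_immunosuppression)
  expect_equal(cfg$scenario$le_difference, 10)
  expect_s3_class(cfg$registry, "islet_registry")

  js <- tempfile(fileext = ".json")
  writeLines('{"scenario": {"id": "from_json", "outcome": "LY"}}', js)
  cfg2 <- load_analysis_config(js)
  expect_equal(cfg2$scenario$outcome, "LY")
  expect_equal(cfg2$config$discount_rate_annual, 0.05)
  expect_error(load_analysis_config(tempfile(fileext = ".txt")), "yaml")
})

test_that("scenario runs with a shared seed are deterministic end to end", {
  lt <- default_lifetable()
  r1 <- run_scenario(scenario(id = "s"), 200, 77,
                     registry = default_registry(), lifetable = lt)
  r2 <- run_scenario(scenario(id = "s"), 200, 77,
                     registry = default_registry(), lifetable = lt)
  expect_identical(r1, r2)
})
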