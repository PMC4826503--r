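test_that("PSA runs are reproducible byte for byte and seed-sensitive", {
  lt <- default_lifetable()
  p1 <- run_psa(50, 17, registry = default_registry(), lifetable = lt)
  p2 <- run_psa(50, 17, registry = default_registry(), lifetable = lt)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$cp_delta_cost, p2$cp_delta_cost)
  p3 <- run_psa(50, 18, registry = default_registry(), lifetable = lt)
  expect_false(identical(p1$draws$delta_cost, p3$draws$delta_cost))
})

test_that("a fixed-only registry collapses the PSA to identical draws", {
  reg <- default_registry()
  reg$sd <- 0
  reg$distribution <- "fixed"
  reg$hyper_a <- NA
  reg$hyper_b <- NA
  psa <- run_psa(2, 1, registry = reg, lifetable = default_lifetable())
  expect_equal(psa$draws[1, ], psa$draws[2, ], ignore_attr = TRUE)
})

test_that("doubling the draws under common random numbers is stable", {
  lt <- default_lifetable()
  pA <- run_psa(1500, 4, registry = default_registry(), lifetable = lt,
                record_every = 0)
  pB <- run_psa(3000, 4, registry = default_registry(), lifetable = lt,
                record_every = 0)
  # common substreams: the first half of the larger run is the smaller run
  expect_equal(pA$draws$delta_cost, pB$draws$delta_cost[1:1500])
  iA <- psa_summary(pA)$icer
  iB <- psa_summary(pB)$icer
  dC <- pB$draws$delta_cost; dE <- pB$draws$delta_effect
  se_icer <- (iB / sqrt(length(dC))) *
    sqrt(stats::var(dC) / mean(dC)^2 + stats::var(dE) / mean(dE)^2 -
         2 * stats::cov(dC, dE) / (mean(dC) * mean(dE)))
  expect_lt(abs(iB - iA), 2 * se_icer)
})

test_that("acceptability curve behaves like a distribution function of the ICER draws", {
  psa <- shared_psa()
  cc <- ceac(psa, seq(0, 300000, by = 10000))
  expect_equal(cc$prob_ce[1], 0)            # all draws cost more
  expect_true(all(psa$draws$delta_cost > 0))
  if (all(psa$draws$delta_effect >= 0))
    expect_true(all(diff(cc$prob_ce) >= 0)) # monotone when all gains positive
  expect_gt(cc$prob_ce[nrow(cc)], 0.9)
})

test_that("acceptability frontier is the curve of the expected-NMB maximizer", {
  psa <- shared_psa()
  icer <- psa_summary(psa)$icer
  grid <- seq(0, 300000, by = 5000)
  cf <- ceaf(psa, grid)
  expect_true(all(cf$best[grid < icer] == "comparator"))
  expect_true(all(cf$best[grid > icer] == "transplant"))
  expect_equal(cf$prob_frontier[1], 1)      # certainty at zero willingness
  # brute-force recomputation on a subset of draws
  sub <- psa$draws[1:100, ]
  for (l in c(20000, icer * 0.9, icer * 1.1, 250000)) {
    nmb_tx <- l * sub$delta_effect - sub$delta_cost
    best_tx <- mean(nmb_tx) > 0
    brute <- if (best_tx) mean(nmb_tx > 0) else mean(nmb_tx <= 0)
    small <- psa
    small$draws <- sub
    expect_equal(ceaf(small, l)$prob_frontier, brute)
  }
})

test_that("net benefit probability map tracks cumulative net health benefit", {
  psa <- shared_psa()
  nb <- nbpm(psa, wtp = 100000)
  expect_equal(nb$years, seq(2.5, 62.5, by = 2.5))
  # early map is dominated by the up-front transplantation costs
  expect_lt(nb$mean[1], 0)
  expect_true(all(nb$d10 <= nb$d90))
  # terminal mean equals the expectation identity dE - dC/lambda
  s <- psa_summary(psa)
  expect_equal(nb$mean[nrow(nb)], s$delta_effect - s$delta_cost / 1e5,
               tolerance = 1e-10)
})

test_that("EVPI is the expected opportunity loss and scales to the population", {
  psa <- shared_psa()
  ev <- evpi(psa, c(0, 50000, 100000, 200000))
  expect_true(all(ev$evpi >= 0))
  expect_equal(ev$evpi_population, ev$evpi * 5140)
  expect_equal(ev$evpi[1], 0)     # all draws dearer: comparator always wins
  # dominance in every draw implies zero value of information
  fake <- psa
  fake$draws$delta_cost <- -abs(fake$draws$delta_cost)
  expect_equal(evpi(fake, 100000)$evpi, 0)
})

test_that("nested EVPPI respects its bounding cases", {
  lt <- default_lifetable()
  reg <- default_registry()
  psa <- shared_psa()
  icer <- psa_summary(psa)$icer
  ev <- evpi(psa, icer)$evpi

  set.seed(1)
  e_all <- evppi_nested(reg$name, outer = 120, inner = 120, wtp_grid = icer,
                        seed = 2, registry = reg, lifetable = lt)
  e_none <- evppi_nested(character(0), outer = 60, inner = 200,
                         wtp_grid = icer, seed = 2, registry = reg,
                         lifetable = lt)
  e_costs <- evppi_nested("costs", outer = 150, inner = 150, wtp_grid = icer,
                          seed = 2, registry = reg, lifetable = lt)
  # all parameters ~ EVPI; empty group ~ 0; both within Monte-Carlo error
  expect_lt(abs(e_all$evppi - ev) / max(ev, 1), 0.35)
  expect_lt(e_none$evppi, 0.25 * ev)
  # partial information is worth less than perfect information
  expect_lt(e_costs$evppi, 1.2 * ev)
  expect_gt(e_costs$evppi, 0)
})

test_that("invalid PSA and EVPPI inputs are rejected", {
  expect_error(run_psa(1, 1), "n_draws")
  expect_error(evppi_nested("not_a_group", 2, 2, wtp_grid = 1e5,
                            registry = default_registry(),
                            lifetable = default_lifetable()),
               "unknown group")
})
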