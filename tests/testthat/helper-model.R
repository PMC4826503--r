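# Shared fixtures, built once per test run.

default_lifetable <- function() {
  if (is.null(.fixtures$lifetable))
    .fixtures$lifetable <- build_background_lifetable()
  .fixtures$lifetable
}

default_registry <- function() {
  if (is.null(.fixtures$registry))
    .fixtures$registry <- build_default_registry()
  .fixtures$registry
}

# Base-case PSA shared between the PSA-level tests.
shared_psa <- function(n = 4000, seed = 1) {
  key <- paste0("psa_", n, "_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- run_psa(n, seed, registry = default_registry(),
                                lifetable = default_lifetable())
  .fixtures[[key]]
}

# A flat life table (constant annual death probability) for oracle tests.
flat_lifetable <- function(q = 0.02, start_age = 47, max_age = 110) {
  ages <- seq(start_age, max_age)
  qv <- rep(q, length(ages))
  qv[length(qv)] <- 1
  structure(list(ages = ages, q_annual = qv, start_age = start_age,
                 calibration = list(family = "flat")),
            class = "islet_lifetable")
}

# Individual-level microsimulation of the comparator chain
# (IIT_N -> IIT_D -> dead) under constant per-cycle probabilities;
# death first, then complications, matching the cohort composition order.
microsim_comparator_ly <- function(n_walkers, n_cycles, q_cycle,
                                   hr_iit, hr_drc, p_drc,
                                   cycles_per_year = 16, seed = 99) {
  set.seed(seed)
  qN <- 1 - (1 - q_cycle)^hr_iit
  qD <- 1 - (1 - q_cycle)^hr_drc
  state <- rep(1L, n_walkers)           # 1 = IIT_N, 2 = IIT_D, 3 = dead
  death_cycle <- rep(NA_integer_, n_walkers)
  for (i in seq_len(n_cycles)) {
    alive <- state != 3L
    if (!any(alive)) break
    u <- runif(sum(alive))
    s <- state[alive]
    qs <- ifelse(s == 1L, qN, qD)
    died <- u < qs
    progressed <- !died & s == 1L & (u < qs + (1 - qs) * p_drc)
    s[died] <- 3L
    s[progressed] <- 2L
    death_cycle[alive][died] <- i
    state[alive] <- s
  }
  ly <- ifelse(is.na(death_cycle), n_cycles, death_cycle - 0.5) / cycles_per_year
  c(mean = mean(ly), se = stats::sd(ly) / sqrt(n_walkers))
}

.fixtures <- new.env(parent = emptyenv())
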