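#' Expanded Markov state space
#'
#' Enumerates the expanded states in engine order: transplantation states
#' `T(k)` for the k-th transplant, full- and partial-graft states `F(k,c)` /
#' `P(k,c)` with `c` cycles since the latest transplant (capped at
#' `first_phase + 1`, the pooled "after 6 months" slot), the two IIT states
#' and the absorbing dead state.
#'
#' @param max_tx Maximum number of transplantations.
#' @param first_phase Early-phase length in cycles.
#' @return Data frame with `id`, `base`, `tx`, `csince`, `label`.
#' @export
expand_states <- function(max_tx = 4, first_phase = 8) {
  nslot <- first_phase + 1
  rows <- list(data.frame(base = "TRANSPLANT", tx = seq_len(max_tx), csince = 0))
  for (b in c("FULL", "PARTIAL")) {
    g <- expand.grid(csince = seq_len(nslot), tx = seq_len(max_tx))
    rows[[length(rows) + 1]] <- data.frame(base = b, tx = g$tx, csince = g$csince)
  }
  rows[[length(rows) + 1]] <- data.frame(base = c("IIT_NO_DRC", "IIT_DRC", "DEAD"),
                                         tx = NA, csince = NA)
  st <- do.call(rbind, rows)
  st$id <- seq_len(nrow(st))
  st$label <- ifelse(st$base %in% c("TRANSPLANT"),
                     paste0("T", st$tx),
                     ifelse(st$base %in% c("FULL", "PARTIAL"),
                            paste0(substr(st$base, 1, 1), st$tx, "_c", st$csince),
                            st$base))
  st[, c("id", "base", "tx", "csince", "label")]
}

state_index <- function(st, base, tx = NA, csince = NA) {
  i <- st$base == base &
    (is.na(tx) | (!is.na(st$tx) & st$tx == tx)) &
    (is.na(csince) | (!is.na(st$csince) & st$csince == csince))
  st$id[which(i)]
}

#' One row of the per-cycle transition matrix
#'
#' The reference (pure R) construction of the transition probabilities out of
#' a single expanded state, composing competing risks in fixed order: death,
#' then diabetes-related complications, then immunosuppression-stopping major
#' complications, then graft events, with the residual mass staying. Used to
#' cross-check the C++ engine and for unit-level inspection.
#'
#' @param state_id Row of [expand_states()] (its `id`).
#' @param pars One row of the `trans` matrix from [build_model_inputs()]
#'   (named vector).
#' @param q_bg_cycle Per-cycle background death probability for this cycle.
#' @param st State table from [expand_states()]; its dimensions define the
#'   state space.
#' @param first_phase,max_tx Structure parameters matching `st`.
#' @return Numeric probability vector over all states (sums to 1).
#' @export
transition_row <- function(state_id, pars, q_bg_cycle, st,
                           first_phase = 8, max_tx = 4) {
  p <- setNames(numeric(nrow(st)), st$label)
  row <- st[st$id == state_id, ]
  if (row$base == "DEAD") { p[state_index(st, "DEAD")] <- 1; return(p) }
  nslot <- first_phase + 1
  iN <- state_index(st, "IIT_NO_DRC"); iD <- state_index(st, "IIT_DRC")
  iDead <- state_index(st, "DEAD")
  split_iit <- function(mass) {
    p[iN] <<- p[iN] + mass * (1 - pars["p_drc_n"])
    p[iD] <<- p[iD] + mass * pars["p_drc_n"]
  }
  if (row$base == "IIT_NO_DRC") {
    q <- apply_hazard_ratio(q_bg_cycle, pars["hr_mort_iit"])
    p[iDead] <- q
    p[iD] <- (1 - q) * pars["p_drc_n"]
    p[iN] <- (1 - q) * (1 - pars["p_drc_n"])
    return(p)
  }
  if (row$base == "IIT_DRC") {
    q <- apply_hazard_ratio(q_bg_cycle, pars["hr_mort_drc"])
    p[iDead] <- q
    p[iD] <- 1 - q
    return(p)
  }
  ## graft-bearing states: background mortality
  q <- q_bg_cycle
  p[iDead] <- q
  rem <- 1 - q
  if (row$base == "TRANSPLANT") {
    drc <- rem * pars["p_drc_n"]
    p[iD] <- p[iD] + drc
    rem2 <- rem - drc
    pf <- c(pars["p_full1"], pars["p_full2"], pars["p_full34"],
            pars["p_full34"])[row$tx]
    p[state_index(st, "FULL", row$tx, 1)] <- rem2 * pf
    p[state_index(st, "PARTIAL", row$tx, 1)] <- rem2 * (1 - pf)
    return(p)
  }
  p_drc_state <- if (row$base == "FULL") pars["p_drc_full"] else pars["p_drc_part"]
  drc <- rem * p_drc_state
  p[iD] <- p[iD] + drc
  rem2 <- rem - drc
  stopf <- rem2 * pars["p_major"] * pars["ratio_stop"]
  split_iit(stopf)
  rem3 <- rem2 - stopf
  cn <- min(row$csince + 1, nslot)
  if (row$base == "FULL") {
    to_part <- rem3 * pars["p_f2p"]
    p[state_index(st, "PARTIAL", row$tx, cn)] <-
      p[state_index(st, "PARTIAL", row$tx, cn)] + to_part
    rem4 <- rem3 - to_part
    fail <- rem4 * pars["p_ffail"]
    split_iit(fail)
    p[state_index(st, "FULL", row$tx, cn)] <-
      p[state_index(st, "FULL", row$tx, cn)] + rem4 - fail
  } else {                                   # PARTIAL
    if (row$csince <= first_phase && row$tx < max_tx) {
      fail <- rem3 * pars["p_pfail_early"]
      split_iit(fail)
      p[state_index(st, "TRANSPLANT", row$tx + 1)] <- rem3 - fail
    } else {
      fail <- rem3 * pars["p_pfail_late"]
      split_iit(fail)
      p[state_index(st, "PARTIAL", row$tx, cn)] <-
        p[state_index(st, "PARTIAL", row$tx, cn)] + rem3 - fail
    }
  }
  p
}

## Slow, matrix-based reference runner over the same inputs as run_cohort().
## Independent re-derivation of the cohort dynamics and rewards, used in
## tests to cross-check the C++ engine.
run_arm_reference <- function(inputs, arm = c("transplant", "comparator")) {
  arm <- match.arg(arm)
  stopifnot(inputs$n_draws == 1)
  K <- inputs$max_tx; C <- inputs$first_phase
  st <- expand_states(K, C)
  S <- nrow(st)
  pars <- inputs$trans[1, ]
  cost <- inputs$costs[1, ]; util <- inputs$utils[1, ]
  dt <- 1 / inputs$cycles_per_year

  memb_cost <- memb_util <- alive <- numeric(S)
  first <- !is.na(st$csince) & st$csince <= C
  memb_cost[st$base == "FULL"] <-
    ifelse(first[st$base == "FULL"], cost["c_full_first"], cost["c_full_after"])
  memb_cost[st$base == "PARTIAL"] <-
    ifelse(first[st$base == "PARTIAL"], cost["c_part_first"], cost["c_part_after"])
  memb_cost[st$base == "IIT_NO_DRC"] <- cost["c_iit"]
  memb_cost[st$base == "IIT_DRC"] <- cost["c_drc"]
  memb_util[st$base == "TRANSPLANT"] <-
    ifelse(st$tx[st$base == "TRANSPLANT"] == 1, util["u_tx1"], util["u_tx_re"])
  memb_util[st$base == "FULL"] <- util["u_full"]
  memb_util[st$base == "PARTIAL"] <- util["u_part"]
  memb_util[st$base == "IIT_NO_DRC"] <- util["u_iit"]
  memb_util[st$base == "IIT_DRC"] <- util["u_drc"]
  alive[st$base != "DEAD"] <- 1

  lumps <- cost[c("lump_tx1", "lump_tx2", "lump_tx3", "lump_tx4")][seq_len(K)]
  tx_idx <- vapply(seq_len(K), function(k) state_index(st, "TRANSPLANT", k), 1L)
  graft <- st$base %in% c("FULL", "PARTIAL")

  occ <- numeric(S)
  totals <- c(cost = 0, qaly = 0, ly = 0,
              cost_undisc = 0, qaly_undisc = 0, ly_undisc = 0)
  if (arm == "transplant") {
    occ[tx_idx[1]] <- 1
    if (inputs$n_cycles >= 1) {
      totals["cost"] <- totals["cost_undisc"] <- lumps[1]
      totals["qaly"] <- totals["qaly_undisc"] <- -util["du_init_lump"]
    }
  } else occ[state_index(st, "IIT_NO_DRC")] <- 1

  tmat_cache <- list()
  for (i in seq_len(inputs$n_cycles)) {
    qb <- inputs$q_bg[i]
    key <- format(qb, digits = 15)
    if (is.null(tmat_cache[[key]])) {
      tm <- t(vapply(st$id, transition_row, numeric(S),
                     pars = pars, q_bg_cycle = qb, st = st,
                     first_phase = C, max_tx = K))
      tmat_cache[[key]] <- tm
    }
    tm <- tmat_cache[[key]]
    nw <- as.numeric(occ %*% tm)
    ## event mass of major complications (graft states, after death and DRC)
    p_drc_state <- ifelse(st$base == "FULL", pars["p_drc_full"], pars["p_drc_part"])
    ev_major <- sum(occ[graft] * (1 - qb) * (1 - p_drc_state[graft])) * pars["p_major"]
    ## inflow into re-transplant states
    retx <- vapply(seq_len(K), function(k) sum(occ * tm[, tx_idx[k]]), 0)
    mid <- 0.5 * (occ + nw)
    cost_cyc <- sum(mid * memb_cost) + ev_major * cost["c_major_event"]
    qaly_cyc <- sum(mid * memb_util) - ev_major * util["du_major_event"]
    ly_cyc <- sum(mid * alive) * dt
    dm <- inputs$disc_mid[i]; de <- inputs$disc_end[i]
    totals["cost"] <- totals["cost"] + cost_cyc * dm
    totals["qaly"] <- totals["qaly"] + qaly_cyc * dm
    totals["ly"] <- totals["ly"] + ly_cyc * dm
    totals["cost_undisc"] <- totals["cost_undisc"] + cost_cyc
    totals["qaly_undisc"] <- totals["qaly_undisc"] + qaly_cyc
    totals["ly_undisc"] <- totals["ly_undisc"] + ly_cyc
    for (k in seq_len(K)[-1]) {
      totals["cost"] <- totals["cost"] + retx[k] * lumps[k] * de
      totals["cost_undisc"] <- totals["cost_undisc"] + retx[k] * lumps[k]
      totals["qaly"] <- totals["qaly"] - retx[k] * util["du_init_lump"] * de
      totals["qaly_undisc"] <- totals["qaly_undisc"] - retx[k] * util["du_init_lump"]
    }
    occ <- nw
  }
  as.list(totals)
}
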