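#' @useDynLib isletcea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta rgamma rlnorm runif uniroot setNames
#' @importFrom utils read.csv write.csv
NULL

PARAM_GROUPS <- c("costs", "natural_history", "effectiveness_safety")

#' Default model parameter registry
#'
#' Builds the full set of parameter distribution specifications used by the
#' cost-utility model: unit costs (2012 CAD), utility weights and decrements,
#' transition probabilities per 1/16-year cycle, and hazard ratios. Each row
#' carries the distribution family and its hyperparameters (Beta alpha/beta,
#' Gamma shape/scale, Log-Normal mu/sigma), the mean and SD the hyperparameters
#' imply, and the value-of-information group the parameter belongs to.
#'
#' Derived per-state totals (e.g. the graft-state per-cycle cost of 747 CAD, or
#' the 94,765 CAD total per transplantation) are not independent rows; they are
#' composed from these components by [build_model_inputs()] so that parameter
#' uncertainty propagates through the composition.
#'
#' The two nested hazard ratios are stored as a base draw plus a ratio draw:
#' the full-graft DRC hazard ratio is `hr_drc_partial * ratio_hr_drc_full`
#' (mean 0.45 x 0.5556 = 0.25) and the mortality hazard ratio with
#' diabetes-related complications is
#' `hr_mortality_hypoglycemia * ratio_hr_mortality_drc` (mean 2.40 x 2.9845 =
#' 7.16), both ratios having their own log-normal distributions.
#'
#' @return A data frame of class `islet_registry` with columns `name`, `mean`,
#'   `sd`, `distribution`, `hyper_a`, `hyper_b`, `group`, `role`.
#' @export
#' @examples
#' reg <- build_default_registry()
#' subset(reg, name == "p_full_to_partial")
build_default_registry <- function() {
  row <- function(name, mean, sd, dist, a, b, group, role) {
    data.frame(name = name, mean = mean, sd = sd, distribution = dist,
               hyper_a = a, hyper_b = b, group = group, role = role,
               stringsAsFactors = FALSE)
  }
  specs <- rbind(
    ## -- costs (2012 CAD) ---------------------------------------------------
    row("cost_pre_transplant_visit", 569, 0, "fixed", NA, NA, "costs",
        "one-time assessment visit before the first transplantation"),
    row("cost_transplant_procedure", 91414, 13712, "lognormal", 11.412029, 0.149166, "costs",
        "transplantation incl. initial medication, 4-day stay"),
    row("cost_tacrolimus_month", 450, 33.75, "lognormal", 6.106443, 0.074895, "costs",
        "tacrolimus per month (component of per-cycle immunosuppression)"),
    row("cost_mmf_month", 500, 37.5, "lognormal", 6.211803, 0.074895, "costs",
        "mycophenolate mofetil per month (component)"),
    row("cost_alemtuzumab", 0, 0, "fixed", NA, NA, "costs",
        "induction agent, provided at no charge (compassionate release)"),
    row("cost_basiliximab", 3000, 0, "fixed", NA, NA, "costs",
        "once at 2nd transplant for about half of patients"),
    row("cost_valganciclovir_course", 5000, 375, "lognormal", 8.514389, 0.074895, "costs",
        "14-week antiviral prophylaxis course"),
    row("cost_anakinra_course", 574, 43, "lognormal", 6.349825, 0.074895, "costs",
        "anakinra for the 3 days after discharge"),
    row("cost_immunosuppression_cycle", 713.5, 53.5, "lognormal", 6.56667, 0.074895, "costs",
        "branded tacrolimus + MMF per 1/16-year cycle"),
    row("cost_immunosuppression_generic_cycle", 238.1, 17.9, "lognormal", 5.46808, 0.074895, "costs",
        "generic immunosuppression per cycle (1/3 of branded)"),
    row("cost_followup_visit", 556, 42, "lognormal", 6.31800, 0.074895, "costs",
        "post-transplant check-up visit (annual after year 1)"),
    row("cost_iit_cycle", 159, 12, "lognormal", 5.06920, 0.074895, "costs",
        "intensive insulin therapy without complications, per cycle"),
    row("cost_drc_cycle", 602, 120, "gamma", 25.00000, 24.0796, "costs",
        "IIT with diabetes-related complications, per cycle"),
    row("cost_initial_complication", 600, 180, "gamma", 11.1111, 54.0000, "costs",
        "extra cost of initial transplant/immunosuppressive complications"),
    row("cost_major_complication", 6500, 1300, "gamma", 25.0000, 260.0000, "costs",
        "extra cost per major immunosuppressive complication"),
    ## -- effectiveness & safety: utilities ----------------------------------
    row("u_full_graft", 0.82, 0.04, "beta", 70.56, 15.48, "effectiveness_safety",
        "annual utility, full graft function (insulin independent)"),
    row("du_partial_graft", 0.01, 0.002, "gamma", 25.00, 0.0004, "effectiveness_safety",
        "decrement full -> partial graft function"),
    row("du_iit", 0.10, 0.020, "gamma", 25.00, 0.004, "effectiveness_safety",
        "decrement partial graft -> IIT with hypoglycemia unawareness"),
    row("du_drc", 0.14, 0.042, "gamma", 11.11, 0.0126, "effectiveness_safety",
        "decrement IIT -> IIT with diabetes-related complications"),
    row("du_initial_complication", 0.05, 0.010, "gamma", 25.00, 0.002, "effectiveness_safety",
        "one-time disutility per initial complication"),
    row("du_major_complication", 0.10, 0.025, "gamma", 16.00, 0.00625, "effectiveness_safety",
        "one-time disutility per major immunosuppressive complication"),
    ## -- effectiveness & safety: probabilities -------------------------------
    row("ratio_initial_complications", 0.650, 0.0650, "beta", 34.30, 18.47, "effectiveness_safety",
        "share of patients with initial complications per transplantation"),
    row("p_full_tx1", 0.150, 0.0375, "beta", 13.45, 76.21, "effectiveness_safety",
        "insulin independent 23 days after 1st transplantation"),
    row("p_full_tx2", 0.700, 0.105, "beta", 12.63, 5.41, "effectiveness_safety",
        "insulin independent 23 days after 2nd transplantation"),
    row("p_full_tx34", 0.850, 0.1275, "beta", 5.80, 1.02, "effectiveness_safety",
        "insulin independent 23 days after 3rd/4th transplantation"),
    row("hr_drc_partial", 0.45, 0.0675, "lognormal", -0.8096, 0.149166, "effectiveness_safety",
        "hazard ratio of diabetes-related complications, partial graft"),
    row("ratio_hr_drc_full", 0.5556, 0.0840, "lognormal", -0.59891, 0.149166, "effectiveness_safety",
        "nested ratio: full-graft DRC HR as share of partial-graft HR (-> 0.25)"),
    row("p_full_to_partial", 0.0077379, 0.001161, "beta", 44.09, 5653.02, "effectiveness_safety",
        "full -> partial graft function, per cycle"),
    row("p_full_graft_failure", 0.0000164732, 0.00000247, "beta", 44.44, 2697667, "effectiveness_safety",
        "full graft -> graft failure, per cycle"),
    row("p_partial_failure_first6m", 0.045, 0.00675, "beta", 42.40, 899.81, "effectiveness_safety",
        "partial graft failure within first 6 months, per cycle"),
    row("p_partial_failure_after6m", 0.00532, 0.000798, "beta", 44.20, 8264.00, "effectiveness_safety",
        "partial graft failure after first 6 months, per cycle"),
    row("p_major_complication", 0.00006201, 0.000009302, "beta", 44.44, 716613, "effectiveness_safety",
        "major immunosuppressive complication in graft states, per cycle"),
    row("ratio_stop_immunosuppression", 0.100, 0.015, "beta", 39.90, 359.10, "effectiveness_safety",
        "share of major complications forcing immunosuppression stop"),
    ## -- natural history ------------------------------------------------------
    row("p_drc_base", 0.0018185, 0.000364, "beta", 24.96, 13700.60, "natural_history",
        "diabetes-related complications without graft protection, per cycle"),
    row("hr_mortality_hypoglycemia", 2.40, 0.24, "lognormal", 0.870494, 0.099751, "natural_history",
        "mortality hazard ratio, hypoglycemia unawareness (IIT states)"),
    row("ratio_hr_mortality_drc", 2.9845, 0.29845, "lognormal", 1.088457, 0.099751, "natural_history",
        "nested ratio: DRC mortality HR as multiple of hypoglycemia HR (-> 7.16)")
  )
  structure(specs, class = c("islet_registry", "data.frame"))
}

#' Recompute distribution moments and compare with the registered values
#'
#' For each specification, recomputes the mean (and SD where defined) implied
#' by the hyperparameters -- `alpha/(alpha+beta)` for Beta, `shape*scale` for
#' Gamma, `exp(mu + sigma^2/2)` for Log-Normal -- and reports the relative
#' error against the registered mean/SD. Mismatches beyond the tolerance are
#' flagged (with a warning, not an error: registered values are rounded).
#'
#' @param registry An `islet_registry` or any data frame with the same columns.
#' @param tol_mean,tol_sd Relative tolerances for the mean and SD checks.
#' @param warn Emit a warning when a spec fails?
#' @return Data frame with `name`, `implied_mean`, `rel_err_mean`,
#'   `implied_sd`, `rel_err_sd`, and logical `pass`.
#' @export
validate_moments <- function(registry, tol_mean = 0.01, tol_sd = 0.05,
                             warn = TRUE) {
  stopifnot(is.data.frame(registry))
  imp <- implied_moments(registry)
  rel_err_mean <- ifelse(registry$mean == 0, abs(imp$mean),
                         abs(imp$mean - registry$mean) / abs(registry$mean))
  rel_err_sd <- ifelse(registry$sd == 0, abs(imp$sd),
                       abs(imp$sd - registry$sd) / abs(registry$sd))
  pass <- rel_err_mean <= tol_mean & rel_err_sd <= tol_sd
  out <- data.frame(name = registry$name,
                    implied_mean = imp$mean, rel_err_mean = rel_err_mean,
                    implied_sd = imp$sd, rel_err_sd = rel_err_sd,
                    pass = pass, stringsAsFactors = FALSE)
  if (warn && any(!pass))
    warning("moment check failed for: ",
            paste(out$name[!pass], collapse = ", "))
  out
}

implied_moments <- function(registry) {
  n <- nrow(registry)
  m <- s <- numeric(n)
  for (i in seq_len(n)) {
    a <- registry$hyper_a[i]; b <- registry$hyper_b[i]
    switch(registry$distribution[i],
      beta = {
        m[i] <- a / (a + b)
        s[i] <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
      },
      gamma = {
        m[i] <- a * b
        s[i] <- sqrt(a) * b
      },
      lognormal = {
        m[i] <- exp(a + b^2 / 2)
        s[i] <- m[i] * sqrt(exp(b^2) - 1)
      },
      fixed = {
        m[i] <- registry$mean[i]
        s[i] <- 0
      },
      stop("unknown distribution: ", registry$distribution[i]))
  }
  list(mean = m, sd = s)
}

check_registry <- function(registry) {
  stopifnot(is.data.frame(registry),
            all(c("name", "mean", "sd", "distribution", "hyper_a",
                  "hyper_b", "group") %in% names(registry)))
  if (anyDuplicated(registry$name))
    stop("duplicate parameter names in registry")
  bad <- !(registry$distribution %in% c("beta", "gamma", "lognormal", "fixed"))
  if (any(bad))
    stop("unknown distribution for: ", paste(registry$name[bad], collapse = ", "))
  for (i in seq_len(nrow(registry))) {
    d <- registry$distribution[i]
    if (d == "fixed") {
      if (registry$sd[i] != 0)
        stop("fixed spec must have sd = 0: ", registry$name[i])
    } else {
      if (!is.finite(registry$hyper_a[i]) ||
          (d != "lognormal" && registry$hyper_a[i] <= 0) ||
          (d != "lognormal" && registry$hyper_b[i] <= 0) ||
          (d == "lognormal" && registry$hyper_b[i] <= 0))
        stop("invalid hyperparameters for spec: ", registry$name[i])
      if (d == "beta" && (registry$mean[i] <= 0 || registry$mean[i] >= 1))
        stop("beta spec must have mean in (0,1): ", registry$name[i])
    }
  }
  invisible(registry)
}

## Deterministic per-parameter substream seed: a root seed plus the parameter
## name yields an independent seed, so adding a parameter never perturbs the
## draws of the others. Plain 31-polynomial string hash mod (2^31 - 1).
substream_seed <- function(seed, name, salt = 0L) {
  h <- 0
  for (byte in utf8ToInt(name)) h <- (h * 31 + byte) %% 2147483647
  as.integer((abs(seed) * 48271 + h * 16807 + salt * 69621) %% 2147483647)
}

#' Sample parameter realizations from the registry
#'
#' `draw_matrix()` samples `n` independent realizations of every registered
#' parameter; `draw()` returns a single realization; `mean_draw()` returns the
#' deterministic realization with every parameter at its registered mean.
#' Sampling is reproducible: each parameter uses its own RNG substream derived
#' from `(seed, name)`.
#'
#' @param registry An `islet_registry`, see [build_default_registry()].
#' @param n Number of realizations.
#' @param seed Integer root seed.
#' @return `draw_matrix()`: an `n x p` numeric matrix with one column per
#'   parameter, attributes `seed` and `kind`. `draw()`/`mean_draw()`: a named
#'   numeric vector with the same attributes (`kind` is `"random"` or
#'   `"mean"`).
#' @export
draw_matrix <- function(registry, n, seed) {
  check_registry(registry)
  stopifnot(n >= 1, is.numeric(seed))
  out <- matrix(NA_real_, nrow = n, ncol = nrow(registry),
                dimnames = list(NULL, registry$name))
  for (i in seq_len(nrow(registry)))
    out[, i] <- sample_spec(registry[i, ], n, substream_seed(seed, registry$name[i]))
  attr(out, "seed") <- seed
  attr(out, "kind") <- "random"
  out
}

sample_spec <- function(spec, n, sub_seed) {
  if (spec$distribution == "fixed") return(rep(spec$mean, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed)
  switch(spec$distribution,
    beta = rbeta(n, spec$hyper_a, spec$hyper_b),
    gamma = rgamma(n, shape = spec$hyper_a, scale = spec$hyper_b),
    lognormal = rlnorm(n, meanlog = spec$hyper_a, sdlog = spec$hyper_b))
}

#' @rdname draw_matrix
#' @export
draw <- function(registry, seed) {
  m <- draw_matrix(registry, 1, seed)
  structure(m[1, ], seed = seed, kind = "random")
}

#' @rdname draw_matrix
#' @export
mean_draw <- function(registry) {
  check_registry(registry)
  structure(setNames(registry$mean, registry$name), kind = "mean")
}

resolve_group <- function(registry, group) {
  if (length(group) == 1 && group %in% PARAM_GROUPS)
    registry$name[registry$group == group]
  else if (all(group %in% registry$name) || length(group) == 0)
    group
  else stop("unknown group or parameter names: ",
            paste(setdiff(group, registry$name), collapse = ", "))
}

#' Conditional draws for the inner loop of partial-information analysis
#'
#' Parameters in `group` are fixed at the values given in `outer_values`;
#' every other parameter is freshly sampled. This is the inner-loop contract
#' of the nested two-level EVPPI estimator: the outer loop resolves the group,
#' the inner loop integrates over the remaining uncertainty.
#'
#' @inheritParams draw_matrix
#' @param group One of `"costs"`, `"natural_history"`,
#'   `"effectiveness_safety"`, or a character vector of parameter names
#'   (possibly empty, in which case the result is distributed as [draw()]).
#' @param outer_values A named numeric vector (e.g. one row of
#'   [draw_matrix()]) providing the fixed values for `group`.
#' @return `partial_draw()`: a named numeric vector; `partial_draw_matrix()`:
#'   an `n x p` matrix.
#' @export
partial_draw_matrix <- function(registry, group, outer_values, n, seed) {
  members <- resolve_group(registry, group)
  m <- draw_matrix(registry, n, seed)
  for (nm in members) {
    if (!nm %in% names(outer_values))
      stop("outer_values missing parameter: ", nm)
    m[, nm] <- outer_values[[nm]]
  }
  m
}

#' @rdname partial_draw_matrix
#' @export
partial_draw <- function(registry, group, outer_values, seed) {
  m <- partial_draw_matrix(registry, group, outer_values, 1, seed)
  structure(m[1, ], seed = seed, kind = "random")
}

#' Read or write a registry as CSV
#'
#' The on-disk schema is one row per parameter with columns
#' `name,mean,sd,distribution,hyper_a,hyper_b,group,role`. The default
#' registry ships at `system.file("extdata", "parameters.csv",
#' package = "isletcea")`; a user-supplied file in the same schema can replace
#' it anywhere a registry is accepted.
#'
#' @param path File path.
#' @param registry Registry to serialize.
#' @return `read_registry()` returns an `islet_registry`.
#' @export
read_registry <- function(path) {
  reg <- read.csv(path, stringsAsFactors = FALSE)
  reg <- structure(reg, class = c("islet_registry", "data.frame"))
  check_registry(reg)
  reg
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  write.csv(as.data.frame(registry), path, row.names = FALSE)
  invisible(path)
}
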