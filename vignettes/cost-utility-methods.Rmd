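---
title: "Methods: the islet transplantation cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the islet transplantation cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletcea)
```

## The decision problem

Adults with "unstable" type 1 diabetes -- hypoglycemia unawareness with
recurrent, potentially fatal severe hypoglycemia despite optimized intensive
insulin therapy (IIT) -- can be stabilized by allogeneic islet cell
transplantation: donor islets are infused into the liver, restoring
endogenous insulin secretion for as long as the graft survives, at the price
of lifelong immunosuppression and a costly procedure that often has to be
repeated (up to four times per patient). `isletcea` implements a cost-utility
comparison of transplantation versus IIT from a provincial healthcare payer
perspective, in 2012 Canadian dollars, over the remaining lifetime of a
cohort starting at age 47 (55 % female), together with probabilistic
sensitivity analysis (PSA) and value-of-information (VOI) analysis.

## Model structure

The engine is a discrete-time Markov cohort model with cycles of 1/16 year
(~23 days) over 1000 cycles (62.5 years). The transplantation arm has six
base states: *Transplantation* (one cycle per procedure), *Full graft
function* (insulin independent), *Partial graft function* (insulin dependent,
C-peptide positive), *IIT without diabetes-related complications (DRC)*,
*IIT with DRC*, and *Dead*. The comparator arm uses only the last three.
Because transition behaviour depends on how many transplantations a patient
has had and on the time since the latest one, the engine expands the state
space: `T(k)` for the k-th transplant, `F(k,c)` / `P(k,c)` for graft states
`c` cycles after that transplant, with `c` capped at `first_phase_cycles + 1`
(the pooled "after six months" slot, with 8 cycles ~ 183 days as the early
phase). This keeps the Markov property while tracking the six-month
high-cost/high-failure phase per transplantation episode.

Transition rules per cycle, with competing risks composed in the fixed order
*death, then DRC, then immunosuppression-stopping complications, then graft
events* (the residual mass stays):

* `T(k)`: death at background mortality; DRC at the unprotected rate
  (0.0018185/cycle); otherwise full graft function with probability 0.15 /
  0.70 / 0.85 / 0.85 for the 1st--4th transplant, else partial function.
  Direct movement to IIT-without-complications is impossible.
* `F(k,c)`: background death; DRC at hazard ratio 0.25 (i.e. 55.56 % of the
  partial-graft hazard ratio 0.45); major immunosuppressive complications
  (0.00006201/cycle), 10 % of which force immunosuppression stop and graft
  loss; loss of insulin independence to partial function (0.0077379/cycle);
  rare outright graft failure (1.65e-5/cycle).
* `P(k,c)` in the first six months: those who neither die, develop DRC, nor
  fail early (0.045/cycle) are re-transplanted in the next cycle while
  fewer than four transplants have been used; at the fourth transplant the
  patient remains partial under the late failure rate.
* `P(k,after)`: stays, or fails at 0.00532/cycle.
* Graft failures split between the two IIT states in proportion to the
  concurrent DRC hazard.
* `IIT_N`: mortality at hazard ratio 2.40 (hypoglycemia); DRC at
  0.0018185/cycle. `IIT_D`: mortality at hazard ratio 7.16 (2.9845 times
  the hypoglycemia ratio); only death can follow.

All hazard-ratio applications are on the hazard scale,
`q' = 1 - (1 - q)^HR`, which commutes with the annual-to-cycle conversion
`q_c = 1 - (1 - q)^(1/16)`.

## Rewards, half-cycle correction and discounting

Per-cycle ("membership") costs and utilities are valued at mid-cycle
occupancy -- the average of beginning- and end-of-cycle state vectors -- and
discounted at `(1+r)^(-(i-0.5)/16)` with 5 % per year in the base case. This
is the trapezoid form of the half-cycle correction, applied to every cycle
including the first and last.

One-time event rewards are deliberately *not* averaged: the total cost per
transplantation (94,765 CAD, covering the procedure and all costs in its
23-day cycle), the one-off pre-transplant visit (569 CAD, first transplant),
expected basiliximab (0.5 x 3000 CAD, second transplant), and the expected
initial-complication cost (0.65 x 600 CAD) and disutility (0.65 x 0.05) are
applied to the full probability mass entering the transplantation state at
the time of entry. Halving these through mid-cycle averaging would halve
every transplantation's cost, which is inconsistent with the per-procedure
totals the cost data define. Major immunosuppressive complications are
handled as expected per-cycle event costs (6500 CAD) and disutilities (0.10)
on the graft-state event mass.

State costs are composed from the sampled components so that uncertainty
propagates: graft survival after six months costs immunosuppression (713.5
CAD/cycle branded, 238.1 generic) plus the annualized follow-up visit
(556/16); the first six months add a component scaled to the valganciclovir
course so the means reconcile to the printed 1886/747 (full) and 1950/811
(partial) totals, with partial states carrying 40 % of the IIT cost as
insulin; IIT states cost 159 (no DRC) and 602 (DRC) per cycle. Utilities
form an incremental decrement chain from full graft function: 0.82, minus
0.01 (partial), minus 0.10 (IIT, hypoglycemia unawareness), minus 0.14
(DRC), giving 0.81 / 0.71 / 0.57 annual. The transplantation cycle carries
the IIT utility for the first transplant and the partial-graft utility for
re-transplants. The doubled-disutility scenario subtracts each IIT-state's
own decrement a second time (0.61 and 0.43 annual).

## Parameters and sampling

`build_default_registry()` holds every distribution specification: Beta for
probabilities and shares, Gamma (shape/scale, so the mean is alpha x beta)
for costs and utility decrements with heavier tails, Log-Normal for costs
and hazard ratios, and fixed point masses where no uncertainty was assigned.
`validate_moments()` recomputes every implied mean and SD from the
hyperparameters and flags deviations beyond 1 %; the shipped registry passes
for all rows. Two transcription choices worth noting: the valganciclovir and
anakinra rows are read as mean 5000 / SD 375 and mean 574 / SD 43 (the 7.5 %
relative-SD column pins the split), and the nested hazard ratios are sampled
as a base draw times a ratio draw, each from its own printed log-normal
(0.45 x 0.5556 -> 0.25 for DRC protection; 2.40 x 2.9845 -> 7.16 for DRC
mortality), reproducing the intended correlation between the two steps.

Sampling uses one root seed with per-parameter substreams derived from
`(seed, name)`, so draws are reproducible, scenarios sharing a seed use
common random numbers wherever specifications coincide (scenario contrasts
are low-variance; the generic-pricing scenario changes cost columns only),
and adding a parameter never perturbs the others' draws.

## Background mortality: the synthetic life table

The only model input not available as a printed table is sex-weighted
background mortality. `build_background_lifetable()` synthesizes it as a
Gompertz-Makeham schedule -- annual hazard `5e-4 + level * exp(0.10 * (age -
47))` -- with the single `level` coefficient calibrated by root finding so
that remaining life expectancy at 47 equals 84.2 - 47 = 37.2 years, the
published non-diabetic anchor. The resulting schedule is realistic for a
contemporary Canadian population (q about 0.002 at 47, 0.011 at 67, 0.078 at
87), but it is *not* the province's actual life table: quantities that
depend on the shape of the survival curve beyond its mean -- discounted life
years, and through them the ICER and the tails of the net-benefit
distribution -- inherit a deviation of a few percent that no calibration of
the level term can remove. Passing tests therefore demonstrate agreement
with the published analysis up to this bounded life-table substitution, not
exact replication of the original implementation. A real life table in
two-column CSV form can be substituted via `read_lifetable()`.

With the printed hazard ratios the IIT arm reaches a total life expectancy
of 71.9 years against the assumed 72.2 (12-year difference), well within the
0.5-year tolerance we regard as acceptable. Scenarios assuming 10- or
14-year differences bisect a common multiplier on both mortality hazard
ratios (`calibrate_le_difference()`; 0.745 and 1.243 respectively) so the
comparator arm lands exactly on 74.2 or 70.2 total years. The base case
keeps the printed ratios unmultiplied: recalibrating it to exactly 72.2 was
examined and moved the cost-utility results *away* from the published
values, so the printed ratios are treated as the primary inputs.

Five-year graft survival at the printed transition probabilities comes out
at 52.6 % full function and 83.8 % overall against the 50 % / 82 % source
rates -- within the 5-point check we apply -- and
`calibrate_graft_transitions()` reports the common multiplier (1.09) that
would hit the full-function target exactly. It is reported, not applied: the
base case uses the printed probabilities.

## PSA, scenario grid and value of information

`run_psa()` propagates parameter uncertainty with a default of 10,000 draws
(the engine, written in C++ with a reduced recursion once the
re-transplantation transient has emptied, runs this in under a second). The
ICER is computed from the expectations over draws. `ceac()` / `ceaf()` give
the acceptability curve and frontier, `nbpm()` the deciles of cumulative net
health benefit at 2.5-year checkpoints, `evpi()` the per-patient and
population expected value of perfect information (population factor 5140
patients, scenario-configurable), and `evppi_nested()` the traditional
two-level nested Monte Carlo EVPPI with 600 outer x 600 inner loops and
common random numbers across options. The three default parameter groups
follow the data-collection-vehicle logic: *costs* (all cost rows), *natural
history* (DRC incidence and the mortality hazard ratios), *effectiveness
and safety* (graft-function and complication probabilities plus utilities);
the exact membership used originally is not recoverable from the published
text, so the assignment is an explicit, overridable default, and the
resulting split of value across groups is the model's own.

The 18-row scenario grid (`run_table4()`) covers discount rates 0--5 %,
life-year outcomes, doubled IIT disutilities, generic immunosuppression
(one third of the branded price), a $20,000 per-transplant cost reduction,
and 1.10x / 1.25x IIT/DRC cost multipliers, and appends the published
reference values shipped in `inst/extdata/table4_reference.csv` for a
column-by-column comparison. With 10,000 draws all 18 ICERs reproduce within
about 10 %.

## Numerical choices and degenerate inputs

Occupancy conservation is asserted every cycle (tolerance 1e-8) and the
engine aborts on any leak; probabilities are validated into [0,1], costs
must stay non-negative after scenario overrides, and utilities within
[-1, 1]. A zero horizon returns zero totals. The engine is cross-checked to
machine precision against an independent pure-R matrix runner built from
`transition_row()`, and against a 200,000-walker microsimulation oracle on
the three-state comparator chain. Life-table calibration and all scenario
calibrations use `uniroot` with explicit brackets and abort with diagnostics
if no sign change exists.

## Known limitations

* The background life table is synthetic (see above); headline central
  estimates carry a few percent of deviation and kink-sensitive quantities
  (EVPI near the base-case willingness-to-pay, acceptability-curve tails)
  inherit more.
* Parameter correlation is limited to the two nested hazard-ratio products
  and the compositional cost structure, mirroring the source analysis.
* Rising IIT costs over time are represented by the 1.10/1.25 multipliers
  rather than tunnel states; the hypothetical no-immunosuppression scenario
  is runnable but has no published comparator.
* No individual-level simulation path is provided; the cohort engine is the
  production path, with microsimulation used only as a test oracle.
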