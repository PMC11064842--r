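---
title: "A Markov cohort model for thrombectomy in large-core stroke: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for thrombectomy in large-core stroke: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`evtcea` estimates lifetime costs and quality-adjusted life years (QALYs)
of endovascular thrombectomy (EVT) versus best medical care (BMC) in acute
ischemic stroke with large infarct cores. This vignette is the package's
account of the model itself: its structure and assumptions, the parameters
that matter, the places where the design was genuinely open and what we
chose, and what the synthetic-data generator does and does not emulate.

## Model structure

The unit of analysis is a cohort characterised by its 90-day modified
Rankin Scale (mRS) distribution — a probability vector over seven states,
mRS 0 (no symptoms) through mRS 5 (severe disability) plus absorbing death.
The cohort starts at age 67 (the average inclusion age of the underlying
trials; configurable) and is evolved through annual cycles until the
life-table terminal age or until the surviving fraction falls below
`1e-9`.

Within a cycle, each surviving state faces two competing events:

* **Death.** The annual life-table probability `qx(age)` is multiplied by a
  per-mRS hazard ratio and clamped at 1. Multiplication of the annual
  *probability* is the default because that is how the combination is
  conventionally described; it is an approximation that degrades as
  `qx · HR` approaches 1, so a rate-scale alternative
  `1 − (1 − qx)^HR` (exact under proportional hazards within the year) is
  available via `markov_inputs(hr_method = "rate")`.
* **Recurrent stroke.** Year-specific probabilities for years 1–10 after
  the index stroke; beyond year 10 the year-10 value (0.016) is carried
  forward by default — the sources are silent there, a constant tail is the
  least-structured extrapolation, and the value is configurable
  (`recurrence_after_year10`). A recurrent stroke redistributes the patient
  over the outcome categories (mRS 0-or-1, 2, 3, 4, 5, death) under a
  **no-improvement rule**: the post-stroke state is the maximum (worse) of
  the current state and the drawn outcome. A second stroke plausibly cannot
  restore function, and the alternative literal reading (improvement to a
  lower mRS) would contradict the deterioration the recurrence event is
  meant to model. The combined "mRS 0 or 1" category maps to mRS 1 — the
  conservative single-state choice; it only affects patients currently at
  mRS 0.

Events are ordered **death first, then recurrence among survivors**
(standard cohort-model practice; recurrence-related death is already
carried by the fatal outcome category). The reverse ordering — recurrence
first, with that year's mortality applied to the post-recurrence state — is
available via `event_order = "recurrence_first"`; for realistic parameter
values the two differ by well under a percent of lifetime totals.

## Rewards and discounting

Cycle 0 represents the first 365 days: it accrues the per-mRS acute
first-year cost, the one-off EVT procedure cost (for the EVT strategy,
charged once to the whole cohort), and the utilities of the 90-day
distribution, undiscounted. Every later cycle `t` accrues per-mRS
maintenance costs, an acute recurrent-stroke cost per incident recurrence
in that cycle (once per event, additive to maintenance), and utilities,
all multiplied by `(1 + r)^(-t)` with `r = 0.03`/year for both costs and
effects. Patients dead at 90 days accrue nothing — whether they should
carry acute costs is unknowable from the available sources, and zero is the
conservative default.

No half-cycle correction is applied by default: the convention the model
mirrors makes no mention of one, and annual cycles with cycle-0 rewards
tied to the 90-day distribution leave little room for it. An optional
variant (`half_cycle = TRUE`) accrues later-cycle rewards on mid-cycle
occupancy, the mean of the start- and end-of-cycle distributions.

Utilities are `(1.00, 0.91, 0.76, 0.65, 0.33, 0.00)` for mRS 0–5, with
death fixed at 0 — the published seven-value quality-of-life row, read as
six living-state weights plus the death anchor.

## Cost-effectiveness comparison

Incremental cost ΔC and effectiveness ΔE are always EVT minus BMC. The
classification is quadrant-aware: a QALY gain at lower cost is *dominant*
and its ICER is reported as the sentinel `"cost saving"`, never as a
(negative, meaningless) number; a QALY gain at extra cost yields
`ICER = ΔC/ΔE`, cost-effective iff at or under the willingness-to-pay
threshold (default $100,000/QALY); losses at extra cost are *dominated*;
the rare south-west quadrant reports the ICER but flags it, since its
decision rule is reversed. Net monetary benefit `ΔE·λ − ΔC` is always
computed. Dollars are rounded to integers and QALYs to two decimals only in
the reporting layer; all arithmetic is double precision.

`check_cea_table()` recomputes a table's incremental columns from its
per-strategy totals and flags disagreements above $1 or 0.01 QALY. It
exists because published comparison tables are not always internally
consistent; the package surfaces such discrepancies rather than silently
fixing either number.

## Sensitivity analysis

**Deterministic (tornado).** Each cost parameter in turn is set to
`(1 ± 0.25)` times base, everything else fixed, and the incremental-cost
swing recorded; rows sort by swing width with a name tie-break so the
ordering is reproducible. Only cost fields may be varied here, matching
the ±25 % cost-variation design; whole cost categories scale as a vector,
or single elements by index (`"first_year_cost_by_mrs[4]"`).

**Probabilistic.** Only the beta family for utilities is externally fixed;
everything else about the PSA design was open, and the defaults are the
package's own assumptions, all configurable via `param_dist()`:

| parameter group | distribution | spread default | rationale |
|---|---|---|---|
| utilities (0 < u < 1) | beta, method of moments | sd = 0.10 × mean | conventional support-respecting choice |
| all costs (> 0) | gamma, method of moments | sd = 0.25 × mean | matches the ±25 % deterministic range |
| recurrent-outcome distribution | Dirichlet | effective sample size 500 | simplex-respecting, moderate confidence |

Boundary utilities (0, 1) and zero costs are held fixed — a beta or gamma
with that mean is degenerate. Drawn utilities are sorted into
non-increasing order so every sampled set satisfies severity monotonicity;
this slightly tightens the marginal spread of adjacent utilities but keeps
every draw a valid parameter set. Per-iteration seeds are derived
deterministically from one root seed, so results are independent of
evaluation order and reproducible by construction. Transition probabilities
other than the recurrent-outcome simplex are not varied by default.

## Numerical contract

* State distributions must sum to 1 within `1e-9` at construction and after
  every transition; the engine renormalises nothing.
* Death probability is clamped to [0, 1] after the hazard-ratio product.
* The life table must cover contiguous integer ages and end in `qx = 1`,
  so the cohort cannot outlive it; runs also stop when the alive mass
  drops below `1e-9`.
* Cohort totals equal their per-cycle trace sums to `1e-6` relative.
* Hazard ratios are **required inputs with no shipped defaults** on the
  analysis path: the available printed row for them duplicates the
  recurrent-outcome row and is uniformly below 1, which is implausible for
  survivor mortality and is treated as a typesetting corruption, not data.

## The synthetic-scenario generator

Published inputs pin down: the mRS 0–3 share per trial arm (37.9 %/17.9 %
SELECT2, 47 %/33.3 % ANGEL-ASPECT, 31 %/12.7 % RESCUE-Japan LIMIT — stored
verbatim, including the mixed precision), arm sizes (231/178/100
intervention; comparator = totals − intervention), the recurrence schedule,
the recurrent-outcome distribution, the utilities, the discount rate, the
WTP threshold, and one cost anchor: the EVT procedure cost whose +25 %
bound is $21,379, i.e. base $17,103.20. Everything else is generated:

* **Within-block mRS composition** — flat Dirichlet draws inside the
  mRS 0–3 block and the mRS 4/5/dead block, scaled to the printed shares.
  Real trial distributions are not flat within blocks; fixed profiles can
  be supplied (`within =`) for regression-stable fixtures.
* **Life table** — Gompertz, `qx(a) = 1 − exp(−a₀ e^{b·a})` with
  `a₀ = 1e-4`, `b = 0.09` (hazard doubling roughly every 8 years, ~4 %/year
  at 67), terminal age 100 forced to `qx = 1`. A real national life table
  can be supplied as an `age,qx` CSV.
* **Hazard ratios** — drawn non-decreasing in severity from ~1.2–1.8 at
  mRS 0 up to a multiplicative build-out at mRS 5, the range survivor
  studies typically report.
* **Costs** — severity-monotone first-year (≈ $20–35k base) and long-term
  annual (≈ $1.5–5k base, climbing steeply toward institutional-care
  levels) vectors and a recurrent-stroke acute cost, at plausible US
  stroke-care scales.

Consequently, passing tests show that the *machinery* is correct —
conservation, absorption, discounting, classification, reproducibility,
agreement with an independent microsimulation — not that any particular
dollar figure generalises to real payer data. Base-case totals from
synthetic scenarios move with the seed by design; only the printed anchors
above are invariant.

## Verification problem sizes

The test suite checks conservation and absorption across 1,000 randomly
generated scenarios; cross-validates the cohort engine against an
independently coded individual-level microsimulation of 200,000 patients
per strategy on three scenarios (agreement within 0.5 % relative);
exercises a 2,000-iteration PSA on a constructed strictly dominant scenario
(100 % cost-effective, as the construction guarantees); and verifies
zero-variance PSA degeneracy bit-exactly. The reproduction script runs a
3,000-iteration PSA — enough for the acceptability fractions it reports to
be stable to well under a percentage point, while keeping a full run fast
on one core.

## Known limitations

* Annual cycles cannot resolve within-first-year dynamics; outcome is
  frozen at the 90-day mRS with no later spontaneous change except via
  recurrence.
* Intracerebral hemorrhage and other complications are not separate
  states; they are folded into the 90-day outcome.
* Costs are USD-2022 and no within-tool inflation or country transfer is
  performed; inputs must arrive already adjusted.
* The probability-scale hazard-ratio default can saturate (clamp at 1) at
  very old ages with large ratios; use the rate-scale option if that
  matters for your inputs.
* Multi-way comparisons (> 2 strategies, efficiency frontiers, extended
  dominance chains) are out of scope.
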