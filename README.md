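# evtcea

Lifetime cost-effectiveness modelling of **endovascular thrombectomy (EVT)**
versus **best medical care (BMC)** for acute ischemic stroke with a large
infarct core, from a US health-payer perspective.

Recent randomised trials (ANGEL-ASPECT, SELECT2, RESCUE-Japan LIMIT) showed
that thrombectomy improves 90-day functional outcome even in patients with
large established infarcts — a group historically excluded from EVT. Whether
the expensive acute procedure pays for itself over a patient's remaining
lifetime is a health-economic question: better functional outcome (a lower
modified Rankin Scale, mRS) means cheaper long-term care and more
quality-adjusted life years (QALYs), but also longer survival over which
care costs accrue. `evtcea` implements the standard decision-analytic
machinery to answer it, for health-economics researchers and modellers.

## The model

A **Markov cohort model** with annual cycles tracks a probability
distribution over seven health states — mRS 0–5 plus death — from the
90-day outcome of each trial arm to cohort extinction (terminal life-table
age 100, inclusion age 67). Each cycle, a patient in state *s* at age *a*:

1. dies with probability `min(1, qx(a) · HR(s))`, the life-table annual
   mortality scaled by a per-mRS hazard ratio (a rate-scale transform
   `1 − (1 − qx)^HR` is available as an option);
2. if surviving, suffers a recurrent stroke with the year-specific
   probability `p_rec(t)` (years 1–10 tabulated; carried forward
   thereafter), redistributing over the recurrent-outcome categories with
   **no functional improvement**: post-state = max(current, drawn outcome);
3. otherwise remains in state.

Rewards per cycle: state utilities `u(s)` accrue QALYs; the first model year
accrues per-mRS acute costs plus the one-off EVT procedure cost; later years
accrue per-mRS maintenance costs plus an acute cost per incident recurrent
stroke. Costs and QALYs are discounted at 3 %/year (cycle *t* divided by
`(1+r)^t`; cycle 0 undiscounted).

Strategies are compared by incremental cost-effectiveness ratio and net
monetary benefit at a willingness-to-pay threshold λ = $100,000/QALY:

```
ICER = (C_EVT − C_BMC) / (E_EVT − E_BMC),    NMB = ΔE·λ − ΔC
```

with quadrant-aware classification (a strategy that gains QALYs *and* saves
money is *dominant* — reported as "cost saving", not as a number).
Uncertainty is handled by one-way ±25 % deterministic cost variation
(tornado) and probabilistic sensitivity analysis (beta-distributed
utilities, gamma-distributed costs, Dirichlet recurrent-outcome
distribution), summarised on the cost-effectiveness plane and as a CEAC.

Because the underlying trial publications report only the mRS 0–3 dichotomy
(and per-mRS cost sources are not reproduced in machine-readable form), the
package ships a **seeded synthetic-scenario generator** that fills in the
unpublished detail under the published constraints — see
`vignettes/stroke-cea-model.Rmd` for exactly what is anchored and what is
synthetic.

## Worked example

```r
library(evtcea)

sc <- synth_scenario(seed = 42)   # complete scenario, all randomness seeded
an <- run_scenario(sc)            # per-trial + pooled base-case CEA
an
```

```
Lifetime cost-effectiveness: EVT vs BMC
  WTP $100,000/QALY | discount 3.0%/yr | start age 67

             Cohort Cost BMC Cost EVT Incr.Cost QALY BMC QALY EVT Incr.QALY         ICER
       ANGEL-ASPECT $180,273 $204,338  $ 24,065     2.16     2.93      0.77 $31,126/QALY
            SELECT2 $183,968 $133,895  $-50,073     0.76     2.54      1.78  cost saving
 RESCUE-Japan LIMIT $ 99,475 $203,796  $104,321     0.91     2.35      1.43 $72,850/QALY
             Pooled $164,975 $179,597  $ 14,622     1.42     2.68      1.26 $11,590/QALY
```

Each row compares the two strategies started from that cohort's 90-day mRS
distribution: discounted lifetime cost and QALYs per strategy, their
differences, and the ICER (or the dominance sentinel). Here, with this
seed's synthetic costs, the pooled cohort gains 1.26 QALYs at $14,622 extra
cost — an ICER of $11,590/QALY, well under the threshold — and the SELECT2
cohort is outright cost saving. Sensitivity analysis:

```r
evt <- pool_arms(unname(lapply(sc$trials, `[[`, "EVT")))
bmc <- pool_arms(unname(lapply(sc$trials, `[[`, "BMC")))
psa <- run_psa(evt, bmc, sc$transition, sc$economics, n = 3000, seed = 42)
tor <- one_way_dsa(evt, bmc, sc$transition, sc$economics)
plot(psa)   # cost-effectiveness plane
plot(tor)   # tornado diagram
```

`write_results()` exports everything (CEA table, cycle traces, PSA points,
CEAC, tornado, hashed run manifest) as CSV/JSON; `load_scenario()` /
`write_scenario()` round-trip scenario configurations through YAML or JSON;
`inst/cli/evtcea` wraps it all as a shell tool
(`evtcea synth|run|dsa|psa|validate`).

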