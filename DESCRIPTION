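Package: evtcea
Title: Lifetime Cost-Effectiveness of Endovascular Thrombectomy in
    Large-Core Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markov cohort model comparing endovascular thrombectomy (EVT)
    against best medical care (BMC) for acute ischemic stroke with large
    infarct cores. Evolves a modified Rankin Scale (mRS) state distribution
    over annual cycles from the 90-day outcome to cohort extinction,
    accumulating discounted lifetime costs and quality-adjusted life years
    (QALYs). Provides incremental cost-effectiveness comparison (ICER,
    dominance classification, net monetary benefit), deterministic (tornado)
    and probabilistic (Monte Carlo) sensitivity analysis with
    cost-effectiveness plane and acceptability-curve exports, a seeded
    generator of internally consistent synthetic scenarios (constrained mRS
    distributions, Gompertz life tables, plausible cost sets), trial pooling,
    and a YAML/JSON scenario configuration layer with validation, CSV/JSON
    result writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
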