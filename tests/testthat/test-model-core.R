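test_that("death probability combines life-table mortality and hazard ratio", {
  mi <- basic_inputs(qx = 0.02, hr = c(1.5, 1, 2, 3, 4, 5))
  expect_equal(death_probability(70, "mRS0", mi), 0.03)
  expect_equal(death_probability(70, "mRS1", mi), 0.02)   # HR = 1 identity

  hi <- basic_inputs(qx = 0.9, hr = rep(2, 6))
  expect_equal(death_probability(50, "mRS3", hi), 1)      # clamped at 1

  # rate-scale alternative: 1 - (1 - q)^HR
  rt <- basic_inputs(qx = 0.1, hr = rep(2, 6), hr_method = "rate")
  expect_equal(death_probability(60, "mRS2", rt), 1 - 0.9^2)

  expect_error(death_probability(70, "DEAD", mi), "DEAD")
  expect_error(death_probability(200, "mRS0", mi), "200")
})

test_that("recurrence schedule is year-specific with carry-forward beyond year 10", {
  mi <- basic_inputs()
  expect_equal(recurrence_probability(1, mi), 0.059)
  expect_equal(recurrence_probability(10, mi), 0.016)
  expect_equal(recurrence_probability(15, mi), 0.016)
  mi2 <- basic_inputs(recurrence_after_year10 = 0.02)
  expect_equal(recurrence_probability(30, mi2), 0.02)
  expect_error(recurrence_probability(0, mi), ">= 1")
  expect_error(recurrence_probability(-3, mi), ">= 1")
})

test_that("recurrent-stroke outcomes never improve the current state", {
  mi <- basic_inputs()
  # hand-collapsed published row for a patient currently mRS3
  out3 <- apply_recurrent_stroke("mRS3", mi)
  expect_equal(as.numeric(out3),
               c(0, 0, 0, 0.129 + 0.136 + 0.164, 0.247, 0.135, 0.189))
  # worst surviving state: all non-fatal mass collapses onto mRS5
  out5 <- apply_recurrent_stroke("mRS5", mi)
  expect_equal(as.numeric(out5), c(0, 0, 0, 0, 0, 0.811, 0.189))
  # the combined mRS 0-or-1 category maps to mRS1 for a current mRS0 patient
  out0 <- apply_recurrent_stroke("mRS0", mi)
  expect_equal(as.numeric(out0),
               c(0, 0.129, 0.136, 0.164, 0.247, 0.135, 0.189))
  expect_equal(sum(out0), 1)
  expect_error(apply_recurrent_stroke("DEAD", mi), "DEAD")
})

test_that("single-cycle transitions handle absorbing, null and pure-mortality cases", {
  mi0 <- null_event_inputs()
  dead <- mrs_distribution(c(0, 0, 0, 0, 0, 0, 1))
  expect_equal(as.numeric(step_cycle(dead, 70, 1, mi0)), as.numeric(dead))

  well <- mrs_distribution(c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(step_cycle(well, 70, 1, mi0)), as.numeric(well))

  mort <- markov_inputs(rep(0, 10), rep(1, 6), OUTCOME_DIST,
                        flat_life_table(0.1))
  stepped <- step_cycle(well, 70, 1, mort)
  expect_equal(as.numeric(stepped), c(0.9, 0, 0, 0, 0, 0, 0.1))
  expect_equal(attr(stepped, "recurrence_mass"), 0)

  expect_error(step_cycle(c(0.5, 0, 0, 0, 0, 0, 0), 70, 1, mi0), "sum to 1")
})

test_that("transitions conserve probability and death is absorbing", {
  set.seed(42)
  for (i in 1:50) {
    mi <- basic_inputs(qx = runif(1, 0, 0.3),
                       hr = sort(runif(6, 1, 6)),
                       event_order = sample(c("death_first",
                                              "recurrence_first"), 1))
    d <- random_dist()
    for (t in 1:5) {
      d2 <- step_cycle(d, 60 + t, t, mi)
      expect_lt(abs(sum(d2) - 1), 1e-9)
      expect_gte(d2[["DEAD"]], d[["DEAD"]] - 1e-12)
      d <- d2
    }
  }
})

test_that("a zero-event unit-utility cohort returns the discounted annuity", {
  well <- mrs_distribution(c(1, 0, 0, 0, 0, 0, 0))
  res <- run_strategy(well, "BMC", null_event_inputs(), null_cost_econ(0.03),
                      start_age = 67, horizon = 3)
  expect_equal(res$total_qalys, sum(1.03^-(0:2)), tolerance = 1e-12)
  expect_equal(res$total_cost, 0)
  # and for a range of horizons and rates
  for (H in c(1, 5, 20)) {
    for (r in c(0, 0.03, 0.1)) {
      res <- run_strategy(well, "BMC", null_event_inputs(), null_cost_econ(r),
                          horizon = H)
      expect_equal(res$total_qalys, sum((1 + r)^-(0:(H - 1))),
                   tolerance = 1e-9)
    }
  }
})

test_that("cohort runs accrue rewards per state with correct edge handling", {
  # all dead at baseline: nothing accrues
  dead <- mrs_distribution(c(0, 0, 0, 0, 0, 0, 1))
  res <- run_strategy(dead, "BMC", basic_inputs(), basic_econ())
  expect_equal(res$total_cost, 0)
  expect_equal(res$total_qalys, 0)

  # one undiscounted cycle, half mRS0 / half mRS5 with published utilities
  half <- mrs_distribution(c(0.5, 0, 0, 0, 0, 0.5, 0))
  res1 <- run_strategy(half, "BMC", null_event_inputs(),
                       null_cost_econ(0, utilities = UTILITIES), horizon = 1)
  expect_equal(res1$total_qalys, 0.5)

  # totals equal the sums over the trace
  res2 <- run_strategy(even_dist(), "EVT", basic_inputs(), basic_econ())
  expect_equal(res2$total_cost, sum(res2$trace$cost_disc), tolerance = 1e-6)
  expect_equal(res2$total_qalys, sum(res2$trace$qaly_disc), tolerance = 1e-6)
  expect_true(all(diff(res2$trace$DEAD) > -1e-12))
  # discounted per-cycle rewards never exceed undiscounted ones
  expect_true(all(res2$trace$cost_disc <= res2$trace$cost + 1e-12))
  expect_true(all(res2$trace$qaly_disc <= res2$trace$qaly + 1e-12))

  expect_error(run_strategy(even_dist(), "BMC", basic_inputs(), basic_econ(),
                            horizon = 0), "horizon")
  expect_error(econ_params(UTILITIES, rep(0, 6), rep(0, 6), 0, 0, -0.01),
               "discount_rate")
})

test_that("EVT and BMC agree exactly when the procedure cost is zero", {
  ec <- basic_econ()
  ec0 <- econ_params(ec$utilities, ec$first_year_cost_by_mrs,
                     ec$longterm_annual_cost_by_mrs, 0,
                     ec$recurrent_stroke_acute_cost, ec$discount_rate)
  d <- gen_mrs_distribution(0.4, seed = 9)
  evt <- run_strategy(d, "EVT", basic_inputs(), ec0)
  bmc <- run_strategy(d, "BMC", basic_inputs(), ec0)
  expect_identical(evt$total_cost, bmc$total_cost)
  expect_identical(evt$total_qalys, bmc$total_qalys)
  expect_identical(evt$trace$cost, bmc$trace$cost)
})

test_that("discounting is monotone: higher rates never increase totals", {
  d <- gen_mrs_distribution(0.35, seed = 3)
  rates <- c(0, 0.01, 0.03, 0.06, 0.1)
  ec <- basic_econ()
  runs <- lapply(rates, function(r) {
    run_strategy(d, "BMC", basic_inputs(),
                 econ_params(ec$utilities, ec$first_year_cost_by_mrs,
                             ec$longterm_annual_cost_by_mrs,
                             ec$evt_procedure_cost,
                             ec$recurrent_stroke_acute_cost, r))
  })
  costs <- vapply(runs, `[[`, numeric(1), "total_cost")
  qalys <- vapply(runs, `[[`, numeric(1), "total_qalys")
  expect_true(all(diff(costs) <= 1e-9))
  expect_true(all(diff(qalys) <= 1e-9))
})

test_that("the cohort is fully absorbed by the terminal age", {
  d <- gen_mrs_distribution(0.5, seed = 5)
  res <- run_strategy(d, "BMC", basic_inputs(qx = 0.01, hr = rep(1.2, 6)),
                      basic_econ(), start_age = 90)
  tr <- res$trace
  expect_lt(1 - tr$DEAD[nrow(tr)], 1e-9)
  expect_lte(tr$age[nrow(tr)], 101)
})

test_that("half-cycle correction uses mid-cycle occupancy and lowers later-cycle rewards", {
  d <- gen_mrs_distribution(0.5, seed = 11)
  mi <- basic_inputs(qx = 0.05)
  plain <- run_strategy(d, "BMC", mi, null_cost_econ(0), horizon = 10)
  hc <- run_strategy(d, "BMC", mi, null_cost_econ(0), horizon = 10,
                     half_cycle = TRUE)
  # with a shrinking alive fraction, averaging start/end occupancy adds back
  # half of each cycle's survivors, so totals increase
  expect_gt(hc$total_qalys, plain$total_qalys)
  # cycle 0 is unaffected by the correction
  expect_equal(hc$trace$qaly[1], plain$trace$qaly[1])
})
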