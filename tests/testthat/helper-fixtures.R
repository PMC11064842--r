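# deterministic building blocks used across test files

# flat life table: constant qx until the terminal age
flat_life_table <- function(qx = 0.02, min_age = 0, max_age = 100) {
  n <- max_age - min_age + 1
  life_table(min_age:max_age, c(rep(qx, n - 1), 1))
}

# published recurrent-outcome distribution (sums to exactly 1.000)
OUTCOME_DIST <- c(0.129, 0.136, 0.164, 0.247, 0.135, 0.189)

# published year 1-10 recurrence schedule
RECURRENCE <- c(0.059, 0.036, 0.025, 0.022, 0.022,
                0.027, 0.027, 0.023, 0.028, 0.016)

# published utilities, mRS0..mRS5 (death fixed at 0)
UTILITIES <- c(1.00, 0.91, 0.76, 0.65, 0.33, 0.00)

basic_inputs <- function(qx = 0.02, hr = rep(1.5, 6), rec = RECURRENCE, ...) {
  markov_inputs(rec, hr, OUTCOME_DIST, flat_life_table(qx), ...)
}

# a zero-event parameter set: no mortality until the terminal age,
# no recurrence, unit utility everywhere, no costs
null_event_inputs <- function() {
  markov_inputs(rep(0, 10), rep(1, 6), OUTCOME_DIST, flat_life_table(0))
}

null_cost_econ <- function(discount_rate = 0.03,
                           utilities = rep(1, 6)) {
  econ_params(utilities, rep(0, 6), rep(0, 6), 0, 0, discount_rate)
}

basic_econ <- function(discount_rate = 0.03) {
  econ_params(UTILITIES,
              first_year_cost_by_mrs = c(20000, 25000, 32000, 45000, 60000, 80000),
              longterm_annual_cost_by_mrs = c(2000, 4000, 9000, 20000, 45000, 70000),
              evt_procedure_cost = 17103.20,
              recurrent_stroke_acute_cost = 25000,
              discount_rate = discount_rate)
}

even_dist <- function() mrs_distribution(rep(1 / 7, 7))

# random valid mRS distribution (flat Dirichlet on the 7-simplex)
random_dist <- function() {
  g <- rgamma(7, 1)
  mrs_distribution(g / sum(g))
}
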