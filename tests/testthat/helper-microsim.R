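# Independent individual-level microsimulation oracle.
#
# Simulates N patients one by one under the same per-cycle event rules as the
# cohort engine (death first, then recurrence among survivors, no functional
# improvement after a recurrent stroke, multiplicative hazard ratios) but
# shares no code with it: transitions are drawn per patient with runif/sample
# and rewards are summed directly. Initial states are allocated
# deterministically in proportion to the starting distribution (largest
# remainder), so the only Monte Carlo error is in the event draws.
microsim_strategy <- function(initial, strategy, inputs, econ,
                              start_age = 67, N = 200000, seed = 1) {
  set.seed(seed)
  p0 <- as.numeric(initial)
  counts <- floor(N * p0)
  rem <- N - sum(counts)
  if (rem > 0) {
    frac <- N * p0 - counts
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  states <- rep.int(seq_len(7L), counts)
  states <- sample(states)                       # shuffle, cosmetic only

  lt <- inputs$life_table
  max_age <- attr(lt, "max_age")
  hr <- inputs$death_hr_by_mrs
  d_out <- inputs$recurrent_outcome_dist
  target <- c(2L, 3L, 4L, 5L, 6L, 7L)            # category -> state mapping
  r <- econ$discount_rate

  alive <- states != 7L
  total_cost <- sum(econ$first_year_cost_by_mrs[states[alive]]) +
    (strategy == "EVT") * econ$evt_procedure_cost * N
  total_qalys <- sum(econ$utilities[states[alive]])

  t <- 0L
  repeat {
    t <- t + 1L
    age <- start_age + t - 1L
    if (age > max_age) break
    alive_idx <- which(states != 7L)
    if (length(alive_idx) == 0L) break
    qx <- lt$qx[match(age, lt$age)]
    # death
    pd <- pmin(1, qx * hr[states[alive_idx]])
    dies <- runif(length(alive_idx)) < pd
    states[alive_idx[dies]] <- 7L
    # recurrence among survivors
    surv_idx <- alive_idx[!dies]
    p_rec <- if (t <= 10L) inputs$recurrence_by_year[t] else
      inputs$recurrence_after_year10
    rec_sel <- runif(length(surv_idx)) < p_rec
    rec_idx <- surv_idx[rec_sel]
    n_rec <- length(rec_idx)
    if (n_rec > 0L) {
      drawn <- target[sample.int(6L, n_rec, replace = TRUE, prob = d_out)]
      states[rec_idx] <- pmax(drawn, states[rec_idx])
    }
    alive2 <- states != 7L
    df <- (1 + r)^(-t)
    cost_t <- sum(econ$longterm_annual_cost_by_mrs[states[alive2]]) +
      n_rec * econ$recurrent_stroke_acute_cost
    qaly_t <- sum(econ$utilities[states[alive2]])
    total_cost <- total_cost + cost_t * df
    total_qalys <- total_qalys + qaly_t * df
  }
  list(total_cost = total_cost / N, total_qalys = total_qalys / N)
}
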