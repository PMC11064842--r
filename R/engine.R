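#' Annual death probability for a surviving state
#'
#' Combines the age-specific life-table mortality with the per-mRS death
#' hazard ratio. Under the default \code{"multiply"} method the annual
#' probability is \code{min(1, qx(age) * HR)}; the \code{"rate"} method
#' applies the hazard ratio on the rate scale, \code{1 - (1 - qx)^HR}.
#'
#' @param age Age in whole years; must be covered by the life table.
#' @param mrs A surviving state (label \code{"mRS0"}..\code{"mRS5"} or index
#'   1..6). The absorbing death state has no death event and is rejected.
#' @param inputs A [markov_inputs()].
#' @return Annual probability of death, clamped to [0, 1].
#' @export
death_probability <- function(age, mrs, inputs) {
  stopifnot(inherits(inputs, "markov_inputs"))
  i <- .state_index(mrs)
  if (i == .DEAD) {
    stop("death_probability is undefined for the absorbing DEAD state",
         call. = FALSE)
  }
  q <- lookup_qx(inputs$life_table, age)
  hr <- inputs$death_hr_by_mrs[i]
  p <- switch(inputs$hr_method,
              multiply = q * hr,
              rate = 1 - (1 - q)^hr)
  min(1, max(0, p))
}

#' Annual stroke recurrence probability
#'
#' Year-specific recurrence probabilities apply for years 1-10 after the
#' index stroke; beyond year 10 the configured carry-forward value (by
#' default the year-10 value) is used.
#'
#' @param years_since_index Whole years since the index stroke (>= 1).
#' @param inputs A [markov_inputs()].
#' @return Probability of a recurrent stroke during that year.
#' @export
recurrence_probability <- function(years_since_index, inputs) {
  stopifnot(inherits(inputs, "markov_inputs"))
  y <- as.integer(years_since_index)
  if (is.na(y) || y < 1L) {
    stop("years_since_index must be a whole number >= 1", call. = FALSE)
  }
  if (y <= 10L) inputs$recurrence_by_year[y] else inputs$recurrence_after_year10
}

#' Post-recurrence state distribution under the no-improvement rule
#'
#' Distributes the recurrent-stroke outcome categories (\code{mRS 0 or 1,
#' mRS2, mRS3, mRS4, mRS5, death}) over the model states for a patient
#' currently in \code{current}. A recurrent stroke cannot improve function:
#' any outcome category better than the current state is collapsed onto the
#' current state. The combined \code{mRS 0 or 1} category maps to mRS1 and
#' the \code{death} category to the absorbing state.
#'
#' @param current The pre-recurrence state (label or index 1..6; not DEAD).
#' @param inputs A [markov_inputs()].
#' @return An [mrs_distribution()] over post-recurrence states.
#' @export
apply_recurrent_stroke <- function(current, inputs) {
  stopifnot(inherits(inputs, "markov_inputs"))
  cur <- .state_index(current)
  if (cur == .DEAD) {
    stop("apply_recurrent_stroke is undefined for the DEAD state", call. = FALSE)
  }
  d <- inputs$recurrent_outcome_dist
  # category -> state index: mRS0or1 -> mRS1 (2), mRS2..mRS5 -> 3..6, death -> 7
  target <- c(2L, 3L, 4L, 5L, 6L, .DEAD)
  target <- pmax(target, cur)      # no functional improvement (death unaffected)
  out <- numeric(.N_STATES)
  for (k in seq_along(d)) out[target[k]] <- out[target[k]] + d[k]
  mrs_distribution(out)
}

#' Advance the cohort distribution by one annual cycle
#'
#' Applies competing death and recurrence events to every surviving state.
#' Under the default \code{"death_first"} ordering each surviving state first
#' faces its age- and mRS-specific death probability; survivors then face the
#' year-specific recurrence probability, with recurrent strokes redistributed
#' by [apply_recurrent_stroke()] (which includes a fatal category); everyone
#' else remains in state. \code{"recurrence_first"} reverses the ordering,
#' with post-recurrence states facing that year's mortality.
#'
#' @param dist An [mrs_distribution()] at the start of the cycle.
#' @param age Cohort age (years) at the start of the cycle.
#' @param years_since_index Cycle index (whole years since the index stroke,
#'   >= 1).
#' @param inputs A [markov_inputs()].
#' @return The end-of-cycle [mrs_distribution()], carrying the incident
#'   recurrence mass of the cycle in attribute \code{"recurrence_mass"}.
#' @export
step_cycle <- function(dist, age, years_since_index, inputs) {
  stopifnot(inherits(inputs, "markov_inputs"))
  dist <- if (inherits(dist, "mrs_distribution")) dist else mrs_distribution(dist)
  p_rec <- recurrence_probability(years_since_index, inputs)
  out <- numeric(.N_STATES)
  out[.DEAD] <- dist[.DEAD]
  rec_mass <- 0
  if (inputs$event_order == "death_first") {
    for (s in 1:6) {
      m <- dist[[s]]
      if (m == 0) next
      p_d <- death_probability(age, s, inputs)
      out[.DEAD] <- out[.DEAD] + m * p_d
      surv <- m * (1 - p_d)
      if (surv == 0) next
      rec <- surv * p_rec
      rec_mass <- rec_mass + rec
      out[s] <- out[s] + surv - rec
      if (rec > 0) {
        out <- out + rec * unclass(apply_recurrent_stroke(s, inputs))
      }
    }
  } else {
    # recurrence first: redistribute, then mortality on post-recurrence states
    mid <- numeric(.N_STATES)
    mid[.DEAD] <- dist[.DEAD]
    for (s in 1:6) {
      m <- dist[[s]]
      if (m == 0) next
      rec <- m * p_rec
      rec_mass <- rec_mass + rec
      mid[s] <- mid[s] + m - rec
      if (rec > 0) mid <- mid + rec * unclass(apply_recurrent_stroke(s, inputs))
    }
    out[.DEAD] <- mid[.DEAD]
    for (s in 1:6) {
      m <- mid[s]
      if (m == 0) next
      p_d <- death_probability(age, s, inputs)
      out[.DEAD] <- out[.DEAD] + m * p_d
      out[s] <- out[s] + m * (1 - p_d)
    }
  }
  res <- mrs_distribution(out)
  attr(res, "recurrence_mass") <- rec_mass
  res
}

#' Run one strategy through the lifetime Markov cohort model
#'
#' Evolves the 90-day mRS distribution through annual cycles until the
#' cohort reaches the life-table terminal age or the surviving fraction falls
#' below \code{alive_tol}, accumulating discounted costs and QALYs.
#'
#' Cycle 0 covers the first 365 days: it accrues the per-mRS acute first-year
#' cost (plus the one-off procedure cost for the EVT strategy) and the
#' utilities of the initial distribution, undiscounted. Every later cycle
#' \code{t} accrues per-mRS maintenance costs, the acute recurrent-stroke
#' cost times the incident recurrence mass of the cycle, and utilities, all
#' discounted by \code{(1 + r)^-t}. Patients dead at 90 days accrue nothing.
#'
#' @param initial 90-day [mrs_distribution()] for the strategy.
#' @param strategy \code{"EVT"} or \code{"BMC"}; EVT adds the one-off
#'   procedure cost in cycle 0.
#' @param inputs A [markov_inputs()].
#' @param econ An [econ_params()].
#' @param start_age Cohort age (years) at the index stroke; default 67, the
#'   average inclusion age of the input trials.
#' @param horizon Optional forced number of cycles (including cycle 0);
#'   \code{NULL} (default) runs the full lifetime horizon.
#' @param half_cycle If \code{TRUE}, maintenance costs and utilities of
#'   cycles >= 1 are accrued on the mid-cycle occupancy (mean of the start-
#'   and end-of-cycle distributions). Off by default.
#' @param alive_tol Surviving fraction below which the run stops.
#' @return An object of class \code{"strategy_result"}: list with
#'   \code{total_cost}, \code{total_qalys} (discounted),
#'   \code{total_cost_undisc}, \code{total_qalys_undisc}, \code{strategy},
#'   and a per-cycle \code{trace} data frame (cycle, age, state occupancy,
#'   incident recurrence mass, undiscounted and discounted cost and QALY).
#' @examples
#' lt <- gen_life_table(max_age = 100)
#' mi <- markov_inputs(rep(0.02, 10), rep(1.5, 6),
#'                     c(0.129, 0.136, 0.164, 0.247, 0.135, 0.189), lt)
#' ec <- econ_params(c(1, 0.91, 0.76, 0.65, 0.33, 0),
#'                   rep(20000, 6), rep(5000, 6), 17103.2, 20000)
#' run_strategy(mrs_distribution(c(0.2, 0.2, 0.2, 0.2, 0.1, 0.05, 0.05)),
#'              "EVT", mi, ec)
#' @export
run_strategy <- function(initial, strategy = c("BMC", "EVT"), inputs, econ,
                         start_age = 67, horizon = NULL, half_cycle = FALSE,
                         alive_tol = 1e-9) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(inputs, "markov_inputs"), inherits(econ, "econ_params"))
  initial <- if (inherits(initial, "mrs_distribution")) initial
             else mrs_distribution(initial)
  max_age <- attr(inputs$life_table, "max_age")
  if (start_age > max_age) {
    stop("start_age exceeds the life-table terminal age", call. = FALSE)
  }
  if (!is.null(horizon)) {
    horizon <- as.integer(horizon)
    if (is.na(horizon) || horizon < 1L) {
      stop("horizon must be at least 1 cycle", call. = FALSE)
    }
  }
  r <- econ$discount_rate

  alive0 <- unclass(initial)[1:6]
  cost0 <- sum(alive0 * econ$first_year_cost_by_mrs) +
    if (strategy == "EVT") econ$evt_procedure_cost else 0
  qaly0 <- sum(alive0 * econ$utilities)

  n_max <- if (!is.null(horizon)) horizon else max_age - start_age + 2L
  cyc_rec <- cyc_cost <- cyc_qaly <- cyc_df <- numeric(n_max)
  occ_mat <- matrix(NA_real_, n_max, .N_STATES,
                    dimnames = list(NULL, mrs_states()))
  occ_mat[1L, ] <- unclass(initial)
  cyc_cost[1L] <- cost0
  cyc_qaly[1L] <- qaly0
  cyc_df[1L] <- 1
  dist <- initial
  t <- 0L
  repeat {
    t <- t + 1L
    if (!is.null(horizon) && t >= horizon) break
    age_tr <- start_age + t - 1L          # age during the transition year
    if (age_tr > max_age) break
    if (sum(unclass(dist)[1:6]) < alive_tol) break
    nxt <- step_cycle(dist, age_tr, t, inputs)
    rec_mass <- attr(nxt, "recurrence_mass")
    occ <- unclass(nxt)[1:6]
    if (half_cycle) occ <- (occ + unclass(dist)[1:6]) / 2
    cyc_rec[t + 1L] <- rec_mass
    cyc_cost[t + 1L] <- sum(occ * econ$longterm_annual_cost_by_mrs) +
      rec_mass * econ$recurrent_stroke_acute_cost
    cyc_qaly[t + 1L] <- sum(occ * econ$utilities)
    cyc_df[t + 1L] <- (1 + r)^(-t)
    occ_mat[t + 1L, ] <- unclass(nxt)
    dist <- nxt
  }
  keep <- seq_len(t)
  trace <- data.frame(cycle = keep - 1L, age = start_age + keep - 1L,
                      occ_mat[keep, , drop = FALSE],
                      recurrence_mass = cyc_rec[keep],
                      cost = cyc_cost[keep],
                      cost_disc = cyc_cost[keep] * cyc_df[keep],
                      qaly = cyc_qaly[keep],
                      qaly_disc = cyc_qaly[keep] * cyc_df[keep],
                      check.names = FALSE)
  rownames(trace) <- NULL
  structure(list(strategy = strategy,
                 total_cost = sum(trace$cost_disc),
                 total_qalys = sum(trace$qaly_disc),
                 total_cost_undisc = sum(trace$cost),
                 total_qalys_undisc = sum(trace$qaly),
                 start_age = start_age,
                 discount_rate = r,
                 trace = trace),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy %s: %d cycles from age %d\n",
              x$strategy, nrow(x$trace), x$start_age))
  cat(sprintf("  discounted lifetime cost : $%s\n",
              format(round(x$total_cost), big.mark = ",")))
  cat(sprintf("  discounted lifetime QALYs: %.2f\n", x$total_qalys))
  invisible(x)
}

#' @export
summary.strategy_result <- function(object, ...) {
  tr <- object$trace
  out <- list(strategy = object$strategy,
              n_cycles = nrow(tr),
              total_cost = object$total_cost,
              total_qalys = object$total_qalys,
              life_years_disc = sum((1 - tr$DEAD) *
                                      (1 + object$discount_rate)^(-tr$cycle)),
              final_dead_fraction = tr$DEAD[nrow(tr)])
  class(out) <- "summary.strategy_result"
  out
}

#' @export
print.summary.strategy_result <- function(x, ...) {
  cat(sprintf("%s over %d annual cycles\n", x$strategy, x$n_cycles))
  cat(sprintf("  cost  $%s | QALYs %.2f | discounted life-years %.2f | dead %.4f\n",
              format(round(x$total_cost), big.mark = ","),
              x$total_qalys, x$life_years_disc, x$final_dead_fraction))
  invisible(x)
}
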