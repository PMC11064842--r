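#' Method-of-moments fit of a beta distribution
#'
#' Utilities are varied on beta distributions in probabilistic sensitivity
#' analysis; the shape parameters are recovered from a target mean and
#' standard deviation by the method of moments:
#' \code{alpha = m (m(1-m)/s^2 - 1)}, \code{beta = (1-m)(m(1-m)/s^2 - 1)}.
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param sd Target standard deviation; must satisfy
#'   \code{sd^2 < mean * (1 - mean)} (the beta variance bound).
#' @param name Parameter name used in error messages.
#' @return Named list with \code{alpha} and \code{beta}.
#' @examples
#' fit_beta_moments(0.5, sqrt(0.05))   # Beta(2, 2)
#' @export
fit_beta_moments <- function(mean, sd, name = "parameter") {
  if (!(mean > 0 && mean < 1)) {
    stop("beta fit for '", name, "': mean must lie strictly in (0, 1)",
         call. = FALSE)
  }
  v <- sd^2
  bound <- mean * (1 - mean)
  if (!(v > 0 && v < bound)) {
    stop("beta fit for '", name, "': need 0 < sd^2 < mean*(1-mean) = ",
         format(bound), call. = FALSE)
  }
  k <- bound / v - 1
  list(alpha = mean * k, beta = (1 - mean) * k)
}

#' Method-of-moments fit of a gamma distribution
#'
#' Cost parameters are varied on gamma distributions (non-negative,
#' right-skewed — the conventional choice for costs).
#' \code{shape = (mean/sd)^2}, \code{scale = sd^2/mean}.
#'
#' @param mean,sd Target mean and standard deviation, both > 0.
#' @param name Parameter name used in error messages.
#' @return Named list with \code{shape} and \code{scale}.
#' @export
fit_gamma_moments <- function(mean, sd, name = "parameter") {
  if (!(mean > 0) || !(sd > 0)) {
    stop("gamma fit for '", name, "': mean and sd must be positive",
         call. = FALSE)
  }
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

# fields a distribution may target, and where they live
.ECON_FIELDS <- c("utilities", "first_year_cost_by_mrs",
                  "longterm_annual_cost_by_mrs", "evt_procedure_cost",
                  "recurrent_stroke_acute_cost", "discount_rate")
.MARKOV_FIELDS <- c("recurrence_by_year", "recurrence_after_year10",
                    "death_hr_by_mrs", "recurrent_outcome_dist")
.COST_FIELDS <- c("first_year_cost_by_mrs", "longterm_annual_cost_by_mrs",
                  "evt_procedure_cost", "recurrent_stroke_acute_cost")

#' Declare a sampling distribution for one model parameter
#'
#' @param kind \code{"fixed"} (no variation), \code{"beta"}, \code{"gamma"},
#'   or \code{"dirichlet"}.
#' @param target Name of the field the draw replaces (an [econ_params()] or
#'   [markov_inputs()] field).
#' @param index For vector-valued targets, the 1-based element the draw
#'   replaces; \code{NULL} for scalar targets or (dirichlet) the full vector.
#' @param alpha,beta Beta shape parameters (both > 0).
#' @param shape,scale Gamma parameters (both > 0).
#' @param conc Dirichlet concentration vector (all > 0), same length as the
#'   target vector.
#' @return Object of class \code{"param_dist"}.
#' @export
param_dist <- function(kind = c("fixed", "beta", "gamma", "dirichlet"),
                       target, index = NULL,
                       alpha = NULL, beta = NULL,
                       shape = NULL, scale = NULL, conc = NULL) {
  kind <- match.arg(kind)
  if (!target %in% c(.ECON_FIELDS, .MARKOV_FIELDS)) {
    stop("param_dist target references no known field: '", target, "'",
         call. = FALSE)
  }
  pos <- function(x, nm) {
    if (is.null(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop(kind, " distribution for '", target, "' needs positive ", nm,
           call. = FALSE)
    }
    x
  }
  switch(kind,
         beta = { pos(alpha, "alpha"); pos(beta, "beta") },
         gamma = { pos(shape, "shape"); pos(scale, "scale") },
         dirichlet = pos(conc, "concentration vector"),
         fixed = NULL)
  structure(list(kind = kind, target = target, index = index,
                 alpha = alpha, beta = beta, shape = shape, scale = scale,
                 conc = conc),
            class = "param_dist")
}

#' Default probabilistic-sensitivity parameter set
#'
#' Utilities get beta distributions (method of moments, sd = a fraction of
#' the mean, default 0.1); all costs get gamma distributions (sd fraction
#' default 0.25, consistent with the deterministic +/-25 percent range); the
#' recurrent-stroke outcome distribution gets a Dirichlet with concentration
#' equal to the category proportions times an effective sample size (default
#' 500). Utilities at the support boundary (0 or 1) and zero costs are held
#' fixed.
#'
#' @param inputs A [markov_inputs()].
#' @param econ An [econ_params()].
#' @param u_sd_frac,cost_sd_frac Standard deviation as a fraction of the
#'   base value for utilities and costs.
#' @param outcome_ess Effective sample size of the Dirichlet on the
#'   recurrent-outcome distribution.
#' @return List of [param_dist()] objects.
#' @export
default_psa_dists <- function(inputs, econ, u_sd_frac = 0.1,
                              cost_sd_frac = 0.25, outcome_ess = 500) {
  dists <- list()
  for (i in seq_along(econ$utilities)) {
    u <- econ$utilities[i]
    if (u > 0 && u < 1) {
      f <- fit_beta_moments(u, u_sd_frac * u, name = sprintf("utilities[%d]", i))
      dists[[length(dists) + 1L]] <-
        param_dist("beta", "utilities", index = i,
                   alpha = f$alpha, beta = f$beta)
    }
  }
  add_gamma <- function(dists, target, value, index = NULL) {
    if (value > 0) {
      f <- fit_gamma_moments(value, cost_sd_frac * value, name = target)
      dists[[length(dists) + 1L]] <-
        param_dist("gamma", target, index = index,
                   shape = f$shape, scale = f$scale)
    }
    dists
  }
  for (i in 1:6) {
    dists <- add_gamma(dists, "first_year_cost_by_mrs",
                       econ$first_year_cost_by_mrs[i], i)
    dists <- add_gamma(dists, "longterm_annual_cost_by_mrs",
                       econ$longterm_annual_cost_by_mrs[i], i)
  }
  dists <- add_gamma(dists, "evt_procedure_cost", econ$evt_procedure_cost)
  dists <- add_gamma(dists, "recurrent_stroke_acute_cost",
                     econ$recurrent_stroke_acute_cost)
  dists[[length(dists) + 1L]] <-
    param_dist("dirichlet", "recurrent_outcome_dist",
               conc = inputs$recurrent_outcome_dist * outcome_ess)
  dists
}

#' Draw one sampled parameter set for probabilistic sensitivity analysis
#'
#' Returns deep, independent copies of the transition and economic inputs
#' with every targeted field replaced by a random draw; untargeted fields and
#' \code{"fixed"}-kind targets are copied unchanged. Drawn utilities are
#' sorted into non-increasing order so the sampled set always satisfies the
#' severity-monotonicity constraint. The same seed always reproduces the
#' same draw.
#'
#' @param inputs A [markov_inputs()].
#' @param econ An [econ_params()].
#' @param dists List of [param_dist()] objects.
#' @param seed Integer seed for this draw.
#' @return List with elements \code{inputs} and \code{econ}.
#' @export
sample_inputs <- function(inputs, econ, dists, seed) {
  stopifnot(inherits(inputs, "markov_inputs"), inherits(econ, "econ_params"))
  set.seed(as.integer(seed))
  e <- unclass(econ)
  m <- unclass(inputs)
  utilities_drawn <- FALSE
  for (d in dists) {
    if (!inherits(d, "param_dist")) stop("dists must be param_dist objects",
                                         call. = FALSE)
    if (d$kind == "fixed") next
    draw <- switch(d$kind,
                   beta = stats::rbeta(1, d$alpha, d$beta),
                   gamma = stats::rgamma(1, shape = d$shape, scale = d$scale),
                   dirichlet = {
                     g <- stats::rgamma(length(d$conc), shape = d$conc, scale = 1)
                     g / sum(g)
                   })
    tgt <- d$target
    store <- if (tgt %in% .ECON_FIELDS) "e" else "m"
    cur <- if (store == "e") e[[tgt]] else m[[tgt]]
    if (d$kind == "dirichlet") {
      if (length(draw) != length(cur)) {
        stop("dirichlet draw length mismatch for '", tgt, "'", call. = FALSE)
      }
      new <- draw
    } else if (is.null(d$index)) {
      if (length(cur) != 1) {
        stop("scalar draw targets vector field '", tgt,
             "' without an index", call. = FALSE)
      }
      new <- draw
    } else {
      if (d$index < 1 || d$index > length(cur)) {
        stop("index ", d$index, " out of range for '", tgt, "'", call. = FALSE)
      }
      new <- cur
      new[d$index] <- draw
    }
    if (store == "e") e[[tgt]] <- new else m[[tgt]] <- new
    if (tgt == "utilities") utilities_drawn <- TRUE
  }
  if (utilities_drawn) e$utilities <- sort(e$utilities, decreasing = TRUE)
  list(inputs = markov_inputs(m$recurrence_by_year, m$death_hr_by_mrs,
                              m$recurrent_outcome_dist, m$life_table,
                              recurrence_after_year10 = m$recurrence_after_year10,
                              hr_method = m$hr_method,
                              event_order = m$event_order),
       econ = econ_params(e$utilities, e$first_year_cost_by_mrs,
                          e$longterm_annual_cost_by_mrs, e$evt_procedure_cost,
                          e$recurrent_stroke_acute_cost, e$discount_rate))
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Repeatedly samples the uncertain parameters, reruns both strategies
#' through the cohort model, and records the incremental cost and QALY of
#' each iteration (one point on the cost-effectiveness plane). Per-iteration
#' seeds are derived deterministically from the root seed, so results do not
#' depend on evaluation order.
#'
#' @param evt_dist,bmc_dist 90-day [mrs_distribution()]s of the two arms.
#' @param inputs A [markov_inputs()].
#' @param econ An [econ_params()].
#' @param dists List of [param_dist()] objects;
#'   default [default_psa_dists()].
#' @param n Number of Monte Carlo iterations.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param seed Root seed.
#' @param start_age Cohort age at the index stroke.
#' @return Object of class \code{"psa_result"}: \code{points} data frame
#'   (iteration, delta_cost, delta_qalys), \code{n_iterations}, \code{seed},
#'   \code{wtp}, \code{fraction_cost_effective_at_wtp} (share with
#'   non-negative incremental net monetary benefit) and
#'   \code{fraction_cost_saving} (share with a QALY gain at lower cost).
#' @export
run_psa <- function(evt_dist, bmc_dist, inputs, econ,
                    dists = default_psa_dists(inputs, econ),
                    n = 1000, wtp = 1e5, seed = 1, start_age = 67) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n)
  dc <- numeric(n)
  dq <- numeric(n)
  for (i in seq_len(n)) {
    smp <- tryCatch(sample_inputs(inputs, econ, dists, seed = iter_seeds[i]),
                    error = function(e) stop("PSA iteration ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    evt <- run_strategy(evt_dist, "EVT", smp$inputs, smp$econ,
                        start_age = start_age)
    bmc <- run_strategy(bmc_dist, "BMC", smp$inputs, smp$econ,
                        start_age = start_age)
    dc[i] <- evt$total_cost - bmc$total_cost
    dq[i] <- evt$total_qalys - bmc$total_qalys
  }
  structure(list(points = data.frame(iteration = seq_len(n),
                                     delta_cost = dc, delta_qalys = dq),
                 n_iterations = n, seed = as.integer(seed), wtp = wtp,
                 fraction_cost_effective_at_wtp = mean(dq * wtp - dc >= 0),
                 fraction_cost_saving = mean(dc < 0 & dq > 0)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d Monte Carlo iterations (seed %d)\n",
              x$n_iterations, x$seed))
  cat(sprintf("  cost-effective at WTP $%s/QALY: %.1f%%\n",
              format(x$wtp, big.mark = ",", scientific = FALSE),
              100 * x$fraction_cost_effective_at_wtp))
  cat(sprintf("  cost-saving (dominant) share  : %.1f%%\n",
              100 * x$fraction_cost_saving))
  invisible(x)
}

#' @export
plot.psa_result <- function(x, ...) {
  p <- x$points
  graphics::plot(p$delta_qalys, p$delta_cost,
       pch = 16, cex = 0.4, col = grDevices::adjustcolor("steelblue", 0.4),
       xlab = "Incremental effectiveness (QALY)",
       ylab = "Incremental cost (USD)",
       main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(a = 0, b = x$wtp, lty = 2, col = "firebrick")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on a grid, the fraction of PSA points
#' with non-negative incremental net monetary benefit.
#'
#' @param points A \code{psa_result} or its \code{points} data frame
#'   (columns \code{delta_cost}, \code{delta_qalys}).
#' @param wtp_grid Numeric vector of WTP values (USD/QALY).
#' @return Data frame with columns \code{wtp} and \code{fraction}.
#' @export
ceac <- function(points, wtp_grid) {
  if (inherits(points, "psa_result")) points <- points$points
  if (NROW(points) == 0 || length(wtp_grid) == 0) {
    stop("ceac needs non-empty PSA points and WTP grid", call. = FALSE)
  }
  frac <- vapply(wtp_grid, function(w) {
    mean(points$delta_qalys * w - points$delta_cost >= 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, fraction = frac)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the comparison with each cost parameter set to its lower and upper
#' bound (base value times \code{1 -/+ spread}, default +/-25 percent), all
#' other parameters held at base, and orders the rows by the width of the
#' incremental-cost swing (tornado order; ties broken by parameter name).
#' Only cost fields may be varied; vector-valued cost categories are scaled
#' as a whole unless an element is named, e.g.
#' \code{"first_year_cost_by_mrs[4]"}.
#'
#' @inheritParams run_psa
#' @param cost_params Character vector of cost-field names to vary;
#'   default: all four cost categories.
#' @param spread Fractional variation, in (0, 1]; \code{spread = 0} is
#'   accepted and collapses every row to the base case.
#' @return Object of class \code{"tornado"}: a data frame with one row per
#'   parameter — its low/base/high values (for whole-vector parameters the
#'   vector mean is reported), the incremental cost and ICER-or-sentinel at
#'   each, and the incremental-cost \code{range}.
#' @export
one_way_dsa <- function(evt_dist, bmc_dist, inputs, econ,
                        cost_params = .COST_FIELDS,
                        spread = 0.25, wtp = 1e5, start_age = 67) {
  if (spread < 0 || spread >= 1) {
    stop("spread must lie in [0, 1)", call. = FALSE)
  }
  parse_target <- function(p) {
    m <- regmatches(p, regexec("^([a-z_0-9]+)(\\[([0-9]+)\\])?$", p))[[1]]
    if (length(m) == 0) stop("cannot parse parameter '", p, "'", call. = FALSE)
    list(field = m[2],
         index = if (nzchar(m[4])) as.integer(m[4]) else NULL)
  }
  scale_econ <- function(econ, field, index, factor) {
    e <- unclass(econ)
    if (is.null(index)) e[[field]] <- e[[field]] * factor
    else e[[field]][index] <- e[[field]][index] * factor
    econ_params(e$utilities, e$first_year_cost_by_mrs,
                e$longterm_annual_cost_by_mrs, e$evt_procedure_cost,
                e$recurrent_stroke_acute_cost, e$discount_rate)
  }
  eval_case <- function(econ2) {
    evt <- run_strategy(evt_dist, "EVT", inputs, econ2, start_age = start_age)
    bmc <- run_strategy(bmc_dist, "BMC", inputs, econ2, start_age = start_age)
    compare_strategies(evt, bmc, wtp)
  }
  base_cmp <- eval_case(econ)
  rows <- lapply(cost_params, function(p) {
    t <- parse_target(p)
    if (!t$field %in% .COST_FIELDS) {
      stop("one_way_dsa varies cost parameters only; '", t$field,
           "' is not a cost field", call. = FALSE)
    }
    base_val <- unclass(econ)[[t$field]]
    rep_val <- if (is.null(t$index)) mean(base_val) else base_val[t$index]
    lo <- eval_case(scale_econ(econ, t$field, t$index, 1 - spread))
    hi <- eval_case(scale_econ(econ, t$field, t$index, 1 + spread))
    data.frame(parameter = p,
               low_value = rep_val * (1 - spread),
               base_value = rep_val,
               high_value = rep_val * (1 + spread),
               dcost_low = lo$delta_cost,
               dcost_base = base_cmp$delta_cost,
               dcost_high = hi$delta_cost,
               icer_low = lo$icer_label,
               icer_base = base_cmp$icer_label,
               icer_high = hi$icer_label,
               range = abs(hi$delta_cost - lo$delta_cost),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"),
            spread = spread, wtp = wtp)
}

#' @export
plot.tornado <- function(x, ...) {
  n <- nrow(x)
  op <- graphics::par(mar = c(4, 12, 3, 1))
  on.exit(graphics::par(op))
  ylim <- c(0.5, n + 0.5)
  xlim <- range(c(x$dcost_low, x$dcost_base, x$dcost_high))
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
       xlab = "Incremental cost (USD)", ylab = "",
       main = sprintf("Tornado: +/-%d%% cost variation",
                      round(100 * attr(x, "spread"))), ...)
  for (i in seq_len(n)) {
    y <- n - i + 1
    graphics::segments(x$dcost_low[i], y, x$dcost_base[i], y,
                       lwd = 8, col = "steelblue", lend = 1)
    graphics::segments(x$dcost_base[i], y, x$dcost_high[i], y,
                       lwd = 8, col = "firebrick", lend = 1)
  }
  graphics::abline(v = x$dcost_base[1], lty = 2, col = "grey50")
  graphics::axis(2, at = n:1, labels = x$parameter, las = 1, cex.axis = 0.8)
  invisible(x)
}
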