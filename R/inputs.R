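#' Transition machinery for the Markov cohort engine
#'
#' Bundles everything the annual transition needs: the year-specific stroke
#' recurrence schedule, per-mRS death hazard ratios applied on top of
#' life-table mortality, the outcome distribution after a recurrent stroke,
#' and the life table itself.
#'
#' @param recurrence_by_year Numeric vector of 10 annual recurrence
#'   probabilities for years 1-10 after the index stroke.
#' @param death_hr_by_mrs Numeric vector of 6 hazard ratios (> 0), one per
#'   surviving state mRS0...mRS5, multiplying the age-specific life-table
#'   death probability.
#' @param recurrent_outcome_dist Numeric vector of 6 fractions over the
#'   outcome categories after a recurrent stroke: \code{mRS 0 or 1, mRS2,
#'   mRS3, mRS4, mRS5, death}; must sum to 1 within \code{1e-9}.
#' @param life_table A [life_table()].
#' @param recurrence_after_year10 Recurrence probability carried forward
#'   beyond year 10; defaults to the year-10 value.
#' @param hr_method How hazard ratios act on the annual death probability
#'   \code{q}: \code{"multiply"} uses \code{min(1, q * HR)};
#'   \code{"rate"} uses the rate transform \code{1 - (1 - q)^HR}.
#' @param event_order Within-cycle ordering of competing events:
#'   \code{"death_first"} (death, then recurrence among survivors; default)
#'   or \code{"recurrence_first"}.
#' @return An object of class \code{"markov_inputs"}.
#' @export
markov_inputs <- function(recurrence_by_year,
                          death_hr_by_mrs,
                          recurrent_outcome_dist,
                          life_table,
                          recurrence_after_year10 = NULL,
                          hr_method = c("multiply", "rate"),
                          event_order = c("death_first", "recurrence_first")) {
  hr_method <- match.arg(hr_method)
  event_order <- match.arg(event_order)
  recurrence_by_year <- as.numeric(recurrence_by_year)
  if (length(recurrence_by_year) != 10 ||
      any(recurrence_by_year < 0) || any(recurrence_by_year > 1)) {
    stop("recurrence_by_year must be 10 probabilities in [0, 1]", call. = FALSE)
  }
  if (is.null(recurrence_after_year10)) {
    recurrence_after_year10 <- recurrence_by_year[10]
  }
  recurrence_after_year10 <- as.numeric(recurrence_after_year10)
  if (recurrence_after_year10 < 0 || recurrence_after_year10 > 1) {
    stop("recurrence_after_year10 must be a probability", call. = FALSE)
  }
  death_hr_by_mrs <- as.numeric(death_hr_by_mrs)
  if (length(death_hr_by_mrs) != 6 || any(!is.finite(death_hr_by_mrs)) ||
      any(death_hr_by_mrs <= 0)) {
    stop("death_hr_by_mrs must be 6 positive hazard ratios (mRS0..mRS5)",
         call. = FALSE)
  }
  recurrent_outcome_dist <- as.numeric(recurrent_outcome_dist)
  if (length(recurrent_outcome_dist) != 6 || any(recurrent_outcome_dist < 0)) {
    stop("recurrent_outcome_dist must be 6 non-negative fractions", call. = FALSE)
  }
  if (abs(sum(recurrent_outcome_dist) - 1) > 1e-9) {
    stop(sprintf("recurrent_outcome_dist must sum to 1 (got %.12f)",
                 sum(recurrent_outcome_dist)), call. = FALSE)
  }
  if (!inherits(life_table, "life_table")) {
    stop("life_table must be a life_table object", call. = FALSE)
  }
  structure(list(recurrence_by_year = recurrence_by_year,
                 recurrence_after_year10 = recurrence_after_year10,
                 death_hr_by_mrs = death_hr_by_mrs,
                 recurrent_outcome_dist = recurrent_outcome_dist,
                 life_table = life_table,
                 hr_method = hr_method,
                 event_order = event_order),
            class = "markov_inputs")
}

#' Economic parameters: costs, utilities, discounting
#'
#' @param utilities QALY weight per year alive in each state mRS0...mRS5
#'   (death is fixed at 0); each in [0, 1] and non-increasing with severity.
#' @param first_year_cost_by_mrs Acute-phase cost (USD) accrued in the first
#'   model year, per 90-day mRS state.
#' @param longterm_annual_cost_by_mrs Maintenance cost (USD/year) per state in
#'   every later year.
#' @param evt_procedure_cost One-off cost (USD) of the thrombectomy procedure,
#'   charged once to the whole EVT cohort in the first year.
#' @param recurrent_stroke_acute_cost Acute-care cost (USD) charged per
#'   incident recurrent stroke, in the cycle it occurs.
#' @param discount_rate Annual discount rate applied to both costs and QALYs
#'   (fraction/year, >= 0); default 0.03.
#' @return An object of class \code{"econ_params"}.
#' @export
econ_params <- function(utilities,
                        first_year_cost_by_mrs,
                        longterm_annual_cost_by_mrs,
                        evt_procedure_cost,
                        recurrent_stroke_acute_cost,
                        discount_rate = 0.03) {
  utilities <- as.numeric(utilities)
  if (length(utilities) != 6 || any(utilities < 0) || any(utilities > 1)) {
    stop("utilities must be 6 values in [0, 1] (mRS0..mRS5)", call. = FALSE)
  }
  if (any(diff(utilities) > 1e-12)) {
    stop("utilities must be non-increasing with mRS severity", call. = FALSE)
  }
  check_cost <- function(x, nm, len) {
    x <- as.numeric(x)
    if (length(x) != len || anyNA(x) || any(x < 0)) {
      stop(nm, " must be ", len, " non-negative value(s)", call. = FALSE)
    }
    x
  }
  first_year_cost_by_mrs <- check_cost(first_year_cost_by_mrs,
                                       "first_year_cost_by_mrs", 6)
  longterm_annual_cost_by_mrs <- check_cost(longterm_annual_cost_by_mrs,
                                            "longterm_annual_cost_by_mrs", 6)
  evt_procedure_cost <- check_cost(evt_procedure_cost, "evt_procedure_cost", 1)
  recurrent_stroke_acute_cost <- check_cost(recurrent_stroke_acute_cost,
                                            "recurrent_stroke_acute_cost", 1)
  discount_rate <- as.numeric(discount_rate)
  if (length(discount_rate) != 1 || is.na(discount_rate) || discount_rate < 0) {
    stop("discount_rate must be a single non-negative fraction", call. = FALSE)
  }
  structure(list(utilities = utilities,
                 first_year_cost_by_mrs = first_year_cost_by_mrs,
                 longterm_annual_cost_by_mrs = longterm_annual_cost_by_mrs,
                 evt_procedure_cost = evt_procedure_cost,
                 recurrent_stroke_acute_cost = recurrent_stroke_acute_cost,
                 discount_rate = discount_rate),
            class = "econ_params")
}

#' @export
print.markov_inputs <- function(x, ...) {
  cat("Markov transition inputs\n")
  cat("  recurrence years 1-10:",
      paste(format(x$recurrence_by_year), collapse = " "), "\n")
  cat("  carry-forward after year 10:", x$recurrence_after_year10, "\n")
  cat("  death HR (mRS0..5):",
      paste(format(x$death_hr_by_mrs), collapse = " "), "\n")
  cat("  HR method:", x$hr_method, "| event order:", x$event_order, "\n")
  cat("  life table ages:", x$life_table$age[1], "-",
      attr(x$life_table, "max_age"), "\n")
  invisible(x)
}

#' @export
print.econ_params <- function(x, ...) {
  cat("Economic parameters (USD)\n")
  cat("  utilities (mRS0..5):", paste(format(x$utilities), collapse = " "), "\n")
  cat("  EVT procedure cost:", format(x$evt_procedure_cost, big.mark = ","), "\n")
  cat("  recurrent stroke acute cost:",
      format(x$recurrent_stroke_acute_cost, big.mark = ","), "\n")
  cat("  discount rate:", x$discount_rate, "/ year\n")
  invisible(x)
}
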