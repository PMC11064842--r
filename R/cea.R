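#' Incremental cost and effectiveness
#'
#' Differences are always intervention minus comparator (EVT minus BMC).
#'
#' @param evt,bmc [run_strategy()] results, or plain lists carrying
#'   \code{total_cost} and \code{total_qalys}.
#' @return Named list with \code{delta_cost} (USD) and \code{delta_qalys}.
#' @export
incremental <- function(evt, bmc) {
  list(delta_cost = evt$total_cost - bmc$total_cost,
       delta_qalys = evt$total_qalys - bmc$total_qalys)
}

#' Net monetary benefit of the incremental comparison
#'
#' \code{NMB = delta_QALYs * WTP - delta_cost}; positive exactly when the
#' intervention is cost-effective at the willingness-to-pay threshold.
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qalys Incremental effectiveness (QALYs).
#' @param wtp Willingness-to-pay threshold (USD/QALY, >= 0).
#' @return Incremental net monetary benefit (USD).
#' @export
nmb <- function(delta_cost, delta_qalys, wtp) {
  if (wtp < 0) stop("wtp must be non-negative", call. = FALSE)
  delta_qalys * wtp - delta_cost
}

#' Classify an incremental comparison on the cost-effectiveness plane
#'
#' Assigns the comparison to its quadrant and reports the ICER where it is
#' meaningful. With a QALY gain and a cost saving the intervention dominates
#' (\code{cost_saving_dominant}) and the ICER is the sentinel
#' \code{"cost saving"}, mirroring how dominant strategies are labelled in
#' cost-effectiveness tables. With a QALY gain at extra cost the ICER is
#' \code{delta_cost / delta_qalys} and the strategy is \code{cost_effective}
#' iff ICER <= WTP. A QALY loss at extra cost is \code{dominated}. A QALY
#' loss with a cost saving (south-west quadrant) reports the ICER but is
#' flagged: there a *larger* ICER favours the intervention. Zero QALY
#' difference is \code{indifferent} at zero cost difference, otherwise
#' dominant/dominated by cost sign, with an ICER sentinel.
#'
#' @inheritParams nmb
#' @return Object of class \code{"cea_comparison"}: list with
#'   \code{delta_cost}, \code{delta_qalys}, \code{icer} (number or NA),
#'   \code{icer_label} (formatted, sentinel where applicable),
#'   \code{classification}, \code{southwest} flag, \code{nmb_delta},
#'   \code{wtp}.
#' @examples
#' classify_ce(-17318, 1.32, 1e5)   # dominant: "cost saving"
#' classify_ce(2145, 1.61, 1e5)     # cost-effective, ICER ~ $1,332/QALY
#' @export
classify_ce <- function(delta_cost, delta_qalys, wtp) {
  if (wtp < 0) stop("wtp must be non-negative", call. = FALSE)
  icer <- NA_real_
  southwest <- FALSE
  if (delta_qalys > 0) {
    if (delta_cost < 0) {
      classification <- "cost_saving_dominant"
      label <- "cost saving"
    } else {
      icer <- delta_cost / delta_qalys
      classification <- if (icer <= wtp) "cost_effective" else "not_cost_effective"
      label <- sprintf("$%s/QALY", format(round(icer), big.mark = ","))
    }
  } else if (delta_qalys < 0) {
    if (delta_cost > 0) {
      classification <- "dominated"
      label <- "dominated"
    } else {
      # south-west quadrant: cheaper but less effective; ICER is a saving
      # per QALY forgone and its decision rule is reversed
      icer <- delta_cost / delta_qalys
      southwest <- TRUE
      classification <- if (icer >= wtp) "cost_effective" else "not_cost_effective"
      label <- sprintf("$%s/QALY (SW quadrant)",
                       format(round(icer), big.mark = ","))
    }
  } else {
    if (delta_cost == 0) {
      classification <- "indifferent"
      label <- "indifferent"
    } else if (delta_cost < 0) {
      classification <- "cost_saving_dominant"
      label <- "cost saving"
    } else {
      classification <- "dominated"
      label <- "dominated"
    }
  }
  structure(list(delta_cost = delta_cost,
                 delta_qalys = delta_qalys,
                 icer = icer,
                 icer_label = label,
                 classification = classification,
                 southwest = southwest,
                 nmb_delta = nmb(delta_cost, delta_qalys, wtp),
                 wtp = wtp),
            class = "cea_comparison")
}

#' Compare two strategy results at a willingness-to-pay threshold
#'
#' Convenience wrapper: [incremental()] followed by [classify_ce()].
#'
#' @inheritParams incremental
#' @param wtp Willingness-to-pay threshold (USD/QALY); default 100,000.
#' @return A \code{"cea_comparison"} (see [classify_ce()]).
#' @export
compare_strategies <- function(evt, bmc, wtp = 1e5) {
  inc <- incremental(evt, bmc)
  classify_ce(inc$delta_cost, inc$delta_qalys, wtp)
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("Incremental cost-effectiveness (EVT vs BMC)\n")
  cat(sprintf("  incremental cost : $%s\n",
              format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  incremental QALYs: %.2f\n", x$delta_qalys))
  cat(sprintf("  ICER             : %s\n", x$icer_label))
  cat(sprintf("  classification   : %s\n", x$classification))
  cat(sprintf("  NMB at WTP $%s/QALY: $%s\n",
              format(x$wtp, big.mark = ",", scientific = FALSE),
              format(round(x$nmb_delta), big.mark = ",")))
  invisible(x)
}
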