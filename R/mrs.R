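#' Modified Rankin Scale state labels
#'
#' The model tracks seven mutually exclusive health states: modified Rankin
#' Scale (mRS) grades 0 (no symptoms) through 5 (severe disability), plus an
#' absorbing death state. State order is fixed throughout the package:
#' \code{mRS0, mRS1, ..., mRS5, DEAD}.
#'
#' @return Character vector of the 7 state labels, in model order.
#' @export
mrs_states <- function() {
  c("mRS0", "mRS1", "mRS2", "mRS3", "mRS4", "mRS5", "DEAD")
}

# index of the absorbing state
.DEAD <- 7L
.N_STATES <- 7L

#' Construct and validate an mRS state distribution
#'
#' A probability vector over the 7 model states (mRS 0-5 and dead), e.g. the
#' 90-day functional outcome of a trial arm. Entries must lie in [0, 1] and
#' sum to 1 within \code{1e-9}.
#'
#' @param p Numeric vector of length 7 (order \code{mRS0...mRS5, DEAD}), or a
#'   named vector using those labels.
#' @return A named numeric vector of class \code{"mrs_distribution"}.
#' @examples
#' mrs_distribution(c(0.1, 0.2, 0.2, 0.2, 0.1, 0.1, 0.1))
#' @export
mrs_distribution <- function(p) {
  if (!is.numeric(p) || length(p) != .N_STATES) {
    stop("an mRS distribution needs exactly 7 numeric entries (mRS0..mRS5, DEAD)",
         call. = FALSE)
  }
  if (!is.null(names(p))) {
    if (!setequal(names(p), mrs_states())) {
      stop("named mRS distribution must use labels: ",
           paste(mrs_states(), collapse = ", "), call. = FALSE)
    }
    p <- p[mrs_states()]
  }
  p <- as.numeric(p)
  names(p) <- mrs_states()
  validate_mrs_distribution(p)
  structure(p, class = "mrs_distribution")
}

#' @rdname mrs_distribution
#' @param x Object to validate.
#' @param tol Tolerance on the simplex constraint.
#' @export
validate_mrs_distribution <- function(x, tol = 1e-9) {
  if (anyNA(x)) stop("mRS distribution contains NA", call. = FALSE)
  if (any(x < -tol) || any(x > 1 + tol)) {
    stop("mRS distribution entries must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(x)
  if (abs(s - 1) > tol) {
    stop(sprintf("mRS distribution must sum to 1 (got %.12f)", s), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.mrs_distribution <- function(x, digits = 4, ...) {
  cat("mRS state distribution\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

# internal: resolve a state given as label or 1-based index; returns index
.state_index <- function(state) {
  if (is.character(state)) {
    i <- match(state, mrs_states())
    if (is.na(i)) stop("unknown mRS state: ", state, call. = FALSE)
    return(i)
  }
  i <- as.integer(state)
  if (is.na(i) || i < 1L || i > .N_STATES) {
    stop("mRS state index must be in 1..7", call. = FALSE)
  }
  i
}
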