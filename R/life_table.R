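#' Construct a life table
#'
#' Annual probabilities of death \code{qx} by integer age, covering a
#' contiguous age range whose terminal age has \code{qx = 1} so a simulated
#' cohort cannot outlive the table.
#'
#' @param age Integer vector of contiguous ages (years).
#' @param qx Numeric vector of annual death probabilities, same length as
#'   \code{age}, each in [0, 1]; the entry for \code{max(age)} must be 1.
#' @return An object of class \code{"life_table"}: a data frame with columns
#'   \code{age} and \code{qx} plus a \code{max_age} attribute.
#' @seealso [gen_life_table()] for a Gompertz synthetic table,
#'   [read_life_table()] for the \code{age,qx} CSV interface.
#' @export
life_table <- function(age, qx) {
  age <- as.integer(age)
  qx <- as.numeric(qx)
  if (length(age) != length(qx) || length(age) == 0) {
    stop("life table needs equal-length, non-empty age and qx", call. = FALSE)
  }
  o <- order(age)
  age <- age[o]; qx <- qx[o]
  if (anyDuplicated(age)) stop("life table has duplicate ages", call. = FALSE)
  if (!all(diff(age) == 1L)) {
    stop("life table ages must be contiguous integers", call. = FALSE)
  }
  if (anyNA(qx) || any(qx < 0) || any(qx > 1)) {
    stop("life table qx values must lie in [0, 1]", call. = FALSE)
  }
  if (qx[length(qx)] != 1) {
    stop("life table must end with qx = 1 at its terminal age", call. = FALSE)
  }
  structure(data.frame(age = age, qx = qx),
            max_age = age[length(age)],
            class = c("life_table", "data.frame"))
}

#' Look up the annual death probability at an age
#'
#' @param lt A [life_table()].
#' @param age Age in whole years (vectorised).
#' @return Annual probability of death before the next birthday.
#' @export
lookup_qx <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  i <- match(as.integer(age), lt$age)
  if (anyNA(i)) {
    bad <- age[is.na(i)]
    stop("age ", paste(bad, collapse = ", "),
         " not covered by the life table (ages ",
         lt$age[1], "-", attr(lt, "max_age"), ")", call. = FALSE)
  }
  lt$qx[i]
}

#' Read / write a life table as CSV
#'
#' The on-disk interface is a plain CSV with header \code{age,qx}, one row per
#' contiguous integer age.
#'
#' @param path File path.
#' @return \code{read_life_table} returns a [life_table()];
#'   \code{write_life_table} returns \code{path} invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df))) {
    stop("life table CSV must have columns 'age' and 'qx': ", path, call. = FALSE)
  }
  life_table(df$age, df$qx)
}

#' @rdname read_life_table
#' @param lt A [life_table()].
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt)[, c("age", "qx")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table: ages ", x$age[1], "-", attr(x, "max_age"),
      " (terminal qx = 1)\n", sep = "")
  invisible(x)
}
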