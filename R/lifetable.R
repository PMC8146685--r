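#' Construct a period life table
#'
#' A period life table holds, for each integer age, the annual probability
#' \code{qx} of dying within the year. It supplies background (all-cause)
#' mortality to the disease model; GEP-NET deaths are modelled separately and
#' are not subtracted from \code{qx}.
#'
#' @param age Integer vector of ages in years; must be contiguous with step 1
#'   and ascending.
#' @param qx Numeric vector of annual death probabilities in \code{[0, 1]},
#'   one per age. The terminal age must have \code{qx == 1} (the table closes
#'   out: everyone dies by its end).
#'
#' @return A \code{data.frame} of class \code{"life_table"} with columns
#'   \code{age} and \code{qx}.
#' @seealso [read_life_table()], [synth_life_table()], [life_expectancy()]
#' @export
#' @examples
#' lt <- life_table(age = 60:62, qx = c(0.011, 0.012, 1))
life_table <- function(age, qx) {
  if (length(age) != length(qx)) {
    stop("`age` and `qx` must have the same length", call. = FALSE)
  }
  if (length(age) < 2L) stop("a life table needs at least two ages", call. = FALSE)
  if (anyNA(age) || anyNA(qx)) stop("life table contains missing values", call. = FALSE)
  if (any(age != as.integer(age))) stop("ages must be integers", call. = FALSE)
  age <- as.integer(age)
  if (anyDuplicated(age)) {
    stop("duplicate age ", age[anyDuplicated(age)], " in life table", call. = FALSE)
  }
  if (is.unsorted(age, strictly = TRUE)) stop("ages must be ascending", call. = FALSE)
  if (any(diff(age) != 1L)) {
    gap <- age[which(diff(age) != 1L)[1L]]
    stop("ages must be contiguous (gap after age ", gap, ")", call. = FALSE)
  }
  bad <- which(qx < 0 | qx > 1)
  if (length(bad)) {
    stop("qx outside [0, 1] at age ", age[bad[1L]], " (qx = ", qx[bad[1L]], ")",
         call. = FALSE)
  }
  if (qx[length(qx)] != 1) {
    stop("terminal age ", age[length(age)], " must have qx = 1", call. = FALSE)
  }
  structure(data.frame(age = age, qx = as.numeric(qx)),
            class = c("life_table", "data.frame"))
}

#' Read a life table from a CSV file or connection
#'
#' Expects two columns, age and annual death probability, in that order. A
#' header row (\code{age,qx}) is optional. Validation is as in
#' [life_table()]: rows are sorted by age, and duplicated or non-contiguous
#' ages, or probabilities outside \code{[0, 1]}, are rejected with the
#' offending row named.
#'
#' @param source Path or connection to a two-column CSV.
#' @return A \code{life_table}.
#' @export
read_life_table <- function(source) {
  raw <- utils::read.csv(source, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#", strip.white = TRUE)
  if (ncol(raw) < 2L) stop("life table CSV needs two columns (age, qx)", call. = FALSE)
  raw <- raw[, 1:2]
  # drop an optional header row
  if (is.character(raw[[1L]]) && suppressWarnings(is.na(as.numeric(raw[1L, 1L])))) {
    raw <- raw[-1L, , drop = FALSE]
  }
  age <- suppressWarnings(as.numeric(raw[[1L]]))
  qx <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(age) | is.na(qx))
  if (length(bad)) {
    stop("malformed life table row ", bad[1L], ": ",
         paste(unlist(raw[bad[1L], ]), collapse = ","), call. = FALSE)
  }
  ord <- order(age)
  life_table(age = age[ord], qx = qx[ord])
}

#' Write a life table to CSV
#'
#' Writes the \code{age,qx} serialization read back by [read_life_table()]
#' (round-trip identity).
#'
#' @param lt A \code{life_table}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Builds a life table from the Gompertz-Makeham hazard
#' \eqn{h(t) = a e^{b t} + c}: annual death probabilities are
#' \deqn{q(x) = 1 - \exp(-c - (a/b)(e^{b(x+1)} - e^{b x})),}
#' clamped to \code{[0, 1]}, with the terminal age forced to \eqn{q = 1}.
#' Useful when a national period table is not at hand, and for engine
#' validation (a constant hazard \code{c} with \code{a} tiny gives a
#' geometric survival curve with known life expectancy \code{1/c}).
#'
#' @param a Baseline Gompertz hazard at age 0 (> 0).
#' @param b Gompertz log-slope per year of age (> 0).
#' @param c Makeham age-independent hazard (>= 0).
#' @param age_min,age_max Integer age range of the table.
#' @return A \code{life_table} covering \code{age_min:age_max}.
#' @export
#' @examples
#' lt <- synth_life_table(a = 6.4e-5, b = 0.085, c = 5e-4)
#' life_expectancy(lt, 60)
synth_life_table <- function(a, b, c = 0, age_min = 0, age_max = 100) {
  if (!is.numeric(a) || a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (!is.numeric(b) || b <= 0) stop("`b` must be > 0", call. = FALSE)
  if (!is.numeric(c) || c < 0) stop("`c` must be >= 0", call. = FALSE)
  if (age_min >= age_max) stop("`age_min` must be < `age_max`", call. = FALSE)
  x <- age_min:age_max
  q <- 1 - exp(-c - (a / b) * (exp(b * (x + 1)) - exp(b * x)))
  q <- pmin(pmax(q, 0), 1)
  q[length(q)] <- 1
  life_table(age = x, qx = q)
}

#' The life table bundled with the package
#'
#' A synthetic Gompertz-Makeham period table (both sexes, all causes)
#' calibrated to approximate contemporary US all-cause mortality at the ages
#' the model visits (q at age 60 about 0.011; remaining life expectancy at 60
#' about 21.6 years). It is generated by [synth_life_table()] with
#' \code{a = 6.4e-5}, \code{b = 0.085}, \code{c = 5e-4} over ages 0-100 and is
#' shipped as \code{extdata/lifetable_us_synthetic.csv}; it is a synthetic
#' stand-in, not a published national table.
#'
#' @return A \code{life_table} for ages 0-100.
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "lifetable_us_synthetic.csv",
                      package = "gepnetcea", mustWork = TRUE)
  read_life_table(path)
}

#' Convert an annual probability to a per-cycle probability
#'
#' Assumes a constant hazard within the year:
#' \code{1 - (1 - q)^(1/cycles_per_year)}. Composing the result
#' \code{cycles_per_year} times recovers \code{q} exactly.
#'
#' @param q_annual Annual probability in \code{[0, 1]} (vectorised).
#' @param cycles_per_year Positive integer number of model cycles per year.
#' @return Per-cycle probability, same length as \code{q_annual}.
#' @export
annual_to_cycle_prob <- function(q_annual, cycles_per_year = 12L) {
  if (any(is.na(q_annual)) || any(q_annual < 0 | q_annual > 1)) {
    stop("`q_annual` must be in [0, 1]", call. = FALSE)
  }
  if (length(cycles_per_year) != 1L || cycles_per_year < 1 ||
      cycles_per_year != as.integer(cycles_per_year)) {
    stop("`cycles_per_year` must be a positive integer", call. = FALSE)
  }
  1 - (1 - q_annual)^(1 / cycles_per_year)
}

#' Remaining life expectancy from a life table
#'
#' Sums the survival curve implied by \code{qx} from \code{start_age} to the
#' table's end, with a trapezoidal within-year correction (deaths counted as
#' occurring mid-year on average). Used as an independent check of the Markov
#' engine in the no-disease limit.
#'
#' @param lt A \code{life_table}.
#' @param start_age Integer age within the table range.
#' @return Expected remaining years of life at \code{start_age}.
#' @export
life_expectancy <- function(lt, start_age) {
  stopifnot(inherits(lt, "life_table"))
  if (start_age < lt$age[1L] || start_age > lt$age[nrow(lt)]) {
    stop("`start_age` ", start_age, " outside table range [",
         lt$age[1L], ", ", lt$age[nrow(lt)], "]", call. = FALSE)
  }
  q <- lt$qx[lt$age >= start_age]
  s <- cumprod(c(1, 1 - q))          # survival at the start of each year
  sum((s[-length(s)] + s[-1L]) / 2)  # trapezoid: deaths at mid-year
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages %d-%d, q(%d) = %.4g, terminal q = %g\n",
              x$age[1L], x$age[nrow(x)], x$age[1L], x$qx[1L], x$qx[nrow(x)]))
  invisible(x)
}
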