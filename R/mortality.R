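#' Load a cohort life table from CSV
#'
#' Reads a cohort life table in the simple tabular layout
#' `birth_year,sex,age,q`: one row per (birth year, sex, age) giving the
#' annual conditional death probability q for that birth cohort at that age.
#' Birth years are tabulated on a (typically decadal) grid; cohorts between
#' grid years are obtained by [interpolate_schedule()].
#'
#' @param path path to the CSV file.
#' @param sex optional sex label; if given, the table is restricted to rows
#'   with that label (the packaged fixture is males-only).
#' @return An object of class `life_table`: a list with elements `sex`,
#'   `birth_years` (increasing integer grid), `ages` (contiguous integer
#'   range) and `q`, an ages x birth-years matrix of death probabilities.
#' @seealso [interpolate_schedule()], [gompertz_schedule()]
#' @examples
#' lt <- load_life_table(system.file("extdata", "life_table_synthetic.csv",
#'                                   package = "crthresh"))
#' lt$birth_years
#' @export
load_life_table <- function(path, sex = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("birth_year", "sex", "age", "q")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("life table file is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(sex)) df <- df[df$sex == sex, , drop = FALSE]
  if (!nrow(df)) stop("life table has no rows", if (!is.null(sex))
    paste0(" for sex '", sex, "'"))
  sexes <- unique(df$sex)
  if (length(sexes) > 1L)
    stop("life table mixes sexes (", paste(sexes, collapse = ", "),
         "); pass `sex` to select one")
  df$q <- as.numeric(df$q)
  if (anyNA(df$q)) stop("non-numeric q values in life table")
  if (any(df$q < 0 | df$q > 1))
    stop("life table q values outside [0, 1]")
  if (anyDuplicated(df[c("birth_year", "age")]))
    stop("duplicated (birth_year, age) keys in life table")
  birth_years <- sort(unique(df$birth_year))
  ages <- sort(unique(df$age))
  if (!identical(ages, seq(min(ages), max(ages))))
    stop("age coverage is not contiguous")
  q <- matrix(NA_real_, nrow = length(ages), ncol = length(birth_years),
              dimnames = list(ages, birth_years))
  q[cbind(match(df$age, ages), match(df$birth_year, birth_years))] <- df$q
  if (anyNA(q))
    stop("life table is not complete over its birth_year x age grid")
  structure(list(sex = sexes, birth_years = birth_years, ages = ages, q = q),
            class = "life_table")
}

#' Annual mortality schedule for a birth cohort
#'
#' Extracts the annual baseline death probabilities B_t, t = 0..n_years-1,
#' for a cohort enrolled at `start_age`, interpolating linearly (age-wise,
#' on the probability scale) between the two tabulated birth years that
#' bracket `birth_year`. Birth years on the grid return tabulated values
#' exactly.
#'
#' @param table a `life_table` from [load_life_table()].
#' @param birth_year birth year of the cohort (within the grid span).
#' @param start_age age at enrolment, years.
#' @param n_years length of follow-up, years.
#' @return An object of class `mortality_schedule`: list with `start_age`,
#'   `n_years` and `q`, the vector of annual death probabilities.
#' @examples
#' lt <- load_life_table(system.file("extdata", "life_table_synthetic.csv",
#'                                   package = "crthresh"))
#' sched <- interpolate_schedule(lt, birth_year = 1940, start_age = 60,
#'                               n_years = 20)
#' @export
interpolate_schedule <- function(table, birth_year, start_age, n_years) {
  stopifnot(inherits(table, "life_table"), n_years >= 1)
  by <- table$birth_years
  if (birth_year < min(by) || birth_year > max(by))
    stop("birth_year ", birth_year, " outside life-table grid span [",
         min(by), ", ", max(by), "]")
  ages <- start_age + seq_len(n_years) - 1L
  if (min(ages) < min(table$ages) || max(ages) > max(table$ages))
    stop("requested ages ", min(ages), "-", max(ages),
         " not covered by the life table")
  rows <- match(ages, table$ages)
  hi <- findInterval(birth_year, by, all.inside = TRUE) + 1L
  lo <- hi - 1L
  if (birth_year == by[lo]) {
    q <- table$q[rows, lo]
  } else if (birth_year == by[hi]) {
    q <- table$q[rows, hi]
  } else {
    w <- (birth_year - by[lo]) / (by[hi] - by[lo])
    q <- (1 - w) * table$q[rows, lo] + w * table$q[rows, hi]
  }
  new_mortality_schedule(unname(q), start_age)
}

#' Gompertz mortality schedule
#'
#' Parametric stand-in for a tabulated life table: annual death
#' probabilities doubling every `doubling_time` years from `q0` at
#' enrolment, clamped at 1. Exponentially rising annual mortality is the
#' classical Gompertz description of adult human mortality over ages 60-80,
#' the range this simulation uses.
#'
#' @param q0 annual death probability at `start_age`, in (0, 1).
#' @param doubling_time mortality doubling time, years (> 0).
#' @param start_age age at enrolment, years.
#' @param n_years length of follow-up, years.
#' @return A `mortality_schedule` (see [interpolate_schedule()]).
#' @examples
#' gompertz_schedule(q0 = 0.011, doubling_time = 8.3, start_age = 60,
#'                   n_years = 20)
#' @export
gompertz_schedule <- function(q0 = 0.011, doubling_time = 8.3,
                              start_age = 60, n_years = 20) {
  if (!(q0 > 0 && q0 < 1)) stop("q0 must lie in (0, 1)")
  if (!(doubling_time > 0)) stop("doubling_time must be positive")
  t <- seq_len(n_years) - 1
  new_mortality_schedule(pmin(1, q0 * 2 ^ (t / doubling_time)), start_age)
}

new_mortality_schedule <- function(q, start_age) {
  stopifnot(all(q >= 0 & q <= 1))
  structure(list(start_age = start_age, n_years = length(q), q = q),
            class = "mortality_schedule")
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat("Annual mortality schedule: ages", x$start_age, "to",
      x$start_age + x$n_years - 1, "\n")
  cat("  q range:", format(min(x$q), digits = 4), "to",
      format(max(x$q), digits = 4), "\n")
  invisible(x)
}

#' @export
print.life_table <- function(x, ...) {
  cat("Cohort life table (", x$sex, "): birth years ",
      paste(x$birth_years, collapse = ", "), "; ages ", min(x$ages), "-",
      max(x$ages), "\n", sep = "")
  invisible(x)
}

#' Packaged synthetic life table
#'
#' Convenience loader for the males-only life-table fixture shipped with the
#' package (birth years 1930/1940/1950, ages 60-80, Gompertz-generated with
#' a mild secular improvement across cohorts; the 1940 column equals the
#' [gompertz_schedule()] defaults).
#'
#' @return A `life_table`.
#' @export
default_life_table <- function() {
  load_life_table(system.file("extdata", "life_table_synthetic.csv",
                              package = "crthresh", mustWork = TRUE))
}
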