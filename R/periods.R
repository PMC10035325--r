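#' Define a study period
#'
#' A study period is a labelled, inclusive window of calendar years. The
#' analysis convention throughout the package is that a date `d` falls within a
#' period iff `start_year <= year(d) <= end_year`, matching the calendar-year
#' aggregation of 5-year ACS products.
#'
#' @param label Character label, e.g. `"2005-2009"`.
#' @param start_year,end_year Inclusive calendar years, `start_year <= end_year`.
#' @return An object of class `study_period`: a list with `label`,
#'   `start_year`, `end_year`.
#' @examples
#' study_period("2005-2009", 2005, 2009)
#' @export
study_period <- function(label, start_year, end_year) {
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  stopifnot(length(label) == 1L, length(start_year) == 1L, length(end_year) == 1L)
  if (is.na(start_year) || is.na(end_year) || start_year > end_year) {
    stop("study_period: need start_year <= end_year")
  }
  structure(list(label = as.character(label), start_year = start_year,
                 end_year = end_year),
            class = "study_period")
}

#' The three canonical 5-year study periods
#'
#' Returns the ACS-aligned windows 2005-2009, 2010-2014, 2015-2019 used by the
#' longitudinal analysis. Any other non-overlapping windows are equally
#' accepted by the pipeline functions.
#'
#' @return A named list of [study_period()] objects.
#' @export
canonical_periods <- function() {
  ps <- list(study_period("2005-2009", 2005, 2009),
             study_period("2010-2014", 2010, 2014),
             study_period("2015-2019", 2015, 2019))
  names(ps) <- vapply(ps, `[[`, "", "label")
  ps
}

#' @export
print.study_period <- function(x, ...) {
  cat(sprintf("<study_period> %s [%d, %d]\n", x$label, x$start_year, x$end_year))
  invisible(x)
}

as_period <- function(x) {
  if (inherits(x, "study_period")) return(x)
  if (is.list(x) && all(c("label", "start_year", "end_year") %in% names(x))) {
    return(study_period(x$label, x$start_year, x$end_year))
  }
  if (is.numeric(x) && length(x) == 2L) {
    return(study_period(paste0(x[1], "-", x[2]), x[1], x[2]))
  }
  stop("cannot interpret object as a study period")
}

as_period_list <- function(x) {
  if (inherits(x, "study_period")) x <- list(x)
  ps <- lapply(x, as_period)
  names(ps) <- vapply(ps, `[[`, "", "label")
  if (anyDuplicated(names(ps))) stop("duplicate period labels")
  ps
}

check_periods_disjoint <- function(periods) {
  periods <- as_period_list(periods)
  yrs <- unlist(lapply(periods, function(p) p$start_year:p$end_year))
  if (anyDuplicated(yrs)) stop("study periods overlap")
  invisible(periods)
}

#' Parse well dates
#'
#' Accepts ISO-8601 dates (`"2005-03-01"`) and year-only strings (`"2005"`,
#' mapped to July 1 of that year, the mid-year convention that minimises bias
#' for mixed-granularity extracts). Empty strings and `NA` become `NA`.
#'
#' @param x Character (or Date) vector.
#' @return A `Date` vector; unparseable non-empty entries raise an error.
#' @export
parse_well_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  blank <- is.na(x) | !nzchar(trimws(x))
  x2 <- trimws(x[!blank])
  if (length(x2)) {
    yearish <- grepl("^[0-9]{4}$", x2)
    parsed <- rep(as.Date(NA), length(x2))
    if (any(yearish)) {
      parsed[yearish] <- as.Date(paste0(x2[yearish], "-07-01"))
    }
    if (any(!yearish)) {
      parsed[!yearish] <- as.Date(x2[!yearish], format = "%Y-%m-%d")
    }
    if (anyNA(parsed)) {
      bad <- x2[is.na(parsed)]
      stop("unparseable date value(s): ", paste(utils::head(bad, 5), collapse = ", "))
    }
    out[!blank] <- parsed
  }
  out
}

#' Shift a date forward by whole calendar years
#'
#' Calendar-exact shift (same month and day, `k` years later); February 29
#' maps to March 1 in non-leap target years. Used for the 8-year long-term
#' idle rule.
#'
#' @param d Date vector (NA allowed).
#' @param k Integer number of years (default 8).
#' @return Date vector.
#' @export
shift_years <- function(d, k = 8L) {
  out <- rep(as.Date(NA), length(d))
  ok <- !is.na(d)
  if (any(ok)) {
    lt <- as.POSIXlt(d[ok])
    y <- lt$year + 1900L + as.integer(k)
    m <- lt$mon + 1L
    day <- lt$mday
    leap <- (y %% 4 == 0 & y %% 100 != 0) | (y %% 400 == 0)
    feb29 <- m == 2L & day == 29L & !leap
    m[feb29] <- 3L
    day[feb29] <- 1L
    out[ok] <- as.Date(sprintf("%04d-%02d-%02d", y, m, day))
  }
  out
}

date_year <- function(d) as.integer(format(d, "%Y"))

year_in_period <- function(y, period) {
  !is.na(y) & y >= period$start_year & y <= period$end_year
}
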