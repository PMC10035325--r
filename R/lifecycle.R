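#' Cumulative production volume within a study period
#'
#' Sums a well's annual BOE over the calendar years of the period; zero when
#' the well produced in none of those years.
#'
#' @param well A [well_record()].
#' @param period A [study_period()].
#' @return Non-negative scalar BOE.
#' @export
cumulative_boe <- function(well, period) {
  period <- as_period(period)
  if (!length(well$annual_boe)) return(0)
  yrs <- as.integer(names(well$annual_boe))
  sum(well$annual_boe[yrs >= period$start_year & yrs <= period$end_year])
}

preproduction_interval <- function(well) {
  # Interval of calendar years during which the well counts as "new":
  # [spud, completion]; right-open-ended when completion is missing; the
  # single completion year when spud is missing (conservative point interval,
  # since completion marks the end of preproduction); NULL when both absent.
  sp <- well$spud_date
  cp <- well$completion_date
  if (!is.na(sp)) {
    c(date_year(sp), if (is.na(cp)) Inf else date_year(cp))
  } else if (!is.na(cp)) {
    rep(date_year(cp), 2L)
  } else {
    NULL
  }
}

#' Is a well new (in preproduction) during a period?
#'
#' A well is new when its preproduction interval, from spud (start of
#' drilling) to completion (ready to produce), overlaps the period's calendar
#' window. A missing completion date leaves the interval open-ended on the
#' right; a well with no spud date is new only in its completion year (and
#' never new if both dates are absent).
#'
#' @inheritParams cumulative_boe
#' @return Logical scalar.
#' @export
is_new <- function(well, period) {
  period <- as_period(period)
  iv <- preproduction_interval(well)
  if (is.null(iv)) return(FALSE)
  iv[1] <= period$end_year && iv[2] >= period$start_year
}

#' Is a well active (producing) during a period?
#'
#' Active means strictly positive cumulative BOE produced in any year of the
#' period. A well can be both new and active in the same 5-year window (e.g.
#' spudded in its first year, producing in its second); both memberships are
#' kept.
#'
#' @inheritParams cumulative_boe
#' @return Logical scalar.
#' @export
is_active <- function(well, period) {
  cumulative_boe(well, period) > 0
}

#' Start of a well's postproduction phase
#'
#' The reported abandonment date when present; otherwise the last production
#' date shifted forward exactly 8 calendar years (the state long-term idle
#' definition); `NA` when neither date is reported.
#'
#' @param well A [well_record()].
#' @param idle_years Years without production after which an unabandoned well
#'   counts as having entered postproduction (default 8, the statutory
#'   long-term idle definition).
#' @return A `Date` or `NA`.
#' @export
postproduction_start <- function(well, idle_years = 8L) {
  if (!is.na(well$abandonment_date)) return(well$abandonment_date)
  if (!is.na(well$last_prod_date)) {
    return(shift_years(well$last_prod_date, idle_years))
  }
  as.Date(NA)
}

#' Is a well retired during a period?
#'
#' Retired means the well entered postproduction (by reported abandonment or
#' the 8-year idle rule) in a calendar year within the period.
#'
#' @inheritParams cumulative_boe
#' @inheritParams postproduction_start
#' @return Logical scalar.
#' @export
is_retired <- function(well, period, idle_years = 8L) {
  period <- as_period(period)
  ps <- postproduction_start(well, idle_years)
  !is.na(ps) && year_in_period(date_year(ps), period)
}

#' Is a well plugged as of a reference year? (cross-sectional)
#'
#' Plugged status is a cross-section relative to a reference year (2019 for
#' the canonical analysis): the well's status marker is plugged and its
#' abandonment date, when reported, is not after the reference year. Plugged
#' wells with no reported dates at all are assumed plugged before the
#' reference year and included.
#'
#' @param well A [well_record()].
#' @param reference_year Integer calendar year (default 2019).
#' @return Logical scalar.
#' @export
is_plugged <- function(well, reference_year = 2019L) {
  if (!identical(well$status, "plugged")) return(FALSE)
  ab <- well$abandonment_date
  is.na(ab) || date_year(ab) <= as.integer(reference_year)
}

#' Assign life-cycle stages to every well for every study period
#'
#' Vectorised driver over the wells and production tables. For each
#' well-period the stage set is any subset of \{new, active, retired\} (dual
#' membership allowed), plus a cross-sectional plugged flag relative to
#' `reference_year`. `retirement_source` records whether the postproduction
#' start came from a reported abandonment date (`"abandonment"`) or the
#' 8-year idle rule (`"idle"`), which supports the plugged-vs-long-term-idle
#' split among retirements.
#'
#' @param wells Wells data frame (see [well_records()]).
#' @param production Long-format production data frame.
#' @param periods A [study_period()] or list of them.
#' @param reference_year Reference year for the plugged cross-section.
#' @inheritParams postproduction_start
#' @return Data frame with one row per well x period: `well_id`, `period`,
#'   logical `new`, `active`, `retired`, `plugged`, `retirement_source`
#'   (`NA` when no postproduction start exists), and `cum_boe` (cumulative
#'   BOE within the period).
#' @export
assign_stages <- function(wells, production, periods,
                          reference_year = 2019L, idle_years = 8L) {
  wells <- validate_wells(wells)
  production <- validate_production(production, wells$well_id)
  periods <- as_period_list(periods)
  if (!nrow(wells)) {
    return(data.frame(well_id = character(), period = character(),
                      new = logical(), active = logical(), retired = logical(),
                      plugged = logical(), retirement_source = character(),
                      cum_boe = numeric(), stringsAsFactors = FALSE))
  }

  spud_y <- date_year(wells$spud_date)
  comp_y <- date_year(wells$completion_date)
  pre_lo <- ifelse(!is.na(spud_y), spud_y, comp_y)
  pre_hi <- ifelse(!is.na(spud_y) & is.na(comp_y), Inf,
                   ifelse(!is.na(comp_y), comp_y, -Inf))
  pre_hi[is.na(pre_lo)] <- -Inf
  pre_lo[is.na(pre_lo)] <- Inf

  post_start <- wells$abandonment_date
  use_idle <- is.na(post_start) & !is.na(wells$last_prod_date)
  post_start[use_idle] <- shift_years(wells$last_prod_date[use_idle], idle_years)
  post_y <- date_year(post_start)
  retirement_source <- ifelse(!is.na(wells$abandonment_date), "abandonment",
                              ifelse(use_idle, "idle", NA_character_))

  ab_y <- date_year(wells$abandonment_date)
  plugged <- wells$status == "plugged" &
    (is.na(ab_y) | ab_y <= as.integer(reference_year))

  out <- lapply(periods, function(p) {
    in_win <- production$year >= p$start_year & production$year <= p$end_year
    cum <- stats::setNames(numeric(nrow(wells)), wells$well_id)
    if (any(in_win)) {
      agg <- tapply(production$boe[in_win], production$well_id[in_win], sum)
      cum[names(agg)] <- as.numeric(agg)
    }
    data.frame(well_id = wells$well_id, period = p$label,
               new = pre_lo <= p$end_year & pre_hi >= p$start_year,
               active = cum > 0,
               retired = !is.na(post_y) & post_y >= p$start_year & post_y <= p$end_year,
               plugged = plugged,
               retirement_source = retirement_source,
               cum_boe = as.numeric(cum),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
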