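#' Construct a single well record
#'
#' A well record bundles one well's location (projected planar metres), its
#' life-cycle dates, regulatory status, and annual production volumes in
#' barrels of oil equivalent (BOE).
#'
#' @param well_id Unique identifier (string).
#' @param x,y Planar coordinates in metres (projected, equal-area CRS).
#' @param status One of `"producing"`, `"idle"`, `"plugged"`, `"unknown"`.
#' @param spud_date,completion_date,first_prod_date,last_prod_date,abandonment_date
#'   `Date` scalars or `NA` (strings are parsed with [parse_well_date()]).
#' @param well_type Free-form type string.
#' @param annual_boe Named numeric vector: names are calendar years, values
#'   are non-negative production volumes in BOE. Negative values are clamped
#'   to zero with a warning (production ledgers occasionally carry negative
#'   adjustment rows; the activity rule is defined on produced volume).
#' @return A list of class `well_record`.
#' @examples
#' w <- well_record("W1", 0, 0, spud_date = "2005-03-01",
#'                  completion_date = "2006-02-01",
#'                  annual_boe = c("2006" = 100, "2007" = 50))
#' @export
well_record <- function(well_id, x, y, status = "unknown",
                        spud_date = NA, completion_date = NA,
                        first_prod_date = NA, last_prod_date = NA,
                        abandonment_date = NA, well_type = "oil_gas",
                        annual_boe = numeric()) {
  spud_date <- parse_well_date(spud_date)
  completion_date <- parse_well_date(completion_date)
  first_prod_date <- parse_well_date(first_prod_date)
  last_prod_date <- parse_well_date(last_prod_date)
  abandonment_date <- parse_well_date(abandonment_date)
  if (!is.na(spud_date) && !is.na(completion_date) && spud_date > completion_date) {
    warning(sprintf("well %s: spud_date after completion_date", well_id))
  }
  annual_boe <- unlist(annual_boe)
  if (length(annual_boe)) {
    yrs <- suppressWarnings(as.integer(names(annual_boe)))
    if (anyNA(yrs) || any(yrs < 1850L)) {
      stop(sprintf("well %s: annual_boe must be named by calendar years >= 1850", well_id))
    }
    if (any(annual_boe < 0, na.rm = TRUE)) {
      warning(sprintf("well %s: negative annual BOE clamped to 0", well_id))
      annual_boe <- pmax(annual_boe, 0)
    }
  }
  structure(list(well_id = as.character(well_id), x = as.numeric(x),
                 y = as.numeric(y), status = match.arg(status,
                 c("unknown", "producing", "idle", "plugged")),
                 spud_date = spud_date, completion_date = completion_date,
                 first_prod_date = first_prod_date,
                 last_prod_date = last_prod_date,
                 abandonment_date = abandonment_date,
                 well_type = as.character(well_type),
                 annual_boe = annual_boe),
            class = "well_record")
}

#' @export
print.well_record <- function(x, ...) {
  cat(sprintf("<well_record> %s (%s) at (%.0f, %.0f), %d production year(s)\n",
              x$well_id, x$status, x$x, x$y, length(x$annual_boe)))
  invisible(x)
}

#' Convert wells and production tables into a list of well records
#'
#' @param wells Data frame with columns `well_id`, `x`, `y`, `status`,
#'   `spud_date`, `completion_date`, `first_prod_date`, `last_prod_date`,
#'   `abandonment_date`, `well_type` (date columns as `Date` or parseable
#'   strings, empty string = absent).
#' @param production Long-format data frame with columns `well_id`, `year`,
#'   `boe` (one row per well-year).
#' @return List of [well_record()] objects, named by `well_id`.
#' @export
well_records <- function(wells, production = NULL) {
  wells <- validate_wells(wells)
  production <- validate_production(production, wells$well_id)
  boe_by_well <- split(production[c("year", "boe")], production$well_id)
  lapply(stats::setNames(seq_len(nrow(wells)), wells$well_id), function(i) {
    row <- wells[i, ]
    pb <- boe_by_well[[row$well_id]]
    ab <- if (is.null(pb)) numeric() else stats::setNames(pb$boe, pb$year)
    well_record(row$well_id, row$x, row$y, row$status, row$spud_date,
                row$completion_date, row$first_prod_date, row$last_prod_date,
                row$abandonment_date, row$well_type, ab)
  })
}

well_date_cols <- c("spud_date", "completion_date", "first_prod_date",
                    "last_prod_date", "abandonment_date")

# Degree-valued coordinates make a metric buffer meaningless. Heuristic: all
# values inside the lon/lat range and at least one with a fractional part
# (projected metre coordinates essentially never satisfy both).
looks_geographic <- function(x, y) {
  length(x) > 0 &&
    all(abs(x) <= 180, na.rm = TRUE) && all(abs(y) <= 90, na.rm = TRUE) &&
    any(x %% 1 != 0 | y %% 1 != 0, na.rm = TRUE)
}

#' Validate a wells table
#'
#' Checks required columns, unique ids, parses dates, and refuses coordinates
#' that look geographic (degrees): a 1 km planar buffer is meaningless in
#' degree units, so reprojection to an equal-area metric CRS is a required
#' pre-step.
#'
#' @param wells Data frame (see [well_records()]).
#' @return The validated data frame with `Date`-typed date columns.
#' @export
validate_wells <- function(wells) {
  req <- c("well_id", "x", "y", well_date_cols)
  miss <- setdiff(req, names(wells))
  if (length(miss)) stop("wells table missing column(s): ", paste(miss, collapse = ", "))
  if (!"status" %in% names(wells)) wells$status <- "unknown"
  if (!"well_type" %in% names(wells)) wells$well_type <- "oil_gas"
  wells$well_id <- as.character(wells$well_id)
  dup <- wells$well_id[duplicated(wells$well_id)]
  if (length(dup)) stop("duplicate well_id(s): ", paste(unique(dup), collapse = ", "))
  wells$x <- as.numeric(wells$x)
  wells$y <- as.numeric(wells$y)
  if (looks_geographic(wells$x, wells$y)) {
    stop("well coordinates appear to be geographic degrees; ",
         "project to an equal-area CRS in metres first")
  }
  for (col in well_date_cols) wells[[col]] <- parse_well_date(wells[[col]])
  bad <- !is.na(wells$spud_date) & !is.na(wells$completion_date) &
    wells$spud_date > wells$completion_date
  if (any(bad)) {
    warning("spud_date after completion_date for well(s): ",
            paste(wells$well_id[bad], collapse = ", "))
  }
  bad_status <- !wells$status %in% c("producing", "idle", "plugged", "unknown")
  if (any(bad_status)) {
    warning("unrecognised status treated as 'unknown' for well(s): ",
            paste(wells$well_id[bad_status], collapse = ", "))
    wells$status[bad_status] <- "unknown"
  }
  wells
}

#' Validate a long-format production table
#'
#' Negative BOE entries are clamped to zero with a warning; the activity rule
#' is defined on produced volume, and negative rows in real ledgers are
#' bookkeeping adjustments.
#'
#' @param production Data frame with `well_id`, `year`, `boe`; `NULL` is
#'   treated as an empty table.
#' @param known_ids Optional character vector of valid well ids; rows for
#'   unknown wells raise an error.
#' @return Validated data frame.
#' @export
validate_production <- function(production, known_ids = NULL) {
  if (is.null(production)) {
    production <- data.frame(well_id = character(), year = integer(),
                             boe = numeric())
  }
  miss <- setdiff(c("well_id", "year", "boe"), names(production))
  if (length(miss)) stop("production table missing column(s): ", paste(miss, collapse = ", "))
  production$well_id <- as.character(production$well_id)
  production$year <- as.integer(production$year)
  production$boe <- as.numeric(production$boe)
  if (nrow(production)) {
    if (anyNA(production$year) || any(production$year < 1850L)) {
      stop("production years must be calendar years >= 1850")
    }
    if (!is.null(known_ids)) {
      unk <- setdiff(production$well_id, known_ids)
      if (length(unk)) stop("production rows for unknown well_id(s): ",
                            paste(utils::head(unk, 5), collapse = ", "))
    }
    neg <- production$boe < 0
    if (any(neg, na.rm = TRUE)) {
      warning(sum(neg, na.rm = TRUE), " negative annual BOE value(s) clamped to 0")
      production$boe[neg] <- 0
    }
    production$boe[is.na(production$boe)] <- 0
  }
  production
}
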