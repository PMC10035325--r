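# Block-group containers and the demographic column schema.

#' Demographic column schema
#'
#' The seven race/ethnicity counts partition `total_population`. Each
#' socioeconomic indicator is a numerator/denominator ("universe") pair and is
#' compared against its own universe when risk ratios are formed (e.g. renter
#' households against all households). Voter-turnout fields are absent (NA)
#' for 2005-2009.
#'
#' @return A list with character vectors `race`, `numerators`, `universes`,
#'   and `all_counts` (every count column including `total_population`).
#' @export
demographic_schema <- function() {
  race <- c("hispanic_latinx", "nh_aian", "nh_asian", "nh_black", "nh_white",
            "nh_other", "nh_two_or_more")
  numerators <- c(poverty_num = "poverty_universe",
                  lt12_edu_num = "edu_universe",
                  renter_households = "total_households",
                  ling_isolated_adults = "total_adults",
                  nonvoters = "eligible_voters")
  list(race = race,
       numerators = names(numerators),
       universes = unname(numerators),
       all_counts = c("total_population", race, names(numerators),
                      unname(numerators)))
}

#' Demographic groups used in risk-ratio tables
#'
#' Maps each reported group to its count column and the universe it is
#' compared against. The `total_population` self-group is included: its risk
#' ratio is identically 1 at every scope, a useful built-in consistency check.
#'
#' @return Data frame with columns `group`, `numerator`, `universe`.
#' @export
demographic_groups <- function() {
  sc <- demographic_schema()
  data.frame(group = c("total_population", sc$race, sc$numerators),
             numerator = c("total_population", sc$race, sc$numerators),
             universe = c("total_population",
                          rep("total_population", length(sc$race)),
                          sc$universes),
             stringsAsFactors = FALSE)
}

#' Assemble a block-group set
#'
#' @param geoms Named list of geometries (names are geoids); each geometry in
#'   any form accepted by [polygon_geom()] / [multipolygon_geom()].
#' @param demo Data frame keyed by (`geoid`, `period`) with the count columns
#'   of [demographic_schema()] and optionally `county`.
#' @param repair Repair (keep, with even-odd interpretation) self-intersecting
#'   rings with a warning instead of failing.
#' @return An object of class `bg_set`: list with `geoms` (named list of
#'   geometries), `demo` (validated data frame), `area` (named m^2 vector).
#' @export
block_groups <- function(geoms, demo, repair = TRUE) {
  if (is.null(names(geoms)) || any(!nzchar(names(geoms)))) {
    stop("geoms must be a named list (names are geoids)")
  }
  if (anyDuplicated(names(geoms))) stop("duplicate geoid in geometry list")
  geoms <- lapply(geoms, as_geom)

  invalid <- !vapply(geoms, geom_is_valid, TRUE)
  if (any(invalid)) {
    if (!repair) stop("self-intersecting geometry for geoid(s): ",
                      paste(names(geoms)[invalid], collapse = ", "))
    warning(sum(invalid), " self-intersecting ring(s) repaired ",
            "(even-odd interpretation) for geoid(s): ",
            paste(names(geoms)[invalid], collapse = ", "))
  }
  area <- vapply(seq_along(geoms), function(i) {
    if (invalid[i]) geom_area_eo(geoms[[i]]) else geom_area(geoms[[i]])
  }, 0)
  names(area) <- names(geoms)
  if (any(area <= 0)) {
    stop("zero-area geometry for geoid(s): ",
         paste(names(geoms)[area <= 0], collapse = ", "))
  }

  demo <- validate_demographics(demo, names(geoms))
  structure(list(geoms = geoms, demo = demo, area = area), class = "bg_set")
}

#' @export
print.bg_set <- function(x, ...) {
  cat(sprintf("<bg_set> %d block group(s), %d block-group-period row(s)\n",
              length(x$geoms), nrow(x$demo)))
  invisible(x)
}

#' Validate a block-group demographics table
#'
#' Fatal: missing columns, duplicate (geoid, period) keys, negative counts,
#' geoids without geometry. Warnings: race/ethnicity counts summing to more
#' than 0.5% away from `total_population`, numerators exceeding their
#' universes (ACS margins of error occasionally produce both in real
#' extracts).
#'
#' @param demo Data frame (see [block_groups()]).
#' @param known_geoids Optional geoid whitelist.
#' @return Validated data frame.
#' @export
validate_demographics <- function(demo, known_geoids = NULL) {
  sc <- demographic_schema()
  req <- c("geoid", "period", setdiff(sc$all_counts, c("nonvoters", "eligible_voters")))
  miss <- setdiff(req, names(demo))
  if (length(miss)) stop("demographics missing column(s): ", paste(miss, collapse = ", "))
  if (!"nonvoters" %in% names(demo)) demo$nonvoters <- NA_real_
  if (!"eligible_voters" %in% names(demo)) demo$eligible_voters <- NA_real_
  if (!"county" %in% names(demo)) demo$county <- NA_character_
  demo$geoid <- as.character(demo$geoid)
  demo$period <- as.character(demo$period)

  key <- paste(demo$geoid, demo$period, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (geoid, period) row(s): ",
         paste(utils::head(unique(sub("\r", " / ", key[duplicated(key)])), 5),
               collapse = ", "))
  }
  if (!is.null(known_geoids)) {
    unk <- setdiff(demo$geoid, known_geoids)
    if (length(unk)) stop("demographics for geoid(s) with no geometry: ",
                          paste(utils::head(unk, 5), collapse = ", "))
  }
  for (col in sc$all_counts) {
    demo[[col]] <- as.numeric(demo[[col]])
    if (any(demo[[col]] < 0, na.rm = TRUE)) {
      stop("negative count(s) in column ", col)
    }
  }
  race_sum <- rowSums(demo[sc$race])
  off <- abs(race_sum - demo$total_population) >
    0.005 * pmax(demo$total_population, 1)
  if (any(off, na.rm = TRUE)) {
    warning(sum(off, na.rm = TRUE),
            " row(s) where race/ethnicity counts differ from total_population by > 0.5%")
  }
  for (i in seq_along(sc$numerators)) {
    num <- demo[[sc$numerators[i]]]; den <- demo[[sc$universes[i]]]
    bad <- !is.na(num) & !is.na(den) & num > den
    if (any(bad)) {
      warning(sum(bad), " row(s) where ", sc$numerators[i], " exceeds ",
              sc$universes[i])
    }
  }
  demo
}

bg_demo_period <- function(bgs, period_label) {
  d <- bgs$demo[bgs$demo$period == period_label, , drop = FALSE]
  rownames(d) <- NULL
  d
}
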