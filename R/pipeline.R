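# Run configuration, validation, and the end-to-end pipeline.

#' Build a run configuration
#'
#' @param wells,production,geographies,demographics Input file paths (CSV,
#'   CSV, GeoJSON, CSV).
#' @param out_dir Output directory.
#' @param tribal Optional tribal-lands GeoJSON path.
#' @param radius_m Buffer radius in metres (default 1,000).
#' @param n_seg Disc polygon segments (default 64).
#' @param periods List of periods; each a [study_period()] or
#'   `list(label=, start_year=, end_year=)`. Default the three canonical
#'   5-year windows. Must be non-overlapping.
#' @param reference_year Plugged cross-section reference year (default 2019).
#' @param idle_years Idle-rule horizon in years (default 8).
#' @param scopes Character vector of risk-ratio scopes (`"state"`,
#'   `"county:<name>"`).
#' @param rr_digits,pct_digits Rounding applied in the report tables (full
#'   precision is always written alongside).
#' @return A list of class `run_config`.
#' @export
run_config <- function(wells, production, geographies, demographics, out_dir,
                       tribal = NULL, radius_m = 1000, n_seg = 64L,
                       periods = canonical_periods(), reference_year = 2019L,
                       idle_years = 8L, scopes = "state",
                       rr_digits = 2L, pct_digits = 1L) {
  stopifnot(radius_m > 0, idle_years > 0)
  periods <- check_periods_disjoint(periods)
  structure(list(wells = wells, production = production,
                 geographies = geographies, demographics = demographics,
                 tribal = tribal, out_dir = out_dir, radius_m = radius_m,
                 n_seg = as.integer(n_seg), periods = periods,
                 reference_year = as.integer(reference_year),
                 idle_years = as.integer(idle_years), scopes = scopes,
                 rr_digits = as.integer(rr_digits),
                 pct_digits = as.integer(pct_digits)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `periods` entries are maps
#' with `label`, `start_year`, `end_year`. Entries in `overrides` replace
#' file values (the CLI uses this for flag overrides). Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param overrides Named list of overriding values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  }
  args <- raw
  for (key in c("wells", "production", "geographies", "demographics",
                "tribal", "out_dir")) {
    args[[key]] <- rel(raw[[key]])
  }
  if (!is.null(raw$periods)) args$periods <- lapply(raw$periods, as_period)
  do.call(run_config, args)
}

#' Load and validate all pipeline inputs
#'
#' Reads and schema-checks the wells, production, geometry, demographics and
#' optional tribal inputs, collecting every validation warning (repaired
#' geometries, clamped volumes, date-order violations, race-sum mismatches)
#' into a report. Duplicate keys, degree-valued coordinates and missing
#' required columns are fatal.
#'
#' @param config A [run_config()].
#' @return List of class `validated_dataset`: `wells`, `production`, `bgs`,
#'   `tribal` (or `NULL`), and `warnings` (character vector, the validation
#'   report).
#' @export
load_and_validate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  notes <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      notes[[length(notes) + 1L]] <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  }
  wells <- collect(read_wells(config$wells))
  production <- collect(read_production(config$production, wells$well_id))
  geoms <- collect(read_geojson(config$geographies))
  demo <- collect(read_demographics(config$demographics))
  bgs <- collect(block_groups(geoms, demo))
  tribal <- if (is.null(config$tribal)) NULL else
    collect(read_geojson(config$tribal, id_property = "land"))
  structure(list(wells = wells, production = production, bgs = bgs,
                 tribal = tribal, warnings = notes),
            class = "validated_dataset")
}

out_path <- function(config, name) file.path(config$out_dir, name)

#' Classification step: stage assignments to disk
#'
#' @param config A [run_config()].
#' @param dataset Optional pre-validated dataset (loaded from the config
#'   paths otherwise).
#' @return The assignments data frame, invisibly; writes
#'   `stage_assignments.csv`.
#' @export
step_classify <- function(config, dataset = NULL) {
  if (is.null(dataset)) dataset <- load_and_validate(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  assignments <- assign_stages(dataset$wells, dataset$production,
                               config$periods, config$reference_year,
                               config$idle_years)
  utils::write.csv(assignments, out_path(config, "stage_assignments.csv"),
                   row.names = FALSE, na = "NA")
  invisible(assignments)
}

read_assignments <- function(config) {
  utils::read.csv(out_path(config, "stage_assignments.csv"),
                  stringsAsFactors = FALSE,
                  colClasses = c(well_id = "character", period = "character",
                                 retirement_source = "character"))
}

#' Exposure step: areal apportionment and centroid intensity to disk
#'
#' Consumes `stage_assignments.csv` from the output directory (so the steps
#' compose exactly like [run_pipeline()]).
#'
#' @inheritParams step_classify
#' @return The exposure data frame, invisibly; writes `exposure.csv`.
#' @export
step_expose <- function(config, dataset = NULL) {
  if (is.null(dataset)) dataset <- load_and_validate(config)
  assignments <- read_assignments(config)
  exposure <- assess_exposure(dataset$bgs, dataset$wells, assignments,
                              config$periods, config$radius_m, config$n_seg)
  utils::write.csv(exposure, out_path(config, "exposure.csv"),
                   row.names = FALSE, na = "NA")
  invisible(exposure)
}

#' Disparity step: risk ratios, quintiles, panel change, overlays, trends
#'
#' Consumes `exposure.csv` (and the validated inputs) and writes the
#' statistical outputs: `rr.csv` (full precision) and `rr_report.csv`
#' (ratios rounded to the configured digits), `rr_quintile.csv`,
#' `panel_change.csv`, `tribal_overlay.csv`, `trends.csv`.
#'
#' @inheritParams step_classify
#' @return Invisibly, a list of the output tables.
#' @export
step_disparity <- function(config, dataset = NULL) {
  if (is.null(dataset)) dataset <- load_and_validate(config)
  exposure <- utils::read.csv(out_path(config, "exposure.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(geoid = "character",
                                             period = "character"))
  bgs <- dataset$bgs
  labels <- names(config$periods)

  rr <- do.call(rbind, lapply(config$scopes, function(sc) {
    rr_table(exposure, bgs, scope = sc)
  }))
  utils::write.csv(rr, out_path(config, "rr.csv"), row.names = FALSE, na = "NA")
  rr_report <- rr
  rr_report$rr <- round(rr_report$rr, config$rr_digits)
  utils::write.csv(rr_report, out_path(config, "rr_report.csv"),
                   row.names = FALSE, na = "NA")

  rrq <- do.call(rbind, lapply(labels, function(p) {
    rr_by_quintile(exposure, bgs, p)
  }))
  utils::write.csv(rrq, out_path(config, "rr_quintile.csv"),
                   row.names = FALSE, na = "NA")

  panel <- NULL
  if (length(labels) >= 2L) {
    pa <- labels[length(labels) - 1L]; pb <- labels[length(labels)]
    panel <- rbind(
      panel_change(exposure, exposure, bgs, pa, pb, "new_well_count"),
      panel_change(exposure, exposure, bgs, pa, pb, "cumulative_boe"))
    utils::write.csv(panel, out_path(config, "panel_change.csv"),
                     row.names = FALSE, na = "NA")
  }

  overlay <- NULL
  if (!is.null(dataset$tribal)) {
    overlay <- tribal_overlay(dataset$wells, dataset$tribal)
    utils::write.csv(overlay, out_path(config, "tribal_overlay.csv"),
                     row.names = FALSE, na = "NA")
  }

  trends <- do.call(rbind, lapply(unique(exposure$stage), function(s) {
    rows <- do.call(rbind, lapply(labels, function(p) {
      ex <- exposure[exposure$stage == s & exposure$period == p, , drop = FALSE]
      if (!nrow(ex)) return(NULL)
      demo <- bg_demo_period(bgs, p)
      data.frame(stage = s, period = p,
                 value = sum(ex$exposed_total_population),
                 universe = sum(demo$total_population),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) return(NULL)
    summarize_trends(rows)
  }))
  utils::write.csv(trends, out_path(config, "trends.csv"),
                   row.names = FALSE, na = "NA")

  invisible(list(rr = rr, rr_quintile = rrq, panel_change = panel,
                 tribal_overlay = overlay, trends = trends))
}

#' Run the full analysis pipeline
#'
#' Chains validation, stage classification, exposure assessment, and the
#' disparity statistics, writing every output table plus a validation log and
#' a manifest (echoed configuration and its MD5 hash) to the output
#' directory. Deterministic: identical inputs and configuration give
#' byte-identical output bundles.
#'
#' @param config A [run_config()] or path to a YAML run configuration.
#' @return Invisibly, a list with the assignments, exposure, and disparity
#'   tables and the validation warnings.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dataset <- load_and_validate(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  assignments <- step_classify(config, dataset)
  exposure <- step_expose(config, dataset)
  stats <- step_disparity(config, dataset)

  writeLines(c(sprintf("validation warnings: %d", length(dataset$warnings)),
               dataset$warnings),
             out_path(config, "validation_log.txt"))
  cfg_plain <- unclass(config)
  cfg_plain$periods <- lapply(cfg_plain$periods, unclass)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null")
  hash_file <- tempfile()
  writeLines(as.character(cfg_json), hash_file)
  manifest <- list(config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
                   config_md5 = unname(tools::md5sum(hash_file)),
                   n_wells = nrow(dataset$wells),
                   n_block_group_periods = nrow(dataset$bgs$demo))
  unlink(hash_file)
  jsonlite::write_json(manifest, out_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(assignments = assignments, exposure = exposure,
                 disparity = stats, warnings = dataset$warnings))
}
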