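# File ingestion and serialisation: CSV tables and GeoJSON geometries.

fmt_date_col <- function(d) {
  out <- format(d, "%Y-%m-%d")
  out[is.na(out)] <- ""
  out
}

#' Read a wells CSV
#'
#' Columns: `well_id`, `x`, `y`, `status`, the five life-cycle date columns
#' (ISO-8601 or year-only; empty = absent), `well_type`. Validated with
#' [validate_wells()].
#'
#' @param path File path.
#' @return Validated wells data frame.
#' @export
read_wells <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  validate_wells(df)
}

#' Write a wells CSV
#' @param wells Wells data frame.
#' @param path File path.
#' @export
write_wells <- function(wells, path) {
  out <- wells
  for (col in well_date_cols) {
    if (col %in% names(out)) out[[col]] <- fmt_date_col(parse_well_date(out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
}

#' Read a long-format production CSV (`well_id`, `year`, `boe`)
#' @param path File path.
#' @param known_ids Optional well-id whitelist.
#' @return Validated production data frame.
#' @export
read_production <- function(path, known_ids = NULL) {
  validate_production(utils::read.csv(path, stringsAsFactors = FALSE), known_ids)
}

#' Read a block-group demographics CSV keyed by (`geoid`, `period`)
#' @param path File path.
#' @return Data frame (validated against the schema when assembled into a
#'   [block_groups()] set).
#' @export
read_demographics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(geoid = "character"))
}

geojson_coords_to_part <- function(coords) {
  lapply(coords, function(ring) {
    as_ring(do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]]))))
  })
}

#' Read polygon geometries from GeoJSON
#'
#' Supports Polygon and MultiPolygon features. The feature property named by
#' `id_property` becomes the geometry name. Coordinates must already be in a
#' projected metric CRS; geographic-looking coordinate ranges are refused.
#'
#' @param path File path.
#' @param id_property Property carrying the identifier (default `"geoid"`).
#' @return Named list of geometries, with a `properties` attribute (data
#'   frame of all feature properties).
#' @export
read_geojson <- function(path, id_property = "geoid") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  ids <- vapply(feats, function(f) {
    v <- f$properties[[id_property]]
    if (is.null(v)) stop("feature missing property '", id_property, "'")
    as.character(v)
  }, "")
  if (anyDuplicated(ids)) {
    stop("duplicate ", id_property, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  geoms <- lapply(feats, function(f) {
    geom <- f$geometry
    parts <- switch(geom$type,
                    Polygon = list(geojson_coords_to_part(geom$coordinates)),
                    MultiPolygon = lapply(geom$coordinates, geojson_coords_to_part),
                    stop("unsupported geometry type: ", geom$type))
    multipolygon_geom(parts)
  })
  names(geoms) <- ids
  bb <- vapply(geoms, geom_bbox, numeric(4))
  if (length(geoms) &&
      looks_geographic(c(bb[1L, ], bb[3L, ]), c(bb[2L, ], bb[4L, ]))) {
    stop("geometry coordinates appear to be geographic degrees; ",
         "project to an equal-area CRS in metres first")
  }
  props <- do.call(rbind, lapply(feats, function(f) {
    as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  attr(geoms, "properties") <- props
  geoms
}

part_to_geojson_coords <- function(part) {
  lapply(part, function(ring) {
    closed <- rbind(ring, ring[1L, , drop = FALSE])
    lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1L], closed[i, 2L]))
  })
}

#' Write geometries to GeoJSON
#'
#' @param geoms Named list of geometries.
#' @param path File path.
#' @param properties Optional data frame of extra per-feature properties
#'   (row order matching `geoms`).
#' @param id_property Property name for the identifier.
#' @export
write_geojson <- function(geoms, path, properties = NULL,
                          id_property = "geoid") {
  feats <- lapply(seq_along(geoms), function(i) {
    g <- as_geom(geoms[[i]])
    geometry <- if (length(g) == 1L) {
      list(type = "Polygon", coordinates = part_to_geojson_coords(g[[1L]]))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(g, part_to_geojson_coords))
    }
    props <- stats::setNames(list(names(geoms)[i]), id_property)
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature", properties = props, geometry = geometry)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
}

#' Write a synthetic landscape to the formats the pipeline reads
#'
#' Produces `wells.csv`, `production.csv`, `blockgroups.geojson`,
#' `demographics.csv`, `tribal.geojson`, and a `manifest.json` recording the
#' generator configuration and seed.
#'
#' @param landscape Output of [generate_landscape()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(wells = file.path(dir, "wells.csv"),
             production = file.path(dir, "production.csv"),
             geographies = file.path(dir, "blockgroups.geojson"),
             demographics = file.path(dir, "demographics.csv"),
             tribal = file.path(dir, "tribal.geojson"),
             manifest = file.path(dir, "manifest.json"))
  write_wells(landscape$wells, paths[["wells"]])
  utils::write.csv(landscape$production, paths[["production"]],
                   row.names = FALSE, na = "")
  write_geojson(landscape$bgs$geoms, paths[["geographies"]])
  utils::write.csv(landscape$bgs$demo, paths[["demographics"]],
                   row.names = FALSE, na = "")
  write_geojson(landscape$tribal, paths[["tribal"]], id_property = "land")
  cfg <- landscape$config
  cfg$planted_cells <- if (is.null(cfg$planted_cells)) NULL else
    as.list(cfg$planted_cells)
  jsonlite::write_json(list(config = unclass(cfg),
                            periods = lapply(landscape$periods, unclass)),
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
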