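# Exposure assessment: areal apportionment of 1 km buffer overlap (who is
# exposed) and centroid-radius intensity (how much).

all_stages <- c("new", "active", "retired", "plugged")

#' Buffer region around all wells in a stage during a period
#'
#' The union of discs of radius `radius_m` centred on every well whose stage
#' assignment for the period includes `stage` (`"plugged"` uses the
#' cross-sectional plugged flag). Discs are approximated by regular polygons
#' with `n_seg` segments and are dissolved into one region, so overlapping
#' per-well buffers never double-count residents.
#'
#' @param wells Wells data frame.
#' @param assignments Output of [assign_stages()].
#' @param stage One of `"new"`, `"active"`, `"retired"`, `"plugged"`.
#' @param period A [study_period()] or its label.
#' @param radius_m Buffer radius in metres (> 0; default 1000).
#' @param n_seg Segments per disc polygon (default 64).
#' @return An object of class `buffer_region` with the well centres, radius,
#'   and disc rings; empty (zero wells) regions are valid and have area 0.
#' @export
stage_buffer <- function(wells, assignments, stage, period, radius_m = 1000,
                         n_seg = 64L) {
  stopifnot(radius_m > 0)
  stage <- match.arg(stage, all_stages)
  label <- if (inherits(period, "study_period")) period$label else as.character(period)
  sel <- assignments$period == label & assignments[[stage]]
  ids <- assignments$well_id[sel]
  w <- wells[wells$well_id %in% ids, , drop = FALSE]
  rings <- lapply(seq_len(nrow(w)), function(i) {
    circle_ring(w$x[i], w$y[i], radius_m, n_seg)
  })
  structure(list(centers = cbind(x = w$x, y = w$y), radius = radius_m,
                 n_seg = as.integer(n_seg), rings = rings,
                 bboxes = lapply(rings, ring_bbox)),
            class = "buffer_region")
}

#' @export
print.buffer_region <- function(x, ...) {
  cat(sprintf("<buffer_region> %d disc(s), radius %.0f m (%d-gon)\n",
              length(x$rings), x$radius, x$n_seg))
  invisible(x)
}

region_polys <- function(region) {
  if (inherits(region, "buffer_region")) return(lapply(region$rings, list))
  if (inherits(region, "wp_geom")) return(unclass(region))
  if (is.matrix(region) || is.data.frame(region)) return(list(list(as_ring(region))))
  if (is.list(region)) return(unclass(as_geom(region)))
  stop("cannot interpret object as a planar region")
}

#' Area of a planar region
#'
#' @param region A `buffer_region` or any geometry.
#' @return Area in m^2 (union area; overlaps counted once).
#' @export
region_area <- function(region) {
  scan_area(region_polys(region))
}

#' Fraction of a block group's area covered by a region
#'
#' `area(geometry intersect region) / area(geometry)`, clipped to `[0, 1]`.
#'
#' @param geom Block-group geometry (any accepted form).
#' @param region A `buffer_region` or polygonal region.
#' @return Real in `[0, 1]`.
#' @export
areal_fraction <- function(geom, region) {
  g <- as_geom(geom)
  denom <- geom_area_eo(g)
  if (denom <= 0) stop("zero-area geometry in areal_fraction")
  polys <- region_polys(region)
  if (!length(polys)) return(0)
  # cheap prefilter: drop region parts whose bbox misses the geometry bbox
  gb <- geom_bbox(g)
  keep <- vapply(polys, function(p) bbox_overlap(ring_bbox(p[[1L]]), gb), TRUE)
  if (!any(keep)) return(0)
  num <- scan_area(unclass(g), polys[keep])
  min(max(num / denom, 0), 1)
}

#' Apportion a block group's counts to its exposed fraction
#'
#' Every demographic count is multiplied by the areal fraction, unrounded:
#' a block group of 1,000 residents with 30% of its area inside the buffer
#' contributes 300 exposed residents, and 150 of them if half its residents
#' belong to the group in question. Real-valued counts preserve conservation
#' (group counts still sum to the exposed total exactly).
#'
#' @param counts Named numeric vector or one-row data frame of counts.
#' @param fraction Areal fraction in `[0, 1]`.
#' @return Named numeric vector of exposed counts.
#' @export
apportion <- function(counts, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (is.data.frame(counts)) counts <- unlist(counts[1L, , drop = TRUE])
  counts * fraction
}

#' Well counts and production volume within 1 km of the block-group centroid
#'
#' The intensity protocol: for each stage, the number of assigned wells whose
#' Euclidean distance to the area-weighted centroid is at most `radius_m`
#' (boundary-inclusive), and for the active stage the cumulative within-period
#' BOE summed over those wells.
#'
#' @param geom Block-group geometry.
#' @param wells Wells data frame.
#' @param assignments Output of [assign_stages()] (carries per-period
#'   `cum_boe`).
#' @param period A [study_period()] or label.
#' @param radius_m Radius in metres (default 1000).
#' @return List with `counts` (named integer vector over stages) and
#'   `active_boe` (scalar BOE).
#' @export
centroid_intensity <- function(geom, wells, assignments, period,
                               radius_m = 1000) {
  ctr <- geom_centroid(as_geom(geom))
  label <- if (inherits(period, "study_period")) period$label else as.character(period)
  a <- assignments[assignments$period == label, , drop = FALSE]
  a <- a[match(wells$well_id, a$well_id), , drop = FALSE]
  near <- sqrt((wells$x - ctr[1L])^2 + (wells$y - ctr[2L])^2) <= radius_m
  counts <- vapply(all_stages, function(s) sum(near & a[[s]], na.rm = TRUE), 0L)
  list(counts = counts,
       active_boe = sum(a$cum_boe[near & a$active], na.rm = TRUE))
}

#' Assess exposure for every block-group-period and stage
#'
#' Drives both protocols over all block groups: per period, one dissolved
#' buffer per stage (new, active, retired in every period; plugged in the
#' final period only, the cross-sectional convention), areal fractions and
#' apportioned counts per block group, and centroid-radius intensities.
#'
#' @param bgs A [block_groups()] set.
#' @param wells Wells data frame.
#' @param assignments Output of [assign_stages()].
#' @param periods A [study_period()] or list of them (plugged exposure is
#'   attached to the last one).
#' @param radius_m Buffer radius in metres.
#' @param n_seg Disc polygon segments.
#' @param verbose Emit a message when a centroid falls outside its polygon.
#' @return Data frame with one row per geoid x period x stage: `geoid`,
#'   `period`, `stage`, `exposed_fraction`, an `exposed_*` column per
#'   demographic count, `centroid_well_count`, and `centroid_boe` (zero for
#'   non-active stages).
#' @export
assess_exposure <- function(bgs, wells, assignments, periods,
                            radius_m = 1000, n_seg = 64L, verbose = FALSE) {
  stopifnot(inherits(bgs, "bg_set"))
  periods <- as_period_list(periods)
  sc <- demographic_schema()
  last_label <- periods[[length(periods)]]$label

  rows <- vector("list", 0L)
  for (p in periods) {
    demo <- bg_demo_period(bgs, p$label)
    stages <- c("new", "active", "retired",
                if (p$label == last_label) "plugged")
    buffers <- lapply(stats::setNames(stages, stages), function(s) {
      stage_buffer(wells, assignments, s, p, radius_m, n_seg)
    })
    for (i in seq_len(nrow(demo))) {
      geoid <- demo$geoid[i]
      g <- bgs$geoms[[geoid]]
      ci <- centroid_intensity(g, wells, assignments, p, radius_m)
      if (verbose) {
        ctr <- geom_centroid(g)
        if (!points_in_geom(ctr[1L], ctr[2L], g)) {
          message("centroid of ", geoid, " falls outside its polygon")
        }
      }
      counts <- unlist(demo[i, sc$all_counts])
      for (s in stages) {
        f <- areal_fraction(g, buffers[[s]])
        exposed <- apportion(counts, f)
        row <- data.frame(geoid = geoid, period = p$label, stage = s,
                          exposed_fraction = f, stringsAsFactors = FALSE)
        for (col in sc$all_counts) row[[paste0("exposed_", col)]] <- exposed[[col]]
        row$centroid_well_count <- ci$counts[[s]]
        row$centroid_boe <- if (s == "active") ci$active_boe else 0
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
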