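# Synthetic landscape generator.
#
# Emulates the statistical structure the analysis assumes: clustered well
# fields with coherent life histories (spud -> completion -> production years
# with log-normally skewed annual BOE -> last production -> abandonment, with
# a configurable fraction of plugged wells losing their dates), a rectangular
# block-group tessellation with ACS-like demographic counts, and an optional
# planted disparity: the target group's share is inflated near well clusters
# with an exponential distance gradient, which yields closed-form expected
# risk ratios in deterministic mode.

#' Configuration for a synthetic landscape
#'
#' Defaults emulate the magnitudes of the California study system: block
#' groups of 600-3,000 residents, ~4% statewide population growth per 5-year
#' period, base race/ethnicity shares matching the statewide 2005-2009
#' composition, production lifetimes around 10.9 +/- 8.2 years, heavily
#' right-skewed annual production, 73% of retirement entries via reported
#' abandonment (the rest via the 8-year idle rule), and 44.3% of plugged
#' wells with blanked last-production/abandonment dates.
#'
#' @param nx,ny Grid dimensions (block groups).
#' @param cell_m Cell edge length in metres. The default (2,500 m) keeps a
#'   1 km disc centred in a cell strictly inside it, which is what makes the
#'   deterministic closed-form oracle exact.
#' @param n_clusters Number of well clusters.
#' @param wells_per_cluster Poisson mean wells per cluster.
#' @param cluster_sd Cluster dispersion (metres).
#' @param spud_year_range Inclusive range of spud years.
#' @param preprod_days_range Uniform range of preproduction durations (days).
#' @param prod_gap_days_range Uniform range from completion to first
#'   production (days).
#' @param lifetime_meanlog,lifetime_sdlog Log-normal production lifetime
#'   (years); defaults give mean ~10.9 y, sd ~8.2 y.
#' @param boe_meanlog,boe_sdlog Log-normal annual BOE per producing
#'   well-year.
#' @param abandon_prob Probability that a well whose production ended gets a
#'   reported abandonment date (otherwise it retires via the idle rule).
#' @param missing_date_frac Fraction of plugged wells whose last-production
#'   and abandonment dates are blanked.
#' @param pop_range Uniform range of block-group population (sampled mode).
#' @param pop_mean Block-group population in deterministic mode.
#' @param pop_growth Multiplicative population growth per period.
#' @param base_shares Named race/ethnicity shares (normalised to sum to 1).
#' @param socio_rates Named rates for the socioeconomic numerators.
#' @param universe_fracs Named fractions of population forming each
#'   socioeconomic universe.
#' @param disparity List: `target` (race column), `multiplier` (near-cluster
#'   share multiplier; 1 = null landscape), `length_scale` (metres).
#' @param mode `"sampled"` (multinomial/binomial counts) or
#'   `"deterministic"` (expected counts; enables exact recovery tests).
#' @param planted_cells Optional data frame `ix`, `iy`, `boe_per_year`: in
#'   deterministic mode, one always-active well at each listed cell centre
#'   replaces the random well field.
#' @param final_year Last calendar year with data (default 2019).
#' @param seed Integer seed; fixes every random draw.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(nx = 6L, ny = 6L, cell_m = 2500,
                             n_clusters = 3L, wells_per_cluster = 8,
                             cluster_sd = 600,
                             spud_year_range = c(1985L, 2018L),
                             preprod_days_range = c(30, 540),
                             prod_gap_days_range = c(0, 90),
                             lifetime_meanlog = 2.165, lifetime_sdlog = 0.67,
                             boe_meanlog = 8, boe_sdlog = 2,
                             abandon_prob = 0.73,
                             missing_date_frac = 0.443,
                             pop_range = c(600, 3000), pop_mean = 1800,
                             pop_growth = 1.041,
                             base_shares = c(hispanic_latinx = 0.361,
                                             nh_aian = 0.005, nh_asian = 0.121,
                                             nh_black = 0.060, nh_white = 0.425,
                                             nh_other = 0.003,
                                             nh_two_or_more = 0.021),
                             socio_rates = c(poverty_num = 0.116,
                                             lt12_edu_num = 0.195,
                                             renter_households = 0.421,
                                             ling_isolated_adults = 0.219,
                                             nonvoters = 0.284),
                             universe_fracs = c(poverty_universe = 0.97,
                                                edu_universe = 0.65,
                                                total_households = 0.345,
                                                total_adults = 0.75,
                                                eligible_voters = 0.60),
                             disparity = list(target = "nh_black",
                                              multiplier = 1,
                                              length_scale = 1500),
                             mode = c("sampled", "deterministic"),
                             planted_cells = NULL,
                             final_year = 2019L, seed = 1L) {
  mode <- match.arg(mode)
  sc <- demographic_schema()
  stopifnot(nx >= 1, ny >= 1, cell_m > 0, cluster_sd > 0,
            all(base_shares >= 0), all(socio_rates >= 0 & socio_rates <= 1),
            all(universe_fracs > 0 & universe_fracs <= 1),
            disparity$multiplier > 0, disparity$length_scale > 0)
  if (!setequal(names(base_shares), sc$race)) {
    stop("base_shares must name exactly the race/ethnicity columns")
  }
  base_shares <- base_shares[sc$race] / sum(base_shares)
  if (!disparity$target %in% sc$race) stop("disparity target must be a race column")
  if (!is.null(planted_cells)) {
    stopifnot(mode == "deterministic",
              all(c("ix", "iy") %in% names(planted_cells)),
              all(planted_cells$ix >= 1 & planted_cells$ix <= nx),
              all(planted_cells$iy >= 1 & planted_cells$iy <= ny))
    if (is.null(planted_cells$boe_per_year)) planted_cells$boe_per_year <- 10000
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), cell_m = cell_m,
                 n_clusters = as.integer(n_clusters),
                 wells_per_cluster = wells_per_cluster,
                 cluster_sd = cluster_sd,
                 spud_year_range = as.integer(spud_year_range),
                 preprod_days_range = preprod_days_range,
                 prod_gap_days_range = prod_gap_days_range,
                 lifetime_meanlog = lifetime_meanlog,
                 lifetime_sdlog = lifetime_sdlog,
                 boe_meanlog = boe_meanlog, boe_sdlog = boe_sdlog,
                 abandon_prob = abandon_prob,
                 missing_date_frac = missing_date_frac,
                 pop_range = pop_range, pop_mean = pop_mean,
                 pop_growth = pop_growth, base_shares = base_shares,
                 socio_rates = socio_rates, universe_fracs = universe_fracs,
                 disparity = disparity, mode = mode,
                 planted_cells = planted_cells,
                 final_year = as.integer(final_year),
                 seed = as.integer(seed)),
            class = "landscape_config")
}

cell_center <- function(config, ix, iy) {
  cbind(x = (ix - 0.5) * config$cell_m, y = (iy - 0.5) * config$cell_m)
}

#' Generate synthetic wells and production records
#'
#' Sampled mode: clustered well locations, each with a coherent ordered life
#' history; a configured fraction of wells whose production ended receive a
#' reported abandonment date (status plugged), the rest stay idle and retire
#' via the 8-year rule; a configured fraction of plugged wells then lose
#' their last-production and abandonment dates. Deterministic mode with
#' `planted_cells`: one always-active well per listed cell centre.
#'
#' @param config A [landscape_config()].
#' @return List with data frames `wells` and `production`, and `clusters`
#'   (matrix of cluster centres anchoring the demographic gradient).
#' @export
generate_wells <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  fy <- config$final_year

  if (!is.null(config$planted_cells)) {
    pc <- config$planted_cells
    ctr <- cell_center(config, pc$ix, pc$iy)
    n <- nrow(pc)
    wells <- data.frame(
      well_id = sprintf("PW%03d", seq_len(n)),
      x = ctr[, "x"], y = ctr[, "y"], status = "producing",
      spud_date = as.Date("1990-03-01"),
      completion_date = as.Date("1990-09-01"),
      first_prod_date = as.Date("1991-01-15"),
      last_prod_date = as.Date(sprintf("%d-12-31", fy)),
      abandonment_date = as.Date(NA), well_type = "oil_gas",
      stringsAsFactors = FALSE)
    production <- data.frame(
      well_id = rep(wells$well_id, each = fy - 1991L + 1L),
      year = rep(1991L:fy, times = n),
      boe = rep(pc$boe_per_year, each = fy - 1991L + 1L))
    return(list(wells = wells, production = production, clusters = ctr))
  }

  W <- config$nx * config$cell_m
  H <- config$ny * config$cell_m
  clusters <- cbind(x = stats::runif(config$n_clusters, 0.15 * W, 0.85 * W),
                    y = stats::runif(config$n_clusters, 0.15 * H, 0.85 * H))
  n_per <- stats::rpois(config$n_clusters, config$wells_per_cluster)
  n <- sum(n_per)
  if (n == 0L) {
    return(list(wells = validate_wells(data.frame(
      well_id = character(), x = numeric(), y = numeric(),
      status = character(), spud_date = character(),
      completion_date = character(), first_prod_date = character(),
      last_prod_date = character(), abandonment_date = character(),
      well_type = character(), stringsAsFactors = FALSE)),
      production = data.frame(well_id = character(), year = integer(),
                              boe = numeric()),
      clusters = clusters))
  }
  ci <- rep(seq_len(config$n_clusters), n_per)
  x <- pmin(pmax(stats::rnorm(n, clusters[ci, "x"], config$cluster_sd), 0), W)
  y <- pmin(pmax(stats::rnorm(n, clusters[ci, "y"], config$cluster_sd), 0), H)

  year_pool <- config$spud_year_range[1]:config$spud_year_range[2]
  spud_year <- if (length(year_pool) == 1L) rep(year_pool, n) else
    sample(year_pool, n, replace = TRUE)
  spud <- as.Date(sprintf("%d-01-01", spud_year)) +
    sample.int(365L, n, replace = TRUE) - 1L
  completion <- spud + round(stats::runif(n, config$preprod_days_range[1],
                                          config$preprod_days_range[2]))
  first_prod <- completion + round(stats::runif(n, config$prod_gap_days_range[1],
                                                config$prod_gap_days_range[2]))
  lifetime <- pmax(stats::rlnorm(n, config$lifetime_meanlog,
                                 config$lifetime_sdlog), 1)
  last_prod <- first_prod + round(lifetime * 365.25)

  prod_rows <- lapply(seq_len(n), function(i) {
    yrs <- date_year(first_prod[i]):min(date_year(last_prod[i]), fy)
    data.frame(well_id = i, year = yrs,
               boe = stats::rlnorm(length(yrs), config$boe_meanlog,
                                   config$boe_sdlog))
  })
  production <- do.call(rbind, prod_rows)

  ended <- date_year(last_prod) <= fy
  abandoned <- ended & stats::runif(n) < config$abandon_prob
  ab_date <- rep(as.Date(NA), n)
  ab_date[abandoned] <- last_prod[abandoned] +
    round(stats::runif(sum(abandoned), 180, 2000))
  status <- ifelse(abandoned, "plugged", ifelse(ended, "idle", "producing"))

  last_prod_rep <- last_prod
  blank <- abandoned & stats::runif(n) < config$missing_date_frac
  last_prod_rep[blank] <- NA
  ab_date[blank] <- NA

  wells <- data.frame(
    well_id = sprintf("SW%04d", seq_len(n)),
    x = x, y = y, status = status,
    spud_date = spud, completion_date = completion,
    first_prod_date = first_prod, last_prod_date = last_prod_rep,
    abandonment_date = ab_date, well_type = "oil_gas",
    stringsAsFactors = FALSE)
  production$well_id <- wells$well_id[production$well_id]
  rownames(production) <- NULL
  list(wells = wells, production = production, clusters = clusters)
}

# Per-cell race shares under the planted disparity gradient.
cell_shares <- function(config, centers, clusters) {
  shares <- matrix(rep(config$base_shares, each = nrow(centers)),
                   nrow = nrow(centers),
                   dimnames = list(NULL, names(config$base_shares)))
  mult <- config$disparity$multiplier
  if (mult != 1 && !is.null(clusters) && nrow(clusters)) {
    d <- apply(clusters, 1, function(cl) {
      sqrt((centers[, 1L] - cl[1L])^2 + (centers[, 2L] - cl[2L])^2)
    })
    dmin <- if (is.matrix(d)) apply(d, 1, min) else d
    m <- 1 + (mult - 1) * exp(-dmin / config$disparity$length_scale)
    shares[, config$disparity$target] <- shares[, config$disparity$target] * m
    shares <- shares / rowSums(shares)
  }
  shares
}

#' Generate the synthetic block-group tessellation and demographics
#'
#' `nx` x `ny` axis-aligned square block groups tiling the landscape, with
#' per-period populations and ACS-like counts for three 5-year periods. The
#' race/ethnicity partition varies with distance to the nearest well cluster
#' per the planted disparity; socioeconomic numerators are binomial draws
#' from their universes (or expectations, in deterministic mode); voter
#' fields are absent in the first period.
#'
#' @param config A [landscape_config()].
#' @param clusters Cluster-centre matrix from [generate_wells()]; required
#'   whenever the disparity multiplier is not 1 (regenerated from the config
#'   seed if omitted).
#' @param periods Study periods (default [canonical_periods()]).
#' @return A [block_groups()] set.
#' @export
generate_blockgroups <- function(config, clusters = NULL,
                                 periods = canonical_periods()) {
  stopifnot(inherits(config, "landscape_config"))
  if (is.null(clusters) && config$disparity$multiplier != 1) {
    clusters <- generate_wells(config)$clusters
  }
  periods <- as_period_list(periods)
  set.seed(config$seed + 7919L)
  sc <- demographic_schema()

  grid <- expand.grid(ix = seq_len(config$nx), iy = seq_len(config$ny))
  geoid <- sprintf("BG%02d%02d", grid$ix, grid$iy)
  centers <- cell_center(config, grid$ix, grid$iy)
  geoms <- lapply(seq_len(nrow(grid)), function(i) {
    rect_geom((grid$ix[i] - 1) * config$cell_m, (grid$iy[i] - 1) * config$cell_m,
              grid$ix[i] * config$cell_m, grid$iy[i] * config$cell_m)
  })
  names(geoms) <- geoid
  county <- ifelse(grid$ix <= config$nx / 2, "West County", "East County")
  shares <- cell_shares(config, centers, clusters)
  det <- config$mode == "deterministic"
  n <- length(geoid)

  base_pop <- if (det) rep(config$pop_mean, n) else
    round(stats::runif(n, config$pop_range[1], config$pop_range[2]))

  demo <- vector("list", length(periods))
  for (pi in seq_along(periods)) {
    pop <- base_pop * config$pop_growth^(pi - 1)
    if (!det) pop <- round(pop)
    if (det) {
      race <- shares * pop
    } else {
      race <- t(vapply(seq_len(n), function(i) {
        as.numeric(stats::rmultinom(1L, pop[i], shares[i, ]))
      }, numeric(ncol(shares))))
      colnames(race) <- colnames(shares)
    }
    d <- data.frame(geoid = geoid, period = periods[[pi]]$label,
                    county = county, total_population = pop,
                    stringsAsFactors = FALSE)
    for (col in sc$race) d[[col]] <- race[, col]
    for (k in seq_along(sc$numerators)) {
      uni_col <- sc$universes[k]; num_col <- sc$numerators[k]
      uni <- config$universe_fracs[[uni_col]] * pop
      if (!det) uni <- round(uni)
      rate <- config$socio_rates[[num_col]]
      num <- if (det) rate * uni else stats::rbinom(n, uni, rate)
      if (num_col == "nonvoters" && pi == 1L) {
        uni <- NA_real_; num <- NA_real_
      }
      d[[num_col]] <- num
      d[[uni_col]] <- uni
    }
    demo[[pi]] <- d
  }
  block_groups(geoms, do.call(rbind, demo))
}

#' Generate synthetic tribal-land polygons
#'
#' Two rectangular land areas in the south-west of the landscape, for
#' exercising the point-in-polygon overlay.
#'
#' @param config A [landscape_config()].
#' @return Named list of geometries.
#' @export
generate_tribal <- function(config) {
  w <- config$cell_m
  list("Tribal Land A" = rect_geom(0.2 * w, 0.2 * w, 1.2 * w, 0.9 * w),
       "Tribal Land B" = rect_geom(1.5 * w, 0.3 * w, 2.1 * w, 1.1 * w))
}

#' Generate a complete synthetic landscape
#'
#' @param config A [landscape_config()].
#' @param periods Study periods (default [canonical_periods()]).
#' @return List: `wells`, `production`, `bgs` (a [block_groups()] set),
#'   `tribal`, `clusters`, `config`, `periods`.
#' @export
generate_landscape <- function(config, periods = canonical_periods()) {
  wp <- generate_wells(config)
  bgs <- generate_blockgroups(config, wp$clusters, periods)
  list(wells = wp$wells, production = wp$production, bgs = bgs,
       tribal = generate_tribal(config), clusters = wp$clusters,
       config = config, periods = as_period_list(periods))
}

#' Closed-form expected state-scope risk ratios (deterministic mode)
#'
#' For a deterministic planted landscape the whole calculation collapses to
#' algebra: each planted cell's exposed fraction is the disc polygon's area
#' over the cell area (the disc fits strictly inside its cell by the
#' `cell_m >= 2 * radius_m` construction, and cells never share a disc), all
#' other fractions are zero, and the per-cell composition follows the
#' configured gradient. The expected risk ratio for group g is then
#' `(sum_i f_i c_gi / sum_i c_gi) / (sum_i f_i P_i / sum_i P_i)`. The value
#' is identical across periods (growth rescales every cell equally).
#' Socioeconomic groups have expectation 1 (no planted socioeconomic
#' gradient). Refuses stochastic configurations, where no closed form exists.
#'
#' @param config A [landscape_config()] with `mode = "deterministic"` and
#'   `planted_cells`.
#' @param radius_m,n_seg Buffer parameters matching the analysis run.
#' @return Named numeric vector of expected risk ratios per group.
#' @export
expected_rr <- function(config, radius_m = 1000, n_seg = 64L) {
  stopifnot(inherits(config, "landscape_config"))
  if (config$mode != "deterministic" || is.null(config$planted_cells)) {
    stop("expected_rr is defined only for deterministic planted landscapes")
  }
  if (2 * radius_m > config$cell_m) {
    stop("closed form requires the disc to fit in one cell (cell_m >= 2 * radius_m)")
  }
  grid <- expand.grid(ix = seq_len(config$nx), iy = seq_len(config$ny))
  centers <- cell_center(config, grid$ix, grid$iy)
  clusters <- cell_center(config, config$planted_cells$ix, config$planted_cells$iy)
  shares <- cell_shares(config, centers, clusters)

  disc_area <- 0.5 * n_seg * radius_m^2 * sin(2 * pi / n_seg)
  f <- numeric(nrow(grid))
  key <- paste(grid$ix, grid$iy)
  f[key %in% paste(config$planted_cells$ix, config$planted_cells$iy)] <-
    disc_area / config$cell_m^2

  pop <- rep(config$pop_mean, nrow(grid))
  race <- shares * pop
  rr_race <- vapply(colnames(race), function(g) {
    (sum(f * race[, g]) / sum(race[, g])) / (sum(f * pop) / sum(pop))
  }, 0)
  sc <- demographic_schema()
  c(total_population = 1, rr_race,
    stats::setNames(rep(1, length(sc$numerators)), sc$numerators))
}
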