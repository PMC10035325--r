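# Shared in-code fixtures: no data files, everything built programmatically.

# A minimal wells table row with absent dates unless supplied.
make_well_row <- function(well_id, x = 0, y = 0, status = "unknown",
                          spud = NA, completion = NA, first_prod = NA,
                          last_prod = NA, abandonment = NA,
                          well_type = "oil_gas") {
  if (!length(well_id)) {
    return(data.frame(well_id = character(), x = numeric(), y = numeric(),
                      status = character(), spud_date = character(),
                      completion_date = character(),
                      first_prod_date = character(),
                      last_prod_date = character(),
                      abandonment_date = character(),
                      well_type = character(), stringsAsFactors = FALSE))
  }
  data.frame(well_id = well_id, x = x, y = y, status = status,
             spud_date = as.character(spud),
             completion_date = as.character(completion),
             first_prod_date = as.character(first_prod),
             last_prod_date = as.character(last_prod),
             abandonment_date = as.character(abandonment),
             well_type = well_type, stringsAsFactors = FALSE)
}

# Random wells table + long production table with coherent ordered dates.
random_wells <- function(n, seed, xmax = 10000, ymax = 10000) {
  set.seed(seed)
  spud_year <- sample(1985:2018, n, replace = TRUE)
  spud <- as.Date(sprintf("%d-01-01", spud_year)) + sample.int(360, n, TRUE)
  completion <- spud + sample.int(500, n, TRUE)
  has_comp <- runif(n) < 0.9
  first_prod <- completion + sample.int(90, n, TRUE)
  lifetime <- sample(1:25, n, replace = TRUE)
  last_prod <- first_prod + lifetime * 365
  has_prod <- runif(n) < 0.85
  abandoned <- has_prod & runif(n) < 0.5
  ab <- last_prod + sample.int(1500, n, TRUE)
  status <- ifelse(abandoned, "plugged",
                   ifelse(has_prod, "idle", "unknown"))
  wells <- data.frame(
    well_id = sprintf("RW%04d", seq_len(n)),
    x = runif(n, 0, xmax), y = runif(n, 0, ymax), status = status,
    spud_date = as.character(spud),
    completion_date = ifelse(has_comp, as.character(completion), ""),
    first_prod_date = ifelse(has_prod, as.character(first_prod), ""),
    last_prod_date = ifelse(has_prod, as.character(last_prod), ""),
    abandonment_date = ifelse(abandoned, as.character(ab), ""),
    well_type = "oil_gas", stringsAsFactors = FALSE)
  prod <- do.call(rbind, lapply(which(has_prod), function(i) {
    yrs <- (spud_year[i] + 1):min(spud_year[i] + lifetime[i], 2019)
    if (!length(yrs)) return(NULL)
    data.frame(well_id = wells$well_id[i], year = yrs,
               boe = round(rlnorm(length(yrs), 7, 1.5), 1))
  }))
  if (is.null(prod)) prod <- data.frame(well_id = character(),
                                        year = integer(), boe = numeric())
  list(wells = wells, production = prod)
}

# A small block-group set: k x 1 strip of unit cells of side `cell` metres,
# deterministic demographics supplied per cell as a share of the target group.
strip_bgs <- function(pops, black_shares, cell = 2000, period = "2005-2009") {
  k <- length(pops)
  geoms <- lapply(seq_len(k), function(i) {
    rect_geom((i - 1) * cell, 0, i * cell, cell)
  })
  names(geoms) <- sprintf("S%02d", seq_len(k))
  white <- 1 - black_shares
  demo <- data.frame(geoid = names(geoms), period = period,
                     county = "Test County",
                     total_population = pops,
                     hispanic_latinx = 0, nh_aian = 0, nh_asian = 0,
                     nh_black = pops * black_shares,
                     nh_white = pops * white, nh_other = 0,
                     nh_two_or_more = 0,
                     poverty_num = 0.1 * pops, poverty_universe = pops,
                     lt12_edu_num = 0.2 * 0.7 * pops, edu_universe = 0.7 * pops,
                     renter_households = 0.4 * 0.35 * pops,
                     total_households = 0.35 * pops,
                     ling_isolated_adults = 0.2 * 0.75 * pops,
                     total_adults = 0.75 * pops,
                     nonvoters = 0.3 * 0.6 * pops,
                     eligible_voters = 0.6 * pops,
                     stringsAsFactors = FALSE)
  block_groups(geoms, demo)
}

canonical3 <- canonical_periods()

# Monte-Carlo areal-fraction oracle: jittered-stratified point sample over
# the geometry's bbox (one uniform point per grid cell — unbiased, with true
# error well below the binomial bound), rejected into the polygon by ray
# casting, then tested against the buffer discs by ray casting. Returns the
# point estimate and its binomial SE, the conservative error scale.
mc_areal_fraction <- function(geom, region, n = 200000, seed = 1) {
  set.seed(seed)
  bb <- wellprox:::geom_bbox(geom)
  w <- bb[3] - bb[1]; h <- bb[4] - bb[2]
  nx <- max(1L, round(sqrt(n * w / h)))
  ny <- max(1L, ceiling(n / nx))
  n <- nx * ny
  gx <- (rep(seq_len(nx), times = ny) - 1) / nx
  gy <- (rep(seq_len(ny), each = nx) - 1) / ny
  px <- bb[1] + (gx + runif(n) / nx) * w
  py <- bb[2] + (gy + runif(n) / ny) * h
  inside <- points_in_geom(px, py, geom, boundary = FALSE)
  px <- px[inside]; py <- py[inside]
  hit <- rep(FALSE, length(px))
  for (ring in region$rings) {
    todo <- !hit
    if (!any(todo)) break
    hit[todo] <- points_in_geom(px[todo], py[todo], ring, boundary = FALSE)
  }
  p <- mean(hit)
  list(p = p, se = sqrt(p * (1 - p) / length(px)))
}
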