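test_that("buffer areas behave as unions of discs", {
  wells <- rbind(make_well_row("A", x = 0, y = 0),
                 make_well_row("B", x = 5000, y = 0))
  asn <- data.frame(well_id = c("A", "B"), period = "2005-2009",
                    new = TRUE, active = FALSE, retired = FALSE,
                    plugged = FALSE, retirement_source = NA, cum_boe = 0)
  buf <- stage_buffer(wells, asn, "new", "2005-2009", radius_m = 1000)
  expect_equal(region_area(buf), 2 * pi * 1e6, tolerance = 0.005)

  # coincident wells: union, not sum
  wells2 <- rbind(make_well_row("A", x = 0, y = 0),
                  make_well_row("B", x = 0, y = 0))
  buf2 <- stage_buffer(wells2, asn, "new", "2005-2009", radius_m = 1000)
  expect_equal(region_area(buf2), pi * 1e6, tolerance = 0.005)

  # empty stage: empty region
  buf0 <- stage_buffer(wells, asn, "retired", "2005-2009")
  expect_equal(region_area(buf0), 0)
})

test_that("the 64-gon disc area matches its closed form", {
  ring <- circle_ring(10, -3, 1000, 64)
  expect_equal(geom_area(polygon_geom(ring)),
               0.5 * 64 * 1000^2 * sin(2 * pi / 64), tolerance = 1e-12)
})

test_that("areal fractions handle exact, disjoint, and nested cases", {
  sq <- rect_geom(0, 0, 1, 1)
  half_plane <- cbind(c(-10, 0.5, 0.5, -10), c(-10, -10, 10, 10))
  expect_equal(areal_fraction(sq, half_plane), 0.5)

  far <- cbind(c(5, 6, 6, 5), c(5, 5, 6, 6))
  expect_equal(areal_fraction(sq, far), 0)

  cover <- cbind(c(-1, 2, 2, -1), c(-1, -1, 2, 2))
  expect_equal(areal_fraction(sq, cover), 1)

  expect_error(areal_fraction(rect_geom(0, 0, 0, 1), half_plane), "zero-area")
})

test_that("union area of random discs matches Monte-Carlo sampling", {
  set.seed(5)
  wells <- do.call(rbind, lapply(1:10, function(i) {
    make_well_row(sprintf("W%d", i), x = runif(1, 0, 4000),
                  y = runif(1, 0, 4000))
  }))
  asn <- data.frame(well_id = wells$well_id, period = "2005-2009",
                    new = TRUE, active = FALSE, retired = FALSE,
                    plugged = FALSE, retirement_source = NA, cum_boe = 0)
  buf <- stage_buffer(wells, asn, "new", "2005-2009", radius_m = 1000)
  bbox_geom <- rect_geom(-1000, -1000, 5000, 5000)
  mc <- mc_areal_fraction(bbox_geom, buf, n = 200000, seed = 9)
  frac <- areal_fraction(bbox_geom, buf)
  expect_lt(abs(frac - mc$p), 3 * mc$se)
})

test_that("apportionment reproduces the worked proportional-allocation example", {
  counts <- c(total_population = 1000, hispanic_latinx = 500, nh_black = 100)
  exposed <- apportion(counts, 0.30)
  expect_equal(exposed[["total_population"]], 300)
  expect_equal(exposed[["hispanic_latinx"]], 150)
  expect_equal(apportion(counts, 0), counts * 0)
  expect_error(apportion(counts, 1.2))
})

test_that("centroid intensity counts wells within the radius, boundary inclusive", {
  sq <- rect_geom(-300, -300, 300, 300)      # centroid at the origin
  wells <- rbind(make_well_row("IN", x = 500, y = 0),
                 make_well_row("OUT", x = 1500, y = 0),
                 make_well_row("EDGE", x = 1000, y = 0))
  asn <- data.frame(well_id = wells$well_id, period = "2005-2009",
                    new = FALSE, active = TRUE, retired = FALSE,
                    plugged = FALSE, retirement_source = NA,
                    cum_boe = c(10, 20, 40))
  ci <- centroid_intensity(sq, wells, asn, "2005-2009", radius_m = 1000)
  expect_equal(ci$counts[["active"]], 2L)     # 500 m and the boundary well
  expect_equal(ci$active_boe, 50)
  # empty assignment
  ci0 <- centroid_intensity(sq, wells[0, ], asn[0, ], "2005-2009")
  expect_equal(unname(ci0$counts), rep(0L, 4))
  expect_equal(ci0$active_boe, 0)
})

test_that("centroid counts agree with a brute-force distance scan on 50 wells", {
  set.seed(21)
  n <- 50
  wells <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_well_row(sprintf("W%02d", i), x = runif(1, -2000, 2000),
                  y = runif(1, -2000, 2000))
  }))
  stages <- matrix(runif(3 * n) < 0.4, ncol = 3)
  asn <- data.frame(well_id = wells$well_id, period = "P",
                    new = stages[, 1], active = stages[, 2],
                    retired = stages[, 3], plugged = FALSE,
                    retirement_source = NA, cum_boe = round(runif(n, 0, 100)))
  geom <- rect_geom(-400, -250, 400, 250)
  ci <- centroid_intensity(geom, wells, asn, "P", radius_m = 1000)
  ctr <- c(0, 0)
  for (s in c("new", "active", "retired")) {
    manual <- 0L
    for (i in seq_len(n)) {
      d <- sqrt((wells$x[i] - ctr[1])^2 + (wells$y[i] - ctr[2])^2)
      if (d <= 1000 && asn[[s]][i]) manual <- manual + 1L
    }
    expect_equal(ci$counts[[s]], manual)
  }
})

test_that("centroid and point-in-polygon handle holes and multiparts", {
  donut <- polygon_geom(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)),
                        list(cbind(c(1, 3, 3, 1), c(1, 1, 3, 3))))
  expect_equal(geom_area(donut), 12)
  expect_equal(geom_centroid(donut), c(2, 2))
  expect_true(points_in_geom(0.5, 0.5, donut))
  expect_false(points_in_geom(2, 2, donut))       # inside the hole
  expect_true(points_in_geom(1, 1, donut))        # hole boundary is boundary

  two <- multipolygon_geom(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                                cbind(c(10, 12, 12, 10), c(0, 0, 1, 1))))
  expect_equal(geom_area(two), 3)
  expect_equal(areal_fraction(two, cbind(c(-1, 2, 2, -1), c(-1, -1, 2, 2))),
               1 / 3)
})

test_that("self-intersecting rings are detected and measured even-odd", {
  # hourglass over [0,2]^2: two triangles (base 2, height 1), area 1 each
  bowtie <- cbind(c(0, 2, 0, 2), c(0, 0, 2, 2))
  expect_false(wellprox:::ring_self_intersects(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  expect_true(wellprox:::ring_self_intersects(bowtie))
  expect_equal(geom_area_eo(polygon_geom(bowtie)), 2)
})
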