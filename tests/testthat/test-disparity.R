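test_that("risk_ratio implements the exposed-proportion ratio", {
  expect_equal(round(risk_ratio(100941, 2172247, 1169930, 36308527), 2), 1.44)
  expect_equal(risk_ratio(50, 1000, 500, 10000), 1)
  expect_equal(risk_ratio(0, 1000, 500, 10000), 0)
  expect_true(is.na(risk_ratio(0, 0, 500, 10000)))
  expect_true(is.na(risk_ratio(10, 100, 0, 10000)))
  expect_error(risk_ratio(-1, 10, 5, 100), "negative")
  expect_error(risk_ratio(20, 10, 5, 100), "exceeds")
  # scale invariance
  expect_equal(risk_ratio(3, 30, 40, 400), risk_ratio(300, 3000, 4000, 40000))
})

two_bg_exposure <- function(bgs, fractions, period = "2005-2009") {
  sc <- demographic_schema()
  demo <- bgs$demo[bgs$demo$period == period, ]
  rows <- lapply(seq_len(nrow(demo)), function(i) {
    row <- data.frame(geoid = demo$geoid[i], period = period, stage = "active",
                      exposed_fraction = fractions[i],
                      stringsAsFactors = FALSE)
    for (col in sc$all_counts) {
      row[[paste0("exposed_", col)]] <- fractions[i] * demo[[col]][i]
    }
    row$centroid_well_count <- as.integer(fractions[i] > 0)
    row$centroid_boe <- 1000 * fractions[i]
    row
  })
  do.call(rbind, rows)
}

test_that("rr_table matches a hand-worked two-block-group computation", {
  # group A concentrated in the exposed block group
  bgs <- strip_bgs(pops = c(1000, 1000), black_shares = c(0.6, 0.2))
  ex <- two_bg_exposure(bgs, fractions = c(1, 0))
  rr <- rr_table(ex, bgs, scope = "state")
  # hand algebra: (600/800) / (1000/2000) = 1.5
  expect_equal(rr$rr[rr$group == "nh_black"], 1.5)
  expect_equal(rr$rr[rr$group == "total_population"], 1)
  expect_equal(rr$rr[rr$group == "nh_white"], (400 / 1200) / 0.5)
  # socioeconomic groups are flat across cells here, so RR = 1
  expect_equal(rr$rr[rr$group == "renter_households"], 1)
})

test_that("single-block-group scope forces every risk ratio to 1", {
  bgs <- strip_bgs(pops = 1000, black_shares = 0.37)
  ex <- two_bg_exposure(bgs, fractions = 0.4)
  rr <- rr_table(ex, bgs, scope = "state")
  # groups with zero members are legitimately undefined (NA), never dropped
  expect_true(all(is.na(rr$rr) == (rr$group_total == 0)))
  expect_true(all(abs(rr$rr[!is.na(rr$rr)] - 1) < 1e-12))
})

test_that("mixture identity: population-share-weighted RRs average to 1", {
  set.seed(14)
  k <- 6
  bgs <- strip_bgs(pops = round(runif(k, 500, 3000)),
                   black_shares = runif(k, 0.05, 0.6))
  ex <- two_bg_exposure(bgs, fractions = runif(k))
  rr <- rr_table(ex, bgs, scope = "state")
  sc <- demographic_schema()
  rrr <- rr[rr$group %in% sc$race & !is.na(rr$rr), ]  # zero-count groups weigh 0
  mix <- sum(rrr$group_total / rrr$pop_total * rrr$rr)
  expect_equal(mix, 1, tolerance = 1e-9)
})

test_that("county scope compares against county composition", {
  bgs <- strip_bgs(pops = c(1000, 1000), black_shares = c(0.6, 0.2))
  bgs$demo$county <- rep(c("Alpha", "Beta"), length.out = nrow(bgs$demo))
  ex <- two_bg_exposure(bgs, fractions = c(0.5, 0))
  rr_alpha <- rr_table(ex, bgs, scope = "county:Alpha")
  # within Alpha only its own block group counts: every defined RR is 1
  expect_true(all(abs(rr_alpha$rr[!is.na(rr_alpha$rr)] - 1) < 1e-12))
  expect_error(rr_table(ex, bgs, scope = "planet"), "unknown scope")
})

test_that("nonvoter group is skipped when turnout data are absent", {
  bgs <- strip_bgs(pops = c(800, 1200), black_shares = c(0.3, 0.3))
  bgs$demo$nonvoters <- NA_real_
  bgs$demo$eligible_voters <- NA_real_
  ex <- two_bg_exposure(bgs, fractions = c(1, 0))
  rr <- rr_table(ex, bgs, scope = "state")
  expect_false("nonvoters" %in% rr$group)
})

test_that("quintile assignment is rank-based with the lowest-rank tie rule", {
  v <- setNames(1:10, sprintf("G%02d", 1:10))
  expect_equal(unname(quintile_assign(v)), rep(1:5, each = 2))
  ties <- setNames(rep(7, 8), sprintf("T%d", 1:8))
  expect_equal(unname(quintile_assign(ties)), rep(1L, 8))
  expect_length(quintile_assign(setNames(numeric(), character())), 0)
  expect_error(quintile_assign(c(a = 0)), "positive")

  # independent sort-then-slice oracle on ties-heavy lognormal draws
  set.seed(33)
  vals <- setNames(round(rlnorm(100, 5, 1), -2), sprintf("L%03d", 1:100))
  vals[vals <= 0] <- 100
  got <- quintile_assign(vals)
  ord <- order(vals)
  oracle <- integer(100)
  pos_q <- floor(5 * (seq_len(100) - 1) / 100) + 1L
  oracle[ord] <- pos_q
  for (u in unique(vals)) oracle[vals == u] <- min(oracle[vals == u])
  expect_equal(unname(got), oracle)
})

test_that("quintile risk ratios are 1 for the whole population and detect enrichment", {
  k <- 10
  shares <- seq(0.1, 0.55, length.out = k)   # enrichment grows with intensity
  bgs <- strip_bgs(pops = rep(1000, k), black_shares = shares)
  ex <- two_bg_exposure(bgs, fractions = rep(1, k))
  ex$centroid_boe <- seq(100, 1000, length.out = k)   # intensity order = share order
  rrq <- rr_by_quintile(ex, bgs, "2005-2009")
  tp <- rrq[rrq$group == "total_population", ]
  expect_equal(tp$rr, rep(1, 5))
  bl <- rrq[rrq$group == "nh_black", ]
  expect_true(all(diff(bl$rr) > 0))           # monotone by construction

  # an empty quintile yields NA records, not silent drops
  bgs2 <- strip_bgs(pops = rep(1000, 3), black_shares = rep(0.2, 3))
  ex2 <- two_bg_exposure(bgs2, fractions = rep(1, 3))
  ex2$centroid_boe <- c(10, 20, 30)
  rrq2 <- rr_by_quintile(ex2, bgs2, "2005-2009")
  expect_equal(nrow(rrq2[rrq2$group == "nh_black", ]), 5)
  expect_true(any(is.na(rrq2$rr)))
})

test_that("panel change categorises by sign and sums later-period counts", {
  k <- 6
  bgs <- strip_bgs(pops = rep(1000, k), black_shares = rep(0.25, k),
                   period = "2010-2014")
  demo3 <- bgs$demo; demo3$period <- "2015-2019"
  demo3$total_population <- demo3$total_population + 100
  demo3$nh_white <- demo3$nh_white + 100
  bgs2 <- block_groups(bgs$geoms, rbind(bgs$demo, demo3))

  exa <- two_bg_exposure(bgs2, fractions = rep(1, k), period = "2010-2014")
  exb <- two_bg_exposure(bgs2, fractions = rep(1, k), period = "2015-2019")
  exa$stage <- "new"; exb$stage <- "new"
  exa$centroid_well_count <- c(3, 5, 5, 9, 0, 2)
  exb$centroid_well_count <- c(5, 5, 2, 9, 1, 0)
  pc <- panel_change(exa, exb, bgs2, "2010-2014", "2015-2019",
                     "new_well_count")
  expect_equal(pc$n_block_groups[pc$category == "increase"], 2)
  expect_equal(pc$n_block_groups[pc$category == "decrease"], 2)
  expect_equal(pc$n_block_groups[pc$category == "no_change"], 2)
  # sums use the later period and partition the pooled population
  expect_equal(sum(pc$total_population), sum(demo3$total_population))
  expect_equal(pc$total_population[pc$category == "increase"], 2 * 1100)

  # elementwise loop oracle on a randomised panel
  set.seed(4)
  exa$centroid_well_count <- sample(0:4, k, replace = TRUE)
  exb$centroid_well_count <- sample(0:4, k, replace = TRUE)
  pc2 <- panel_change(exa, exb, bgs2, "2010-2014", "2015-2019",
                      "new_well_count")
  man <- c(increase = 0, decrease = 0, no_change = 0)
  for (i in seq_len(k)) {
    d <- exb$centroid_well_count[i] - exa$centroid_well_count[i]
    cat_i <- if (d > 0) "increase" else if (d < 0) "decrease" else "no_change"
    man[cat_i] <- man[cat_i] + demo3$total_population[i]
  }
  expect_equal(setNames(pc2$total_population, pc2$category), man)

  # geoid mismatch is fatal
  expect_error(panel_change(exa[-1, ], exb, bgs2, "2010-2014", "2015-2019",
                            "new_well_count"), "different block-group sets")
})

test_that("tribal overlay counts match an exhaustive containment scan", {
  set.seed(12)
  n <- 100
  wells <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_well_row(sprintf("W%03d", i), x = runif(1, 0, 5000),
                  y = runif(1, 0, 5000))
  }))
  polys <- list(A = rect_geom(0, 0, 1500, 1500),
                B = rect_geom(1000, 1000, 2500, 4000),
                C = rect_geom(4000, 4000, 5000, 5000),
                D = polygon_geom(cbind(c(2600, 3800, 3200), c(200, 200, 1400))),
                E = rect_geom(-2000, -2000, -1000, -1000))
  ov <- tribal_overlay(wells, polys)
  for (nm in names(polys)) {
    manual <- sum(vapply(seq_len(n), function(i) {
      points_in_geom(wells$x[i], wells$y[i], polys[[nm]])
    }, TRUE))
    expect_equal(ov$n_wells[ov$land == nm], manual)
  }
  expect_equal(ov$n_wells[ov$land == "E"], 0)

  inside_one <- make_well_row("IN", x = 4500, y = 4500)
  ov2 <- tribal_overlay(inside_one, polys)
  expect_equal(ov2$n_wells, c(0L, 0L, 1L, 0L, 0L))
})

test_that("trend arithmetic rounds shares and changes as reported", {
  expect_equal(pct_share(13102161, 36308527), 36.1)
  expect_equal(pct_change(36308527, 39283497), 8.2)
  expect_equal(pct_change(5, 5), 0)
  expect_true(is.na(pct_change(0, 5)))
  expect_true(is.na(pct_share(1, 0)))

  df <- data.frame(period = c("2005-2009", "2010-2014", "2015-2019"),
                   value = c(1169930, 1150382, 1109293),
                   universe = c(36308527, 38066920, 39283497))
  tr <- summarize_trends(df)
  expect_equal(tr$share, c(3.2, 3.0, 2.8))
  expect_equal(tr$change[-1], c(-1.7, -3.6))
  expect_equal(attr(tr, "averages")$mean_share, 3.0)
})
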