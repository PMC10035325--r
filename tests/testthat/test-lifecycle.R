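p1 <- canonical3[["2005-2009"]]
p2 <- canonical3[["2010-2014"]]
p3 <- canonical3[["2015-2019"]]

test_that("cumulative production sums the period window, with an independent oracle", {
  w <- well_record("W", 0, 0, annual_boe = c("2005" = 100, "2006" = 50, "2011" = 10))
  expect_equal(cumulative_boe(w, p1), 150)
  expect_equal(cumulative_boe(w, p2), 10)
  expect_equal(cumulative_boe(well_record("E", 0, 0), p1), 0)

  set.seed(11)
  yrs <- sample(1990:2020, 30, replace = FALSE)
  vols <- round(runif(30, 0, 5000), 2)
  w2 <- well_record("R", 0, 0, annual_boe = setNames(vols, yrs))
  oracle <- 0
  for (y in 2010:2014) {                  # loop-and-add oracle
    i <- which(yrs == y)
    if (length(i)) oracle <- oracle + vols[i]
  }
  expect_equal(cumulative_boe(w2, p2), oracle)
})

test_that("new-well classification follows the preproduction interval", {
  w <- well_record("A", 0, 0, spud_date = "2005-03-01",
                   completion_date = "2006-02-01")
  expect_true(is_new(w, p1))
  expect_false(is_new(w, p2))
  expect_false(is_new(well_record("B", 0, 0, spud_date = "1998-01-01",
                                  completion_date = "1999-01-01"), p1))
  # open-ended on the right when completion is missing
  w_open <- well_record("C", 0, 0, spud_date = "2009-12-15")
  expect_true(is_new(w_open, p2))
  expect_true(is_new(w_open, p3))
  expect_false(is_new(w_open, study_period("pre", 2000, 2004)))
  # missing spud with completion: new only in the completion year
  w_pt <- well_record("D", 0, 0, completion_date = "2012-05-01")
  expect_true(is_new(w_pt, p2))
  expect_false(is_new(w_pt, p3))
  # no dates at all: never new
  expect_false(is_new(well_record("E", 0, 0), p1))
})

test_that("activity requires strictly positive cumulative production", {
  expect_true(is_active(well_record("A", 0, 0, annual_boe = c("2006" = 5)), p1))
  expect_false(is_active(well_record("B", 0, 0, annual_boe = c("2006" = 0)), p1))
  # dual membership: spudded and producing within the same window
  w <- well_record("C", 0, 0, spud_date = "2005-03-01",
                   completion_date = "2005-11-01",
                   annual_boe = c("2006" = 120))
  expect_true(is_new(w, p1))
  expect_true(is_active(w, p1))
})

test_that("postproduction start uses abandonment or the 8-year idle rule", {
  w_ab <- well_record("A", 0, 0, abandonment_date = "2012-06-01")
  expect_equal(postproduction_start(w_ab), as.Date("2012-06-01"))
  w_idle <- well_record("B", 0, 0, last_prod_date = "2000-07-15")
  expect_equal(postproduction_start(w_idle), as.Date("2008-07-15"))
  expect_true(is.na(postproduction_start(well_record("C", 0, 0))))
  # calendar-exact shift; Feb 29 maps to Mar 1 in non-leap targets
  expect_equal(shift_years(as.Date("2004-02-29"), 8), as.Date("2012-02-29"))
  expect_equal(shift_years(as.Date("2004-02-29"), 7), as.Date("2011-03-01"))
})

test_that("retirement means entering postproduction within the window", {
  w_idle <- well_record("A", 0, 0, last_prod_date = "2000-07-15")
  expect_true(is_retired(w_idle, p1))          # 2008 in [2005, 2009]
  expect_false(is_retired(w_idle, p2))
  w_old <- well_record("B", 0, 0, abandonment_date = "1990-01-01")
  expect_false(is_retired(w_old, p1))
  w_ab <- well_record("C", 0, 0, abandonment_date = "2013-05-01")
  expect_true(is_retired(w_ab, p2))
  expect_false(is_retired(w_ab, p3))
})

test_that("plugged cross-section includes dateless and pre-study wells", {
  expect_true(is_plugged(well_record("A", 0, 0, status = "plugged",
                                     abandonment_date = "1987-02-01"), 2019))
  expect_true(is_plugged(well_record("B", 0, 0, status = "plugged"), 2019))
  expect_false(is_plugged(well_record("C", 0, 0, status = "producing"), 2019))
  # abandonment after the reference year excludes from the cross-section
  expect_false(is_plugged(well_record("D", 0, 0, status = "plugged",
                                      abandonment_date = "2021-03-01"), 2019))
})

test_that("assign_stages equals per-well predicate evaluation on 200 random wells", {
  rw <- random_wells(200, seed = 31)
  asn <- assign_stages(rw$wells, rw$production, canonical3)
  recs <- well_records(rw$wells, rw$production)
  for (p in canonical3) {
    sub <- asn[asn$period == p$label, ]
    sub <- sub[match(names(recs), sub$well_id), ]
    expect_equal(sub$new, vapply(recs, is_new, TRUE, period = p),
                 ignore_attr = TRUE)
    expect_equal(sub$active, vapply(recs, is_active, TRUE, period = p),
                 ignore_attr = TRUE)
    expect_equal(sub$retired, vapply(recs, is_retired, TRUE, period = p),
                 ignore_attr = TRUE)
    expect_equal(sub$plugged,
                 vapply(recs, is_plugged, TRUE, reference_year = 2019),
                 ignore_attr = TRUE)
    expect_equal(sub$cum_boe, vapply(recs, cumulative_boe, 0, period = p),
                 ignore_attr = TRUE)
    # definitional consistency across code paths
    expect_equal(sub$active, sub$cum_boe > 0, ignore_attr = TRUE)
  }
})

test_that("dual-membership well is both new and active in its period", {
  wells <- make_well_row("DU", spud = "2005-02-01", completion = "2005-12-01",
                         first_prod = "2006-01-15", status = "producing")
  prod <- data.frame(well_id = "DU", year = 2006L, boe = 500)
  asn <- assign_stages(wells, prod, canonical3)
  row <- asn[asn$period == "2005-2009", ]
  expect_true(row$new)
  expect_true(row$active)
})

test_that("retirement source distinguishes abandonment from long-term idle", {
  wells <- rbind(
    make_well_row("AB", last_prod = "2010-01-01", abandonment = "2011-06-01",
                  status = "plugged"),
    make_well_row("ID", last_prod = "2004-03-01", status = "idle"),
    make_well_row("NO"))
  asn <- assign_stages(wells, NULL, canonical3)
  first <- asn[asn$period == "2005-2009", ]
  expect_equal(first$retirement_source[match(c("AB", "ID", "NO"), first$well_id)],
               c("abandonment", "idle", NA))
  # last production 2004-03-01 + 8y = 2012-03-01 falls in 2010-2014
  expect_false(first$retired[first$well_id == "ID"])
  second <- asn[asn$period == "2010-2014", ]
  expect_true(second$retired[second$well_id == "ID"])
})

test_that("wells wholly before 1997 never enter any canonical period", {
  wells <- make_well_row("OLD", spud = "1980-05-01", completion = "1981-02-01",
                         first_prod = "1981-06-01", last_prod = "1996-12-01",
                         abandonment = "1996-12-20", status = "plugged")
  prod <- data.frame(well_id = "OLD", year = 1981:1996, boe = 100)
  asn <- assign_stages(wells, prod, canonical3)
  expect_false(any(asn$new | asn$active | asn$retired))
  expect_true(all(asn$plugged))    # the plugged cross-section still sees it
})

test_that("stage membership is equivariant under shifting all dates by k years", {
  rw <- random_wells(40, seed = 77)
  k <- 5L
  shift_chr <- function(s) {
    d <- parse_well_date(s)
    ifelse(is.na(d), "", as.character(shift_years(d, k)))
  }
  wells_s <- rw$wells
  for (col in c("spud_date", "completion_date", "first_prod_date",
                "last_prod_date", "abandonment_date")) {
    wells_s[[col]] <- shift_chr(rw$wells[[col]])
  }
  prod_s <- rw$production
  prod_s$year <- prod_s$year + k
  periods_s <- lapply(canonical3, function(p) {
    study_period(p$label, p$start_year + k, p$end_year + k)
  })
  a0 <- assign_stages(rw$wells, rw$production, canonical3)
  a1 <- assign_stages(wells_s, prod_s, periods_s)
  expect_equal(a1$new, a0$new)
  expect_equal(a1$active, a0$active)
  expect_equal(a1$retired, a0$retired)
})

test_that("duplicate well ids are fatal and empty input gives empty output", {
  wells <- rbind(make_well_row("X"), make_well_row("X"))
  expect_error(assign_stages(wells, NULL, canonical3), "duplicate well_id")
  empty <- assign_stages(make_well_row(character(0)), NULL, canonical3)
  expect_equal(nrow(empty), 0)
})

test_that("date parsing accepts year-only values and flags garbage", {
  expect_equal(parse_well_date("2005"), as.Date("2005-07-01"))
  expect_equal(parse_well_date(c("", NA, "2010-02-03")),
               as.Date(c(NA, NA, "2010-02-03")))
  expect_error(parse_well_date("not-a-date"), "unparseable")
})

test_that("negative production is clamped with a warning", {
  expect_warning(out <- validate_production(
    data.frame(well_id = "A", year = 2010L, boe = -5)), "clamped")
  expect_equal(out$boe, 0)
})
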