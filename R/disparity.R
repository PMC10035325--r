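# Group risk ratios, exposure-intensity quintiles, panel change, tribal
# overlay, and trend arithmetic.

#' Group risk ratio
#'
#' `RR = (group_exposed / group_total) / (pop_exposed / pop_total)`: the ratio
#' of the proportion of a demographic group that is exposed to the proportion
#' of the comparison population that is exposed. `RR > 1` means the group is
#' over-represented among the exposed. Undefined ratios (any zero
#' denominator) are returned as `NA`, never as 0 — silent drops would bias
#' group comparisons.
#'
#' @param group_exposed,group_total Exposed members and total size of the
#'   group.
#' @param pop_exposed,pop_total Exposed members and total size of the
#'   comparison population.
#' @return Non-negative real (vectorised), `NA` where undefined.
#' @examples
#' risk_ratio(100941, 2172247, 1169930, 36308527)  # 1.4421...
#' @export
risk_ratio <- function(group_exposed, group_total, pop_exposed, pop_total) {
  args <- cbind(group_exposed, group_total, pop_exposed, pop_total)
  if (any(args < 0, na.rm = TRUE)) stop("risk_ratio: negative input")
  if (any(group_exposed > group_total, na.rm = TRUE)) {
    stop("risk_ratio: group_exposed exceeds group_total")
  }
  if (any(pop_exposed > pop_total, na.rm = TRUE)) {
    stop("risk_ratio: pop_exposed exceeds pop_total")
  }
  undef <- is.na(group_total) | is.na(pop_exposed) | is.na(pop_total) |
    group_total == 0 | pop_exposed == 0 | pop_total == 0
  out <- (group_exposed / group_total) / (pop_exposed / pop_total)
  out[undef] <- NA_real_
  out
}

scope_filter <- function(demo, scope) {
  if (identical(scope, "state")) return(rep(TRUE, nrow(demo)))
  if (grepl("^county:", scope)) {
    county <- sub("^county:", "", scope)
    if (all(is.na(demo$county))) stop("scope '", scope, "' but demographics carry no county")
    return(!is.na(demo$county) & demo$county == county)
  }
  stop("unknown scope: ", scope)
}

#' Risk-ratio table at a given scope
#'
#' For each demographic group, stage, and period, sums apportioned exposed
#' counts and totals over the in-scope block-group-periods and forms the risk
#' ratio. `scope = "state"` uses all block groups; `scope = "county:<name>"`
#' restricts both numerators and denominators to that county's block groups,
#' i.e. compares against the county-level composition. Socioeconomic groups
#' are compared against their own universes (renters against all households,
#' and so on); the non-voter group is skipped for periods where turnout data
#' are absent.
#'
#' @param exposure Output of [assess_exposure()].
#' @param bgs The [block_groups()] set.
#' @param scope `"state"` or `"county:<name>"`.
#' @param stages Stages to report (default all present in `exposure`).
#' @param periods Period labels to report (default all present).
#' @return Data frame of risk-ratio records: `group`, `stage`, `period`,
#'   `scope`, `group_exposed`, `group_total`, `pop_exposed`, `pop_total`,
#'   `rr` (`NA` where undefined).
#' @export
rr_table <- function(exposure, bgs, scope = "state", stages = NULL,
                     periods = NULL) {
  stopifnot(inherits(bgs, "bg_set"))
  if (is.null(stages)) stages <- unique(exposure$stage)
  if (is.null(periods)) periods <- unique(exposure$period)
  groups <- demographic_groups()

  out <- vector("list", 0L)
  for (p in periods) {
    demo <- bg_demo_period(bgs, p)
    demo <- demo[scope_filter(demo, scope), , drop = FALSE]
    for (s in stages) {
      ex <- exposure[exposure$period == p & exposure$stage == s, , drop = FALSE]
      ex <- ex[ex$geoid %in% demo$geoid, , drop = FALSE]
      if (!nrow(ex) && !nrow(demo)) next
      for (k in seq_len(nrow(groups))) {
        num <- groups$numerator[k]; uni <- groups$universe[k]
        g_tot <- sum(demo[[num]])
        p_tot <- sum(demo[[uni]])
        if ((is.na(g_tot) || is.na(p_tot)) && num == "nonvoters") next
        g_exp <- sum(ex[[paste0("exposed_", num)]])
        p_exp <- sum(ex[[paste0("exposed_", uni)]])
        out[[length(out) + 1L]] <- data.frame(
          group = groups$group[k], stage = s, period = p, scope = scope,
          group_exposed = g_exp, group_total = g_tot,
          pop_exposed = p_exp, pop_total = p_tot,
          rr = risk_ratio(g_exp, g_tot, p_exp, p_tot),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Equal-frequency quintile assignment
#'
#' Rank-based quintiles (1 = least, 5 = most) over strictly positive
#' intensity values. Ties share the quintile of their smallest rank (a
#' deterministic tie rule: all-equal inputs all land in quintile 1).
#'
#' @param values Named numeric vector (names are geoids), all `> 0`.
#' @return Named integer vector of quintiles; empty input gives an empty
#'   vector.
#' @export
quintile_assign <- function(values) {
  if (!length(values)) return(stats::setNames(integer(), character()))
  if (any(is.na(values) | values <= 0)) {
    stop("quintile_assign: values must be positive (only exposed block groups enter)")
  }
  r <- rank(values, ties.method = "min")
  q <- as.integer(floor(5 * (r - 1) / length(values)) + 1L)
  stats::setNames(q, names(values))
}

#' Risk ratios stratified by production-intensity quintile
#'
#' Among block groups with positive centroid-radius production volume for the
#' active stage, assigns intensity quintiles per period and computes, for each
#' group and quintile, the ratio of the group's exposed share to the total
#' population's exposed share. Numerators (exposed counts) are restricted to
#' the quintile; group and population totals are the statewide totals, so the
#' `total_population` self-group has RR 1 in every non-empty quintile. Empty
#' quintiles are emitted with `NA` ratios rather than dropped.
#'
#' @param exposure Output of [assess_exposure()].
#' @param bgs The [block_groups()] set.
#' @param period Period label.
#' @param stage Stage providing the intensity metric (default `"active"`,
#'   using `centroid_boe`).
#' @return Data frame of risk-ratio records with `scope = "quintile:<q>"`.
#' @export
rr_by_quintile <- function(exposure, bgs, period, stage = "active") {
  stopifnot(inherits(bgs, "bg_set"))
  ex <- exposure[exposure$period == period & exposure$stage == stage, , drop = FALSE]
  vals <- stats::setNames(ex$centroid_boe, ex$geoid)
  vals <- vals[vals > 0]
  q <- quintile_assign(vals)
  demo <- bg_demo_period(bgs, period)
  groups <- demographic_groups()

  out <- vector("list", 0L)
  for (qq in 1:5) {
    in_q <- ex$geoid %in% names(q)[q == qq]
    for (k in seq_len(nrow(groups))) {
      num <- groups$numerator[k]; uni <- groups$universe[k]
      g_tot <- sum(demo[[num]])
      p_tot <- sum(demo[[uni]])
      if ((is.na(g_tot) || is.na(p_tot)) && num == "nonvoters") next
      g_exp <- sum(ex[[paste0("exposed_", num)]][in_q])
      p_exp <- sum(ex[[paste0("exposed_", uni)]][in_q])
      out[[length(out) + 1L]] <- data.frame(
        group = groups$group[k], stage = stage, period = period,
        scope = paste0("quintile:", qq),
        group_exposed = g_exp, group_total = g_tot,
        pop_exposed = p_exp, pop_total = p_tot,
        rr = risk_ratio(g_exp, g_tot, p_exp, p_tot),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Within-block-group panel change between two periods
#'
#' For block groups observed in both periods (identical geoid sets are
#' required — the decennial boundary redefinition forbids mixing vintages),
#' categorises each block group by the sign of the change in an intensity
#' metric and sums the demographic counts of the later period within each
#' category. `"no_change"` means exact equality for well counts and
#' `|delta| < 1e-6` BOE for production volume, so floating-point accumulation
#' noise cannot create spurious categories.
#'
#' @param exposure_a,exposure_b [assess_exposure()] outputs for the earlier
#'   and later period (may be the same table; the period labels select rows).
#' @param bgs The [block_groups()] set (supplies later-period counts).
#' @param period_a,period_b Earlier and later period labels.
#' @param metric `"new_well_count"` (centroid count of new wells) or
#'   `"cumulative_boe"` (centroid-radius production volume).
#' @return Data frame: `metric`, `category`, `n_block_groups`, one column per
#'   race/ethnicity count plus `total_population`.
#' @export
panel_change <- function(exposure_a, exposure_b, bgs, period_a, period_b,
                         metric = c("new_well_count", "cumulative_boe")) {
  metric <- match.arg(metric)
  stopifnot(inherits(bgs, "bg_set"))
  pick <- function(exposure, period) {
    s <- if (metric == "new_well_count") "new" else "active"
    ex <- exposure[exposure$period == period & exposure$stage == s, , drop = FALSE]
    v <- if (metric == "new_well_count") ex$centroid_well_count else ex$centroid_boe
    stats::setNames(v, ex$geoid)
  }
  va <- pick(exposure_a, period_a)
  vb <- pick(exposure_b, period_b)
  if (!setequal(names(va), names(vb))) {
    stop("panel_change: the two periods cover different block-group sets")
  }
  vb <- vb[names(va)]
  delta <- vb - va
  tol <- if (metric == "cumulative_boe") 1e-6 else 0
  category <- ifelse(abs(delta) <= tol, "no_change",
                     ifelse(delta > 0, "increase", "decrease"))

  sc <- demographic_schema()
  demo <- bg_demo_period(bgs, period_b)    # later-period counts by convention
  demo <- demo[match(names(va), demo$geoid), , drop = FALSE]
  cols <- c("total_population", sc$race)
  out <- lapply(c("increase", "decrease", "no_change"), function(cat) {
    sel <- category == cat
    row <- data.frame(metric = metric, category = cat,
                      n_block_groups = sum(sel), stringsAsFactors = FALSE)
    for (col in cols) row[[col]] <- sum(demo[[col]][sel])
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count wells on tribal lands
#'
#' Boundary-inclusive point-in-polygon counts of wells per tribal polygon;
#' wells falling in no polygon are not counted anywhere.
#'
#' @param wells Wells data frame (projected metres, same CRS as the
#'   polygons).
#' @param tribal Named list of geometries (names identify the land areas).
#' @return Data frame: `land`, `n_wells`.
#' @export
tribal_overlay <- function(wells, tribal) {
  if (is.null(names(tribal))) stop("tribal polygons must be a named list")
  n <- vapply(tribal, function(g) {
    if (!nrow(wells)) 0L else sum(points_in_geom(wells$x, wells$y, g))
  }, 0L)
  data.frame(land = names(tribal), n_wells = as.integer(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percent share, rounded as reported
#'
#' `100 * num / denom` to one decimal; `NA` when the denominator is zero.
#'
#' @param num,denom Numerator and denominator.
#' @param digits Decimal places (default 1).
#' @return Numeric vector.
#' @export
pct_share <- function(num, denom, digits = 1) {
  out <- ifelse(denom == 0, NA_real_, 100 * num / denom)
  round(out, digits)
}

#' Percent change between two period values
#'
#' `100 * (new - old) / old` to one decimal; `NA` (undefined, reported as
#' such) when the baseline is zero.
#'
#' @param old,new Baseline and later values.
#' @param digits Decimal places (default 1).
#' @return Numeric vector.
#' @export
pct_change <- function(old, new, digits = 1) {
  out <- ifelse(old == 0, NA_real_, 100 * (new - old) / old)
  round(out, digits)
}

#' Trend summary rows over study periods
#'
#' For a table of per-period values (optionally with universes), computes the
#' percent share within each period, the period-over-period percent change,
#' and multi-period averages of the value and of the share.
#'
#' @param df Data frame with columns `period`, `value`, and optionally
#'   `universe`; one row per period, in period order.
#' @return `df` with added `share` (NA without a universe) and `change`
#'   columns, plus an `"averages"` attribute holding `mean_value` and
#'   `mean_share`.
#' @export
summarize_trends <- function(df) {
  stopifnot(all(c("period", "value") %in% names(df)))
  has_u <- "universe" %in% names(df)
  df$share <- if (has_u) pct_share(df$value, df$universe) else NA_real_
  df$change <- c(NA_real_, pct_change(df$value[-nrow(df)], df$value[-1L]))
  attr(df, "averages") <- data.frame(
    mean_value = mean(df$value),
    mean_share = if (has_u) round(mean(100 * df$value / df$universe), 1) else NA_real_)
  df
}
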