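# Group-level aggregation. The central convention: group indicators are
# expenditure-weighted aggregates — levels are sums over member countries,
# and ratios are computed from the aggregates of the numerators and
# denominators (so large economies carry large weight). The country-weighted
# alternative (each country counts once) is provided for methodology
# comparison.

check_indicator <- function(indicator) {
  known <- c("population", panel_monetary_cols())
  if (!indicator %in% known) {
    abort(paste0("unknown indicator: ", indicator))
  }
  indicator
}

panel_cell <- function(panel, iso3s, year, indicator) {
  rows <- panel[panel$iso3 %in% iso3s & panel$year == year, ]
  stats::setNames(rows[[indicator]], rows$iso3)
}

resolve_groups_years <- function(panel, assignment, groups, years) {
  if (is.null(groups)) groups <- reporting_groups(assignment)
  if (is.null(years)) years <- sort(unique(panel$year))
  list(groups = groups, years = as.integer(years))
}

#' Aggregate level of an indicator for reporting groups
#'
#' The group value is the exact sum over member countries with a present
#' value; members with a missing value are skipped and reflected in the
#' coverage count. If no member has data the cell is `NA`.
#'
#' @param panel a `fin_panel`.
#' @param assignment a `fin_groups` object.
#' @param indicator a level indicator name (e.g. `"gghe_d"`,
#'   `"population"`).
#' @param years,groups subsets to compute; default all years in the panel
#'   and all reporting groups.
#' @return tibble with columns group, year, indicator, value, n_countries,
#'   n_members, weighting.
#' @export
aggregate_level <- function(panel, assignment, indicator, years = NULL,
                            groups = NULL) {
  check_indicator(indicator)
  rg <- resolve_groups_years(panel, assignment, groups, years)
  grid <- tidyr::expand_grid(group = rg$groups, year = rg$years)
  purrr::pmap_dfr(grid, function(group, year) {
    vals <- panel_cell(panel, group_members(assignment, group), year,
                       indicator)
    present <- vals[!is.na(vals)]
    tibble::tibble(
      group = group, year = year, indicator = indicator,
      value = if (length(present) > 0) sum(present) else NA_real_,
      n_countries = length(present), n_members = length(vals),
      weighting = "aggregate"
    )
  })
}

#' Aggregate ratio of two level indicators
#'
#' Computed as the ratio of group sums: only members with BOTH the numerator
#' and the denominator present contribute, and they contribute to both sums
#' (complete-pairs rule), keeping the two sums over an identical country
#' set. Per-capita values are this operation with `denominator =
#' "population"`.
#'
#' @inheritParams aggregate_level
#' @param numerator,denominator level indicator names.
#' @return tibble with columns group, year, indicator
#'   (`"numerator/denominator"`), value (dimensionless ratio), n_countries,
#'   weighting.
#' @export
aggregate_ratio <- function(panel, assignment, numerator, denominator,
                            years = NULL, groups = NULL) {
  check_indicator(numerator)
  check_indicator(denominator)
  rg <- resolve_groups_years(panel, assignment, groups, years)
  grid <- tidyr::expand_grid(group = rg$groups, year = rg$years)
  purrr::pmap_dfr(grid, function(group, year) {
    members <- group_members(assignment, group)
    num <- panel_cell(panel, members, year, numerator)
    den <- panel_cell(panel, members, year, denominator)
    common <- intersect(names(num)[!is.na(num)], names(den)[!is.na(den)])
    if (length(common) == 0) {
      value <- NA_real_
    } else {
      den_sum <- sum(den[common])
      if (den_sum == 0) {
        abort(paste0("zero denominator sum for group ", group, ", year ",
                     year, " (", denominator, ")"))
      }
      value <- sum(num[common]) / den_sum
    }
    tibble::tibble(
      group = group, year = year,
      indicator = paste0(numerator, "/", denominator),
      value = value, n_countries = length(common), weighting = "aggregate"
    )
  })
}

#' Per-capita aggregate value
#'
#' Convenience wrapper: [aggregate_ratio()] with population as denominator.
#' If the panel stores monetary values in millions, the result is in
#' dollars per person times 1e-6; use `scale` to convert (default 1).
#'
#' @inheritParams aggregate_level
#' @param scale multiplier applied to the ratio (e.g. `1e6` when monetary
#'   columns are in millions and population in persons, to obtain US$ per
#'   person).
#' @export
per_capita <- function(panel, assignment, indicator, years = NULL,
                       groups = NULL, scale = 1) {
  out <- aggregate_ratio(panel, assignment, indicator, "population",
                         years = years, groups = groups)
  out$value <- out$value * scale
  out$indicator <- paste0(indicator, " per capita")
  out
}

#' Composition of current health expenditure by financing source
#'
#' For each group-year, the share of aggregate CHE financed by each of the
#' five sources (GGHE-D, EXT, OOP, voluntary prepayment, other private).
#' Each share is the aggregate component over aggregate CHE, summed over the
#' members contributing to the CHE sum; a member's missing component counts
#' as zero and sets `flagged` for that component. Shares are fractions;
#' rendering as percent is a reporting concern.
#'
#' @inheritParams aggregate_level
#' @return tibble with columns group, year, component, share, flagged.
#' @export
composition_shares <- function(panel, assignment, years = NULL,
                               groups = NULL) {
  rg <- resolve_groups_years(panel, assignment, groups, years)
  components <- c("gghe_d", "ext", "oop", "vpp", "pvt_other")
  grid <- tidyr::expand_grid(group = rg$groups, year = rg$years)
  purrr::pmap_dfr(grid, function(group, year) {
    members <- group_members(assignment, group)
    che <- panel_cell(panel, members, year, "che")
    contributors <- names(che)[!is.na(che)]
    che_sum <- sum(che[contributors])
    if (length(contributors) == 0 || is.na(che_sum) || che_sum <= 0) {
      abort(paste0("group ", group, " has no positive CHE aggregate in ",
                   year))
    }
    purrr::map_dfr(components, function(comp) {
      vals <- panel_cell(panel, contributors, year, comp)
      tibble::tibble(
        group = group, year = year, component = comp,
        share = sum(vals, na.rm = TRUE) / che_sum,
        flagged = anyNA(vals)
      )
    })
  })
}

#' Country-weighted average of a ratio
#'
#' The unweighted arithmetic mean of member-level ratios — each country
#' counts once regardless of size. This is the convention used by
#' country-weighted summaries and is reported alongside the aggregate
#' (expenditure-weighted) ratio to quantify methodological divergence.
#'
#' @inheritParams aggregate_ratio
#' @return tibble like [aggregate_ratio()] with weighting
#'   `"country_weighted"`.
#' @export
country_weighted_average <- function(panel, assignment, numerator,
                                     denominator, years = NULL,
                                     groups = NULL) {
  check_indicator(numerator)
  check_indicator(denominator)
  rg <- resolve_groups_years(panel, assignment, groups, years)
  grid <- tidyr::expand_grid(group = rg$groups, year = rg$years)
  purrr::pmap_dfr(grid, function(group, year) {
    members <- group_members(assignment, group)
    num <- panel_cell(panel, members, year, numerator)
    den <- panel_cell(panel, members, year, denominator)
    ok <- !is.na(num) & !is.na(den) & den != 0
    if (!any(ok)) {
      abort(paste0("no member of group ", group,
                   " has complete data for ", numerator, "/", denominator,
                   " in ", year))
    }
    tibble::tibble(
      group = group, year = year,
      indicator = paste0(numerator, "/", denominator),
      value = mean(num[ok] / den[ok]),
      n_countries = sum(ok), weighting = "country_weighted"
    )
  })
}
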