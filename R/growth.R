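# Endpoint growth metrics. Both operations are pure endpoint formulas
# (no regression smoothing): total percent change and the annualized
# compound rate ((x_end/x_base)^(1/(end-base)) - 1) * 100.

#' Total percent change between two values
#'
#' @param x_base base-period value, strictly positive.
#' @param x_end end-period value.
#' @return percent change `(x_end/x_base - 1) * 100`; negative allowed.
#'   Vectorized.
#' @export
percent_change <- function(x_base, x_end) {
  if (anyNA(x_base) || any(x_base <= 0)) {
    abort("percent_change requires a positive, non-missing base value")
  }
  (x_end / x_base - 1) * 100
}

#' Annualized compound growth rate between two years
#'
#' Returns `((x_end/x_base)^(1/(end_year - base_year)) - 1) * 100`, i.e. the
#' constant yearly rate that compounds the base value into the end value
#' over the period. The exponent denominator is the year difference (15 for
#' 2000 to 2015).
#'
#' @param x_base,x_end strictly positive values.
#' @param base_year,end_year calendar years, `end_year > base_year`.
#' @return annualized growth in percent per year. Vectorized.
#' @export
annualized_growth <- function(x_base, x_end, base_year, end_year) {
  if (anyNA(x_base) || anyNA(x_end) || any(x_base <= 0) || any(x_end <= 0)) {
    abort("annualized_growth requires positive, non-missing values")
  }
  if (any(end_year <= base_year)) {
    abort("end_year must exceed base_year")
  }
  ((x_end / x_base)^(1 / (end_year - base_year)) - 1) * 100
}

#' Round half away from zero
#'
#' Presentation rounding used in the report tables (base `round()` rounds
#' half to even). Applied only at reporting time; stored values keep full
#' precision.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Group growth table for levels, ratios and per-capita values
#'
#' Builds a tidy table of base-year value, end-year value, total percent
#' change and annualized growth for each reporting group, for any mix of
#' level indicators, aggregate ratios and per-capita values.
#'
#' @param panel a `fin_panel`.
#' @param assignment a `fin_groups` object.
#' @param base_year,end_year endpoint years.
#' @param levels character vector of level indicators to sum.
#' @param ratios list of `c(numerator, denominator)` pairs.
#' @param per_capita_of character vector of indicators reported per person.
#' @param pc_scale multiplier for per-capita values (see [per_capita()]).
#' @param groups reporting groups; default all.
#' @return tibble with columns group, measure, base_value, end_value,
#'   pct_change, annualized_pct, n_base, n_end.
#' @export
growth_table <- function(panel, assignment, base_year, end_year,
                         levels = character(), ratios = list(),
                         per_capita_of = character(), pc_scale = 1,
                         groups = NULL) {
  if (is.null(groups)) groups <- reporting_groups(assignment)
  years <- c(base_year, end_year)
  pieces <- list()
  for (ind in levels) {
    pieces[[length(pieces) + 1]] <-
      aggregate_level(panel, assignment, ind, years = years, groups = groups)
  }
  for (rt in ratios) {
    pieces[[length(pieces) + 1]] <-
      aggregate_ratio(panel, assignment, rt[1], rt[2], years = years,
                      groups = groups)
  }
  for (ind in per_capita_of) {
    pieces[[length(pieces) + 1]] <-
      per_capita(panel, assignment, ind, years = years, groups = groups,
                 scale = pc_scale)
  }
  long <- dplyr::bind_rows(pieces)
  wide <- long %>%
    dplyr::select("group", "year", "indicator", "value", "n_countries") %>%
    tidyr::pivot_wider(names_from = "year",
                       values_from = c("value", "n_countries"))
  vb <- wide[[paste0("value_", base_year)]]
  ve <- wide[[paste0("value_", end_year)]]
  tibble::tibble(
    group = wide$group,
    measure = wide$indicator,
    base_value = vb,
    end_value = ve,
    pct_change = ifelse(!is.na(vb) & vb > 0 & !is.na(ve),
                        (ve / vb - 1) * 100, NA_real_),
    annualized_pct = ifelse(!is.na(vb) & vb > 0 & !is.na(ve) & ve > 0,
                            ((ve / vb)^(1 / (end_year - base_year)) - 1) * 100,
                            NA_real_),
    n_base = wide[[paste0("n_countries_", base_year)]],
    n_end = wide[[paste0("n_countries_", end_year)]]
  )
}
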