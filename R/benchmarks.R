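# Benchmarking against international health-spending targets and a
# configurable percentile outlier screen.

#' Benchmark health-spending shares against policy targets
#'
#' Computes, per reporting group (or per country) and year, government
#' health expenditure as a share of general government expenditure and as a
#' share of GDP, and flags whether the Abuja target (at least 15% of the
#' government budget to health) and the lower edge of the 5-6%-of-GDP band
#' are met. The default numerator adds external health expenditure to
#' GGHE-D (government health spending from domestic and external sources,
#' missing EXT contributing zero); a GGHE-D-only variant is selectable.
#'
#' @param panel a `fin_panel`.
#' @param assignment a `fin_groups` object.
#' @param years years to evaluate; default all panel years.
#' @param level `"group"` (aggregate shares per reporting group) or
#'   `"country"` (per included country).
#' @param abuja_threshold share of GGE at which the Abuja flag is met
#'   (default 0.15).
#' @param gdp_threshold share of GDP at which the band flag is met
#'   (default 0.05, the lower edge of the 5-6% band).
#' @param numerator_variant `"gghe_d_plus_ext"` (default) or `"gghe_d"`.
#' @return tibble with columns entity, year, gghe_gge_share,
#'   abuja_met, abuja_gap_pp (signed, percentage points), gghe_gdp_share,
#'   gdp_band_met, gdp_gap_pp, numerator_variant; thresholds are carried as
#'   attributes `abuja_threshold` and `gdp_threshold`.
#' @export
benchmark_flags <- function(panel, assignment, years = NULL,
                            level = c("group", "country"),
                            abuja_threshold = 0.15, gdp_threshold = 0.05,
                            numerator_variant = c("gghe_d_plus_ext",
                                                  "gghe_d")) {
  level <- match.arg(level)
  numerator_variant <- match.arg(numerator_variant)
  if (is.null(years)) years <- sort(unique(panel$year))
  entities <- if (level == "group") {
    reporting_groups(assignment)
  } else {
    names(assignment$base_of)
  }
  grid <- tidyr::expand_grid(entity = entities, year = as.integer(years))
  out <- purrr::pmap_dfr(grid, function(entity, year) {
    members <- if (level == "group") {
      group_members(assignment, entity)
    } else {
      entity
    }
    ghd <- panel_cell(panel, members, year, "gghe_d")
    ext <- panel_cell(panel, members, year, "ext")
    gge <- panel_cell(panel, members, year, "gge")
    gdp <- panel_cell(panel, members, year, "gdp")
    num <- if (numerator_variant == "gghe_d_plus_ext") {
      ghd + ifelse(is.na(ext), 0, ext)
    } else {
      ghd
    }
    share_of <- function(den) {
      ok <- !is.na(num) & !is.na(den)
      if (!any(ok) || sum(den[ok]) == 0) NA_real_
      else sum(num[ok]) / sum(den[ok])
    }
    s_gge <- share_of(gge)
    s_gdp <- share_of(gdp)
    if (is.na(s_gge) || is.na(s_gdp)) {
      abort(paste0("benchmark shares not computable for ", entity, " in ",
                   year))
    }
    tibble::tibble(
      entity = entity, year = year,
      gghe_gge_share = s_gge,
      abuja_met = s_gge >= abuja_threshold,
      abuja_gap_pp = (s_gge - abuja_threshold) * 100,
      gghe_gdp_share = s_gdp,
      gdp_band_met = s_gdp >= gdp_threshold,
      gdp_gap_pp = (s_gdp - gdp_threshold) * 100,
      numerator_variant = numerator_variant
    )
  })
  attr(out, "abuja_threshold") <- abuja_threshold
  attr(out, "gdp_threshold") <- gdp_threshold
  out
}

# Nearest-rank percentile: value at sorted rank ceiling(p * n), ties broken
# deterministically by (value, iso3). Flagging compares values (not ranks)
# strictly against the cutoffs, so tied values share the same fate.
nearest_rank_cutoffs <- function(values, iso3, lower, upper) {
  ord <- order(values, iso3)
  sorted <- values[ord]
  n <- length(sorted)
  list(low = sorted[max(1L, ceiling(lower * n))],
       high = sorted[min(n, ceiling(upper * n))])
}

#' Flag outlier countries on an indicator ratio
#'
#' Screens country-level values of `numerator/denominator` (or the raw
#' indicator when `denominator` is `NULL`) in each given year, and the
#' period change between the first and last year, against percentile or
#' absolute bounds. The default rule flags values strictly outside the
#' nearest-rank 1st-99th percentile cutoffs of the countries screened; it
#' refuses to run with fewer than 10 countries.
#'
#' @param panel a `fin_panel`.
#' @param numerator level indicator.
#' @param denominator optional level indicator; when given, the screened
#'   value is the country's own ratio.
#' @param years years to screen; the change screen uses the first and last.
#' @param countries iso3 codes to screen (e.g. the included cohort);
#'   default all countries in the panel.
#' @param lower,upper percentile bounds as fractions (default 0.01, 0.99).
#' @param bounds optional `c(low, high)` absolute bounds; when supplied the
#'   percentile rule is bypassed and no minimum country count applies.
#' @return An object of class `fin_outliers`: list with `flagged` (tibble:
#'   iso3, indicator, window, value, rule_id) and `rule` (parameters).
#' @export
flag_outliers <- function(panel, numerator, denominator = NULL,
                          years = c(2000L, 2015L), countries = NULL,
                          lower = 0.01, upper = 0.99, bounds = NULL) {
  check_indicator(numerator)
  if (!is.null(denominator)) check_indicator(denominator)
  if (is.null(countries)) countries <- sort(unique(panel$iso3))
  years <- sort(as.integer(years))
  label <- if (is.null(denominator)) numerator
           else paste0(numerator, "/", denominator)
  country_values <- function(year) {
    num <- panel_cell(panel, countries, year, numerator)
    num <- num[countries[countries %in% names(num)]]
    if (is.null(denominator)) {
      v <- num
    } else {
      den <- panel_cell(panel, countries, year, denominator)
      den <- den[names(num)]
      v <- ifelse(!is.na(den) & den != 0, num / den, NA_real_)
      names(v) <- names(num)
    }
    v[!is.na(v)]
  }
  rule_id <- if (is.null(bounds)) {
    sprintf("percentile[%g,%g]", lower, upper)
  } else {
    sprintf("absolute[%g,%g]", bounds[1], bounds[2])
  }
  screen <- function(v, window) {
    if (length(v) == 0) return(NULL)
    if (is.null(bounds)) {
      if (length(v) < 10) {
        abort("percentile outlier rule needs at least 10 countries with data")
      }
      cut <- nearest_rank_cutoffs(unname(v), names(v), lower, upper)
    } else {
      cut <- list(low = bounds[1], high = bounds[2])
    }
    hit <- v < cut$low | v > cut$high
    if (!any(hit)) return(NULL)
    tibble::tibble(iso3 = names(v)[hit], indicator = label,
                   window = window, value = unname(v[hit]),
                   rule_id = rule_id)
  }
  flagged <- list()
  for (yr in years) {
    flagged[[length(flagged) + 1]] <- screen(country_values(yr),
                                             as.character(yr))
  }
  if (length(years) >= 2) {
    v0 <- country_values(years[1])
    v1 <- country_values(years[length(years)])
    common <- intersect(names(v0), names(v1))
    change <- v1[common] - v0[common]
    flagged[[length(flagged) + 1]] <-
      screen(change, paste0(years[1], "-", years[length(years)]))
  }
  flagged <- dplyr::bind_rows(flagged)
  if (nrow(flagged) == 0) {
    flagged <- tibble::tibble(iso3 = character(), indicator = character(),
                              window = character(), value = numeric(),
                              rule_id = character())
  }
  structure(
    list(flagged = flagged,
         rule = list(id = rule_id, lower = lower, upper = upper,
                     bounds = bounds, years = years)),
    class = "fin_outliers"
  )
}

#' @export
print.fin_outliers <- function(x, ...) {
  cat("Outlier screen (", x$rule$id, "): ", nrow(x$flagged),
      " flag(s)\n", sep = "")
  if (nrow(x$flagged) > 0) print(x$flagged)
  invisible(x)
}
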