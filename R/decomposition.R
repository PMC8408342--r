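# Log-additive decomposition of growth in domestic government health
# expenditure (GGHE-D). Writing GGHE-D = GDP * (GGE/GDP) * (GGHE-D/GGE) in
# both anchor years gives
#
#   ln(1 + g) = ln(1 + y) + ln(1 + e) + ln(1 + h)
#
# where g, y, e, h are the total-period growth rates of GGHE-D, GDP,
# GGE/GDP and GGHE-D/GGE. Each log term over ln(1+g) is the share of
# GGHE-D growth attributable to economic growth, expansion of government
# relative to GDP, and prioritization of health within the budget.

#' Decompose GGHE-D growth from six levels
#'
#' The primary entry point takes the six underlying levels so that the
#' log-additive identity holds exactly by construction (residual at machine
#' precision). Growth rates at or below -100% are mathematically undefined
#' here and rejected.
#'
#' @param gdp_0,gdp_1 GDP levels in the base and end year, positive.
#' @param gge_0,gge_1 general government expenditure levels, positive.
#' @param gghed_0,gghed_1 domestic government health expenditure levels,
#'   positive.
#' @return An object of class `gghed_decomposition`: a list with growth
#'   fractions `g`, `y`, `e`, `h`; log terms `Lg`, `Ly`, `Le`, `Lh` (nats);
#'   shares `s_y`, `s_e`, `s_h` (fractions of `Lg`, `NA` with
#'   `shares_defined = FALSE` when `Lg == 0`); and `residual`
#'   (`Lg - (Ly + Le + Lh)`, nats).
#' @export
decompose_gghed <- function(gdp_0, gdp_1, gge_0, gge_1, gghed_0, gghed_1) {
  levels <- c(gdp_0, gdp_1, gge_0, gge_1, gghed_0, gghed_1)
  if (anyNA(levels) || any(levels <= 0)) {
    abort("all six levels must be present and strictly positive")
  }
  if (gghed_0 > gge_0 || gghed_1 > gge_1) {
    warn("GGHE-D exceeds GGE in at least one year")
  }
  y <- gdp_1 / gdp_0 - 1
  e <- (gge_1 / gdp_1) / (gge_0 / gdp_0) - 1
  h <- (gghed_1 / gge_1) / (gghed_0 / gge_0) - 1
  g <- gghed_1 / gghed_0 - 1
  build_decomposition(g = g, y = y, e = e, h = h)
}

#' Decompose from pre-computed growth rates
#'
#' Reconstructs the decomposition from the four growth rates themselves
#' (e.g. rates printed in a report). When the rates come from rounded
#' sources the log identity need not hold; the discrepancy is reported in
#' `residual` and never silently redistributed.
#'
#' @param y,e,h growth fractions of GDP, GGE/GDP and GGHE-D/GGE; each must
#'   exceed -1.
#' @param g growth fraction of GGHE-D; if `NULL`, taken as the exact
#'   product `(1+y)(1+e)(1+h) - 1` (zero residual).
#' @return A `gghed_decomposition` object.
#' @export
decompose_from_rates <- function(y, e, h, g = NULL) {
  if (any(c(y, e, h) <= -1)) {
    abort("growth rates at or below -100% are undefined in log space")
  }
  if (is.null(g)) {
    g <- growth_from_component_rates(y, e, h)
  } else if (g <= -1) {
    abort("growth rates at or below -100% are undefined in log space")
  }
  build_decomposition(g = g, y = y, e = e, h = h)
}

build_decomposition <- function(g, y, e, h) {
  Lg <- log1p(g); Ly <- log1p(y); Le <- log1p(e); Lh <- log1p(h)
  shares_defined <- Lg != 0
  structure(
    list(g = g, y = y, e = e, h = h,
         Lg = Lg, Ly = Ly, Le = Le, Lh = Lh,
         s_y = if (shares_defined) Ly / Lg else NA_real_,
         s_e = if (shares_defined) Le / Lg else NA_real_,
         s_h = if (shares_defined) Lh / Lg else NA_real_,
         shares_defined = shares_defined,
         residual = Lg - (Ly + Le + Lh)),
    class = "gghed_decomposition"
  )
}

#' @export
print.gghed_decomposition <- function(x, ...) {
  cat("GGHE-D growth decomposition\n")
  cat(sprintf("  g = %.1f%% (GGHE-D), y = %.1f%% (GDP), e = %.1f%% (GGE/GDP), h = %.1f%% (GGHE-D/GGE)\n",
              100 * x$g, 100 * x$y, 100 * x$e, 100 * x$h))
  if (x$shares_defined) {
    cat(sprintf("  shares of ln(1+g): GDP %.1f%%, GGE/GDP %.1f%%, GGHE-D/GGE %.1f%%\n",
                100 * x$s_y, 100 * x$s_e, 100 * x$s_h))
  } else {
    cat("  shares undefined (no change in GGHE-D)\n")
  }
  cat(sprintf("  residual: %.3g nats\n", x$residual))
  invisible(x)
}

#' Share of GGHE-D log-growth attributable to one component
#'
#' `ln(comp_1/comp_0) / ln(gghed_1/gghed_0)`. The component pair may be
#' levels or ratio values — only the ratio of the pair matters, so 22.6 and
#' 24.5 (percent) work as well as 0.226 and 0.245.
#'
#' @param comp_0,comp_1 positive component values at base and end.
#' @param gghed_0,gghed_1 positive GGHE-D levels; must differ.
#' @return the share as a fraction.
#' @export
component_share <- function(comp_0, comp_1, gghed_0, gghed_1) {
  if (anyNA(c(comp_0, comp_1, gghed_0, gghed_1)) ||
      any(c(comp_0, comp_1, gghed_0, gghed_1) <= 0)) {
    abort("component_share requires positive, non-missing inputs")
  }
  denom <- log(gghed_1 / gghed_0)
  if (denom == 0) {
    abort("GGHE-D did not change; the share denominator is zero")
  }
  log(comp_1 / comp_0) / denom
}

#' GGHE-D growth implied by its component growth rates
#'
#' `g = (1+y)(1+e)(1+h) - 1`, the multiplicative composition of economic
#' growth, government-size expansion and health prioritization.
#'
#' @param y,e,h growth fractions; each `1 + rate` must be positive.
#' @return g as a fraction.
#' @export
growth_from_component_rates <- function(y, e, h) {
  if (any(c(1 + y, 1 + e, 1 + h) <= 0)) {
    abort("each growth factor (1 + rate) must be positive")
  }
  (1 + y) * (1 + e) * (1 + h) - 1
}

#' Decomposition table for all reporting groups
#'
#' Aggregates GDP, GGE and GGHE-D over each reporting group at the two
#' anchor years and decomposes the group-level GGHE-D growth. Because the
#' decomposition runs on one consistent set of aggregate levels, the log
#' identity is exact for every row.
#'
#' @param panel a `fin_panel`.
#' @param assignment a `fin_groups` object.
#' @param base_year,end_year anchor years.
#' @param groups reporting groups; default all.
#' @return tibble with one row per group: growth rates and shares in
#'   percent, residual in nats.
#' @export
group_decomposition <- function(panel, assignment, base_year, end_year,
                                groups = NULL) {
  if (is.null(groups)) groups <- reporting_groups(assignment)
  years <- c(base_year, end_year)
  lev <- function(ind) {
    aggregate_level(panel, assignment, ind, years = years, groups = groups)
  }
  gdp <- lev("gdp"); gge <- lev("gge"); ghd <- lev("gghe_d")
  pick <- function(tab, group, year) {
    tab$value[tab$group == group & tab$year == year]
  }
  purrr::map_dfr(groups, function(grp) {
    d <- decompose_gghed(
      pick(gdp, grp, base_year), pick(gdp, grp, end_year),
      pick(gge, grp, base_year), pick(gge, grp, end_year),
      pick(ghd, grp, base_year), pick(ghd, grp, end_year)
    )
    tibble::tibble(
      group = grp,
      g_pct = 100 * d$g, y_pct = 100 * d$y,
      e_pct = 100 * d$e, h_pct = 100 * d$h,
      share_gdp_pct = 100 * d$s_y,
      share_gge_gdp_pct = 100 * d$s_e,
      share_gghed_gge_pct = 100 * d$s_h,
      residual_nats = d$residual
    )
  })
}
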