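# Synthetic GHED-like panel generator. Countries follow multiplicative
# trajectories: GDP, the GGE/GDP ratio, the GGHE-D/GGE ratio and population
# each compound at a constant per-year factor derived from a total-period
# growth parameter, so endpoint formulas recover the configured parameters
# exactly. CHE is built additively from its five components, which keeps
# the accounting identity exact before any missingness injection.

default_group_params <- function() {
  # Total-period (15-year) rates derived from annualized group trends of
  # roughly 6.3/7.1/3.3/1.5 %/yr GDP growth and the corresponding
  # government-size and prioritization drifts; base levels are GHED-like
  # orders of magnitude in constant 2010 US$.
  tibble::tibble(
    group        = c("LIC", "LMIC", "UMIC", "HIC"),
    n_countries  = c(15L, 15L, 15L, 15L),
    pop_min      = c(2e6, 2e6, 3e6, 4e6),
    pop_max      = c(6e7, 8e7, 8e7, 1e8),
    gdp_pc_min   = c(300, 900, 3000, 20000),
    gdp_pc_max   = c(900, 2500, 9000, 50000),
    gge_gdp_min  = c(0.16, 0.18, 0.22, 0.32),
    gge_gdp_max  = c(0.28, 0.30, 0.34, 0.48),
    gghe_gge_min = c(0.03, 0.04, 0.07, 0.10),
    gghe_gge_max = c(0.06, 0.09, 0.13, 0.18),
    oop_che      = c(0.60, 0.47, 0.14, 0.16),
    ext_che      = c(0.10, 0.02, 0.005, 0.001),
    vpp_che      = c(0.02, 0.05, 0.15, 0.20),
    other_che    = c(0.04, 0.06, 0.10, 0.12),
    y            = c(1.50, 1.80, 0.63, 0.25),
    e            = c(0.075, 0.40, 0.26, 0.06),
    h            = c(0.10, 0.19, 0.64, 0.36),
    pop_growth   = c(0.31, 0.13, 0.20, 0.11)
  )
}

default_focus_params <- function() {
  # Two large, fast-growing economies in the lower groups, emulating a
  # group-dominating country whose weight warrants a singleton breakout.
  tibble::tibble(
    iso3 = c("AXX", "BXX"),
    group = c("LIC", "LMIC"),
    population = c(1.0e9, 1.3e9),
    gdp_pc = c(450, 950),
    gge_gdp = c(0.26, 0.24),
    gghe_gge = c(0.035, 0.062),
    y = c(1.9, 3.0),
    e = c(0.15, 0.85),
    h = c(0.12, 0.65),
    pop_growth = c(0.25, 0.09)
  )
}

#' Configuration for the synthetic panel generator
#'
#' Defaults describe a four-income-group world of 15 countries per group
#' plus two focus-style large economies, observed 2000-2015, noise-free and
#' fully observed. All randomness is governed by `seed`; the same
#' configuration always yields the same panel.
#'
#' @param groups tibble of per-group parameters (see
#'   `fiscalspace:::default_group_params()` for the column set): country
#'   count, base ranges for population, GDP per capita (US$/person),
#'   GGE/GDP and GGHE-D/GGE, point shares of CHE for OOP, EXT, voluntary
#'   prepayment and other private (their sum must stay below 1; the GGHE-D
#'   share is the remainder), and total-period growth fractions `y`
#'   (GDP), `e` (GGE/GDP), `h` (GGHE-D/GGE) and `pop_growth`.
#' @param focus tibble of focus-country rows (iso3, group, base levels,
#'   own growth rates); `NULL` for none.
#' @param years analysis years (default 2000:2015).
#' @param noise_sigma lognormal sigma of multiplicative noise applied to
#'   levels (0 = noise-free).
#' @param growth_jitter standard deviation of per-country additive jitter
#'   on the group growth fractions (0 = every member grows at the group
#'   rate, making group aggregates recover the parameters exactly).
#' @param missingness `NULL`, a named numeric vector of per-indicator
#'   blanking rates, or a data frame (indicator, year, rate); applied via
#'   [inject_missingness()].
#' @param seed integer RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(groups = default_group_params(),
                             focus = default_focus_params(),
                             years = 2000:2015,
                             noise_sigma = 0,
                             growth_jitter = 0,
                             missingness = NULL,
                             seed = 1L) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(groups$n_countries >= 0),
            all(groups$pop_min > 0), all(groups$pop_max >= groups$pop_min),
            all(groups$gdp_pc_min > 0),
            all(groups$gge_gdp_min > 0), all(groups$gge_gdp_max < 1),
            all(groups$gghe_gge_min > 0), all(groups$gghe_gge_max < 1),
            noise_sigma >= 0, growth_jitter >= 0, length(years) >= 2)
  comp_sum <- groups$oop_che + groups$ext_che + groups$vpp_che +
    groups$other_che
  if (any(comp_sum >= 1) || any(c(groups$oop_che, groups$ext_che,
                                  groups$vpp_che, groups$other_che) < 0)) {
    abort("infeasible CHE shares: component shares must be >= 0 and sum below 1")
  }
  if (any(c(groups$y, groups$e, groups$h, groups$pop_growth) <= -1)) {
    abort("total-period growth fractions must exceed -1")
  }
  structure(
    list(groups = groups, focus = focus, years = sort(as.integer(years)),
         noise_sigma = noise_sigma, growth_jitter = growth_jitter,
         missingness = missingness, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

group_prefix <- function(group) {
  prefixes <- c(LIC = "A", LMIC = "B", UMIC = "C", HIC = "D")
  if (group %in% names(prefixes)) prefixes[[group]] else substr(group, 1, 1)
}

#' Generate a synthetic health-financing panel with known ground truth
#'
#' Builds country trajectories over the configured years: base-year levels
#' drawn uniformly from the group ranges, then compounded at the constant
#' per-year factor `(1 + rate)^(1/(last - first))` for GDP, GGE/GDP,
#' GGHE-D/GGE and population. CHE is the exact sum of its five components
#' in every cell (before optional noise, after which CHE is re-summed so
#' additivity still holds). Deterministic for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `panel` (a `fin_panel`), `truth` (list:
#'   `country_rates` tibble of the exact per-country y, e, h, g and
#'   population growth; `group_rates`; `classification` tibble usable with
#'   [assign_income_groups()]; `focus` iso3 codes; the config), and `mask`
#'   (missingness mask tibble, empty when no missingness configured).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- config$years
  span <- years[length(years)] - years[1]
  withr::with_seed(config$seed, {
    country_rows <- list()
    for (gi in seq_len(nrow(config$groups))) {
      gp <- config$groups[gi, ]
      n <- gp$n_countries
      if (n == 0) next
      iso3 <- sprintf("%s%02d", group_prefix(gp$group), seq_len(n))
      jit <- function(rate) {
        if (config$growth_jitter > 0) {
          pmax(rate + stats::rnorm(n, 0, config$growth_jitter), -0.95)
        } else {
          rep(rate, n)
        }
      }
      country_rows[[length(country_rows) + 1]] <- tibble::tibble(
        iso3 = iso3, group = gp$group,
        population = stats::runif(n, gp$pop_min, gp$pop_max),
        gdp_pc = stats::runif(n, gp$gdp_pc_min, gp$gdp_pc_max),
        gge_gdp = stats::runif(n, gp$gge_gdp_min, gp$gge_gdp_max),
        gghe_gge = stats::runif(n, gp$gghe_gge_min, gp$gghe_gge_max),
        oop_che = gp$oop_che, ext_che = gp$ext_che,
        vpp_che = gp$vpp_che, other_che = gp$other_che,
        y = jit(gp$y), e = jit(gp$e), h = jit(gp$h),
        pop_growth = jit(gp$pop_growth)
      )
    }
    countries <- dplyr::bind_rows(country_rows)
    if (!is.null(config$focus)) {
      fc <- tibble::as_tibble(config$focus)
      shares <- config$groups[match(fc$group, config$groups$group), ]
      countries <- dplyr::bind_rows(countries, tibble::tibble(
        iso3 = fc$iso3, group = fc$group,
        population = fc$population, gdp_pc = fc$gdp_pc,
        gge_gdp = fc$gge_gdp, gghe_gge = fc$gghe_gge,
        oop_che = shares$oop_che, ext_che = shares$ext_che,
        vpp_che = shares$vpp_che, other_che = shares$other_che,
        y = fc$y, e = fc$e, h = fc$h, pop_growth = fc$pop_growth
      ))
    }
    records <- tidyr::expand_grid(
      countries, year = years
    ) %>%
      dplyr::mutate(frac = (.data$year - years[1]) / span)
    # Levels in millions of constant dollars; population in persons.
    records <- records %>%
      dplyr::mutate(
        pop_t = .data$population * (1 + .data$pop_growth)^.data$frac,
        gdp = .data$population * .data$gdp_pc / 1e6 *
          (1 + .data$y)^.data$frac,
        gge = .data$gdp * .data$gge_gdp * (1 + .data$e)^.data$frac,
        gghe_d = .data$gge * .data$gghe_gge * (1 + .data$h)^.data$frac
      )
    gghe_che <- 1 - (records$oop_che + records$ext_che + records$vpp_che +
                       records$other_che)
    che <- records$gghe_d / gghe_che
    panel_df <- tibble::tibble(
      iso3 = records$iso3,
      name = paste("Country", records$iso3),
      year = records$year,
      population = records$pop_t,
      gdp = records$gdp,
      gge = records$gge,
      gghe_d = records$gghe_d,
      oop = che * records$oop_che,
      ext = che * records$ext_che,
      vpp = che * records$vpp_che,
      pvt_other = che * records$other_che
    )
    if (config$noise_sigma > 0) {
      noisy <- function(x) {
        x * stats::rlnorm(length(x), 0, config$noise_sigma)
      }
      panel_df <- panel_df %>%
        dplyr::mutate(dplyr::across(c("population", "gdp", "gge", "gghe_d",
                                      "oop", "ext", "vpp", "pvt_other"),
                                    noisy))
    }
    # CHE re-summed from (possibly noisy) components: additivity holds.
    panel_df$che <- panel_df$gghe_d + panel_df$ext + panel_df$oop +
      panel_df$vpp + panel_df$pvt_other
    panel <- as_fin_panel(panel_df,
                          unit_scale = "millions, constant 2010 US$",
                          provenance = paste0("synthetic, seed ",
                                              config$seed))
    truth <- list(
      country_rates = countries %>%
        dplyr::mutate(g = (1 + .data$y) * (1 + .data$e) * (1 + .data$h) - 1) %>%
        dplyr::select("iso3", "group", "y", "e", "h", "g", "pop_growth"),
      group_rates = config$groups %>%
        dplyr::mutate(g = (1 + .data$y) * (1 + .data$e) * (1 + .data$h) - 1) %>%
        dplyr::select("group", "y", "e", "h", "g", "pop_growth"),
      classification = tibble::tibble(
        iso3 = countries$iso3, group = countries$group,
        classification_year = years[1]
      ),
      focus = if (is.null(config$focus)) character() else config$focus$iso3,
      config = config
    )
    mask <- tibble::tibble(iso3 = character(), year = integer(),
                           indicator = character())
    if (!is.null(config$missingness)) {
      inj <- inject_missingness(panel, config$missingness,
                                seed = config$seed + 1L)
      panel <- inj$panel
      mask <- inj$mask
    }
    list(panel = panel, truth = truth, mask = mask)
  })
}

#' Blank panel cells at configured rates
#'
#' Each targeted (indicator, year) cell is blanked independently with its
#' configured probability; the returned mask records exactly which cells
#' were blanked. Blanking anchor-year cells interacts with the inclusion
#' filters in the expected way (affected countries drop out downstream).
#'
#' @param panel a `fin_panel`.
#' @param rates either a named numeric vector of rates (indicator -> rate
#'   applied in every year) or a data frame with columns `indicator`,
#'   `year`, `rate`. Rates must lie in `[0, 1]`.
#' @param seed integer RNG seed for the Bernoulli draws.
#' @return list with `panel` (blanked copy) and `mask` (tibble: iso3,
#'   year, indicator of blanked cells).
#' @export
inject_missingness <- function(panel, rates, seed = 1L) {
  if (is.data.frame(rates)) {
    spec <- tibble::as_tibble(rates)
    stopifnot(all(c("indicator", "year", "rate") %in% names(spec)))
  } else {
    if (is.null(names(rates)) || any(names(rates) == "")) {
      abort("rates must be named by indicator")
    }
    spec <- tidyr::expand_grid(
      indicator = names(rates), year = sort(unique(panel$year))
    ) %>%
      dplyr::mutate(rate = unname(rates[.data$indicator]))
  }
  if (any(spec$rate < 0 | spec$rate > 1)) {
    abort("missingness rates must lie in [0, 1]")
  }
  bad <- setdiff(spec$indicator, c("population", panel_monetary_cols()))
  if (length(bad) > 0) {
    abort(paste0("unknown indicator(s) in missingness spec: ",
                 paste(bad, collapse = ", ")))
  }
  out <- panel
  mask <- list()
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(spec))) {
      ind <- spec$indicator[i]; yr <- spec$year[i]; rate <- spec$rate[i]
      rows <- which(out$year == yr & !is.na(out[[ind]]))
      if (length(rows) == 0 || rate == 0) next
      hit <- rows[stats::runif(length(rows)) < rate]
      if (length(hit) == 0) next
      out[[ind]][hit] <- NA_real_
      mask[[length(mask) + 1]] <- tibble::tibble(
        iso3 = out$iso3[hit], year = as.integer(yr), indicator = ind
      )
    }
  })
  mask <- if (length(mask) > 0) {
    dplyr::bind_rows(mask)
  } else {
    tibble::tibble(iso3 = character(), year = integer(),
                   indicator = character())
  }
  list(panel = out, mask = mask)
}

#' Write a synthetic panel and its ground truth to disk
#'
#' @param generated result of [generate_panel()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(generated$panel, file.path(dir, "panel.csv"))
  readr::write_csv(generated$truth$classification,
                   file.path(dir, "classification.csv"))
  truth <- generated$truth
  truth$config <- truth$config[setdiff(names(truth$config),
                                       c("groups", "focus"))]
  jsonlite::write_json(
    list(country_rates = truth$country_rates,
         group_rates = truth$group_rates,
         focus = truth$focus,
         seed = generated$truth$config$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
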