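# Small in-code fixtures shared across the suite.

# An additively consistent country-year record; override any field.
make_record <- function(iso3 = "AAA", year = 2000, population = 1e6,
                        gdp = 1000, gge = 250, gghe_d = 20, ext = 5,
                        oop = 30, vpp = 3, pvt_other = 2,
                        che = gghe_d + ext + oop + vpp + pvt_other) {
  tibble::tibble(iso3 = iso3, year = year, population = population,
                 gdp = gdp, gge = gge, gghe_d = gghe_d, che = che,
                 oop = oop, ext = ext, vpp = vpp, pvt_other = pvt_other)
}

make_panel <- function(...) {
  as_fin_panel(dplyr::bind_rows(...))
}

# Panel of n identical-structure countries across the anchor years only.
anchor_panel <- function(n = 3, years = c(2000, 2015)) {
  rows <- lapply(seq_len(n), function(i) {
    dplyr::bind_rows(lapply(years, function(yr) {
      make_record(iso3 = sprintf("C%02d", i), year = yr,
                  population = 1e6 * i, gdp = 1000 * i, gge = 250 * i,
                  gghe_d = 20 * i, ext = 5 * i, oop = 30 * i, vpp = 3 * i,
                  pvt_other = 2 * i)
    }))
  })
  make_panel(dplyr::bind_rows(rows))
}

# Assignment placing every country of the panel in one group, without
# running the inclusion filters (handy for single-year fixtures).
single_group_assignment <- function(panel, group = "LIC",
                                    focus = character()) {
  iso <- sort(unique(panel$iso3))
  rep <- structure(
    list(decisions = tibble::tibble(iso3 = iso, decision = "included",
                                    population_ref = NA_real_,
                                    missing = list(character())),
         counts = tibble::tibble(decision = "included", n = length(iso)),
         criteria = inclusion_criteria()),
    class = "fin_exclusions"
  )
  cls <- tibble::tibble(iso3 = iso, group = group)
  assign_income_groups(rep, cls, focus_countries = focus)
}

default_generated <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_panel(synthetic_config(seed = 42))
    cache
  }
})
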